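#' Min-max intensity normalization
#'
#' Rescales a raw intensity array to \eqn{I_0 = (I - I_{min}) /
#' (I_{max} - I_{min}) \in [0, 1]}.  Works for 8-bit `[0, 255]` integers as
#' well as arbitrary finite ranges; a constant image cannot be normalized
#' and is mapped to all zeros with a warning.
#'
#' @param raw Numeric matrix of raw intensities.
#' @param grid Optional [grid_spec()]; defaults to a unit-width domain
#'   matching the matrix (height follows from the common mesh size).
#' @return An [image_field()] with `source_min`/`source_max` recording the
#'   original range.
#' @examples
#' normalize_intensity(matrix(c(50, 100, 150), 1))$values  # 0, 0.5, 1
#' @export
normalize_intensity <- function(raw, grid = NULL) {
  raw <- as.matrix(raw)
  if (length(raw) == 0L) stop("empty image")
  if (!all(is.finite(raw))) stop("image contains non-finite values")
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) {
    warning("constant image: normalization undefined, returning all zeros")
    vals <- raw * 0
  } else {
    vals <- (raw - lo) / (hi - lo)
  }
  image_field(vals, grid, source_min = lo, source_max = hi)
}

#' Initialize the phase field from the image
#'
#' \eqn{\phi = K I_0}: the normalized intensity stretched over the `K`
#' phase levels, so that dark cells start near the 0-well and the
#' brightest cells at level `K`.
#'
#' @param image A normalized [image_field()].
#' @param K Number of phases (>= 1).
#' @return A [phase_field()] with values in `[0, K]` and time index 0.
#' @export
init_phase <- function(image, K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  phase_field(K * image$values, K, image$grid, time_index = 0L)
}

#' Extract phase labels and masks from a phase field
#'
#' Assigns label `k` where \eqn{\phi \in [k - 1/2, k + 1/2)}, with the two
#' outer bands extended so every cell gets exactly one label in
#' `0, ..., K-1` (values at or above `K - 1/2` belong to the top phase).
#' A value exactly on a band edge `k + 1/2` is assigned upward, to phase
#' `k + 1`.
#'
#' @param phi A [phase_field()] (or numeric matrix together with `K`).
#' @param K Number of phases.
#' @return List with `labels` (integer matrix, 0-based), `masks` (list of
#'   `K` logical matrices forming a partition) and `contour_levels`
#'   (`0.5, 1.5, ..., K - 0.5`).
#' @export
extract_phases <- function(phi, K = NULL) {
  if (inherits(phi, "phase_field")) {
    if (is.null(K)) K <- phi$K
    M <- phi$values
  } else {
    if (is.null(K)) stop("K required when phi is a bare matrix")
    M <- as.matrix(phi)
  }
  K <- as.integer(K)
  if (!all(is.finite(M))) stop("phase values must be finite")
  lab <- floor(M + 0.5)
  lab[lab < 0] <- 0
  lab[lab > K - 1] <- K - 1
  storage.mode(lab) <- "integer"
  masks <- lapply(seq_len(K) - 1L, function(k) lab == k)
  list(labels = lab, masks = masks,
       contour_levels = seq_len(K) - 0.5)
}

#' Contour of a phase field at a level
#'
#' Finds where the level set \eqn{\phi = \ell} passes between cells: all
#' 4-neighbor cell pairs whose values straddle the level strictly
#' (`(phi1 - l)(phi2 - l) < 0`), plus any cells sitting exactly on it.
#'
#' @param phi A [phase_field()] or numeric matrix.
#' @param level The contour level (typically half-integer).
#' @return List with `edges` — a data frame of crossed edges (`i1`, `j1`,
#'   `i2`, `j2`, row/column indices of the two cells) — and `cells`, a data
#'   frame (`i`, `j`) of cells with `phi` exactly equal to `level`.  Both
#'   are empty when the field lies strictly on one side.
#' @export
extract_contour <- function(phi, level) {
  M <- if (inherits(phi, "phase_field")) phi$values else as.matrix(phi)
  if (!is.finite(level)) stop("level must be finite")
  S <- M - level
  ny <- nrow(M); nx <- ncol(M)
  e <- list()
  if (nx > 1L) {
    cross <- which(S[, 1:(nx - 1L), drop = FALSE] * S[, 2:nx, drop = FALSE] < 0,
                   arr.ind = TRUE)
    e[[1L]] <- data.frame(i1 = cross[, 1L], j1 = cross[, 2L],
                          i2 = cross[, 1L], j2 = cross[, 2L] + 1L)
  }
  if (ny > 1L) {
    cross <- which(S[1:(ny - 1L), , drop = FALSE] * S[2:ny, , drop = FALSE] < 0,
                   arr.ind = TRUE)
    e[[2L]] <- data.frame(i1 = cross[, 1L], j1 = cross[, 2L],
                          i2 = cross[, 1L] + 1L, j2 = cross[, 2L])
  }
  edges <- do.call(rbind, e)
  if (is.null(edges)) edges <- data.frame(i1 = integer(), j1 = integer(),
                                          i2 = integer(), j2 = integer())
  on_level <- which(S == 0, arr.ind = TRUE)
  cells <- data.frame(i = as.integer(on_level[, 1L]),
                      j = as.integer(on_level[, 2L]))
  list(edges = edges, cells = cells)
}

#' Read a single-channel raster image
#'
#' Supports grayscale PNG and TIFF (via the \pkg{png} and \pkg{tiff}
#' packages) and PGM (P2/P5).  Multi-channel input is an error unless
#' `to_gray = TRUE`, in which case Rec. 601 luma weights are applied.
#'
#' @param path Image file path (`.png`, `.tif(f)`, `.pgm`).
#' @param to_gray Convert RGB(A) input to luma instead of erroring.
#' @return Numeric matrix of raw intensities.
#' @export
read_image <- function(path, to_gray = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, " (use PNG, TIFF or PGM)")
  )
  if (length(dim(raw)) == 3L) {
    if (!to_gray)
      stop("multi-channel image; pass to_gray = TRUE to convert with Rec. 601 luma")
    nc <- dim(raw)[3L]
    if (nc >= 3L)
      raw <- 0.299 * raw[, , 1L] + 0.587 * raw[, , 2L] + 0.114 * raw[, , 3L]
    else raw <- raw[, , 1L]
  }
  as.matrix(raw)
}

# Minimal PGM reader: ASCII P2 and binary 8-bit P5.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens, skipping comments
  while (length(tokens) < 4L) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PGM header")
    line <- sub("#.*$", "", line)
    tk <- strsplit(trimws(line), "\\s+")[[1]]
    tokens <- c(tokens, tk[nzchar(tk)])
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L]); hgt <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (magic == "P2") {
    vals <- scan(con, what = numeric(), n = w * hgt, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval > 255) stop("16-bit P5 PGM not supported")
    vals <- as.numeric(readBin(con, "integer", n = w * hgt, size = 1L,
                               signed = FALSE))
  } else stop("not a PGM file (magic ", magic, ")")
  if (length(vals) != w * hgt) stop("truncated PGM data")
  matrix(vals, nrow = hgt, ncol = w, byrow = TRUE)
}

# Minimal ASCII (P2) PGM writer for 8-bit data in [0, 1] or [0, 255].
write_pgm <- function(values, path) {
  v <- as.matrix(values)
  if (max(v) <= 1) v <- v * 255
  v <- round(pmin(pmax(v, 0), 255))
  lines <- c("P2", paste(ncol(v), nrow(v)), "255",
             apply(v, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Segment an image end to end
#'
#' The full pipeline: read (or accept) a single-channel raster, min-max
#' normalize, initialize \eqn{\phi = K I_0}, evolve the phase field, and
#' extract labels, masks and half-integer contours.  Optionally writes the
#' label map, the per-phase masks, a contour overlay, the energy trace and
#' a config echo to `out_dir`.  The pipeline contains no randomness:
#' identical input and configuration give identical output.
#'
#' @param input File path (PNG/TIFF/PGM) or a numeric matrix of raw
#'   intensities.
#' @param K Number of phases; ignored when `params` is supplied.
#' @param params A [solver_params()]; defaults to
#'   `solver_params(K = K)`.
#' @param out_dir Optional output directory (created if missing).
#' @param to_gray Convert multi-channel input with Rec. 601 luma.
#' @param verbose Log per-step energies to `stderr`.
#' @return The `segmentation_result` from [evolve()], with an extra
#'   `files` element when outputs were written.
#' @export
run_segmentation <- function(input, K = 2L, params = NULL, out_dir = NULL,
                             to_gray = FALSE, verbose = FALSE) {
  if (is.null(params)) params <- solver_params(K = K)
  raw <- if (is.character(input)) read_image(input, to_gray = to_gray)
         else as.matrix(input)
  image <- normalize_intensity(raw)
  res <- evolve(image, params)
  if (verbose) {
    for (n in seq_along(res$energy_trace))
      message(sprintf("step %d: energy = %.8g", n - 1L, res$energy_trace[n]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    res$files <- write_outputs(res, image, out_dir)
  }
  res
}

write_outputs <- function(res, image, out_dir) {
  K <- res$params$K
  files <- character(0)
  f <- file.path(out_dir, "labels.png")
  png::writePNG(res$labels / 255, f)              # stored byte = phase index
  files <- c(files, f)
  for (k in seq_len(K) - 1L) {
    f <- file.path(out_dir, sprintf("mask_%d.png", k))
    png::writePNG(res$masks[[k + 1L]] * 1, f)
    files <- c(files, f)
  }
  contour <- matrix(0, nrow(res$labels), ncol(res$labels))
  for (lev in res$contour_levels) {
    ct <- extract_contour(res$phi_final, lev)
    if (nrow(ct$edges)) {
      contour[cbind(ct$edges$i1, ct$edges$j1)] <- 1
      contour[cbind(ct$edges$i2, ct$edges$j2)] <- 1
    }
    if (nrow(ct$cells)) contour[cbind(ct$cells$i, ct$cells$j)] <- 1
  }
  f <- file.path(out_dir, "contours.png")
  png::writePNG(pmax(image$values * 0.5, contour), f)
  files <- c(files, f)
  tr <- data.frame(step = seq_along(res$energy_trace) - 1L,
                   energy = res$energy_trace)
  cmat <- res$means_trace
  colnames(cmat) <- paste0("C_", seq_len(K) - 1L)
  tr <- cbind(tr, cmat)
  f <- file.path(out_dir, "energy_trace.tsv")
  utils::write.table(tr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  p <- res$params
  cfg <- c(sprintf("K=%d", p$K), sprintf("epsilon=%.10g", p$epsilon),
           sprintf("m=%d", p$m), sprintf("rho=%g", p$rho),
           sprintf("lambda=%g", p$lambda), sprintf("dt=%g", p$dt),
           sprintf("n_steps=%d", p$n_steps), sprintf("scheme=%s", p$scheme),
           sprintf("subgrid=%s", tolower(p$subgrid_enabled)),
           sprintf("update_means=%s", tolower(p$update_means)),
           sprintf("potential=%s", p$potential$mode),
           sprintf("deriv=%s", p$potential$deriv_mode))
  f <- file.path(out_dir, "config.txt")
  writeLines(cfg, f)
  c(files, f)
}
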