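#' Phantom specification
#'
#' Describes a seeded piecewise-constant K-phase test image with known
#' ground-truth labels.  Default intensities are `k/K` for phases
#' `0, ..., K-2` and 1 for the top phase: these are invariant under
#' min-max normalization and place every plateau of the initialization
#' \eqn{\phi = K I_0} at an integer well strictly inside its half-integer
#' label band (the top plateau \eqn{\phi = K} clamps to label `K - 1`),
#' so a perfect segmentation of the noiseless phantom is representable.
#'
#' @param shape One of `"disk"` (concentric disks on background),
#'   `"stripes"` (K equal vertical stripes), `"checkerboard"` (K = 2),
#'   `"glyph"` (binary strokes, K = 2).
#' @param N Image side in pixels (default 256).
#' @param K Number of phases.
#' @param intensities Strictly increasing vector of K values in `[0, 1]`.
#' @param noise_sigma Additive Gaussian noise standard deviation (in
#'   intensity units); the noisy image is clipped back to `[0, 1]`.
#' @param seed RNG seed; required when `noise_sigma > 0`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c("disk", "stripes", "checkerboard", "glyph"),
                         N = 256L, K = 2L, intensities = NULL,
                         noise_sigma = 0, seed = NULL) {
  shape <- match.arg(shape)
  N <- as.integer(N); K <- as.integer(K)
  if (N < 4L) stop("N must be >= 4")
  if (K < 1L) stop("K must be >= 1")
  if (is.null(intensities)) intensities <- default_phantom_intensities(K)
  if (length(intensities) != K) stop("need exactly K intensities")
  if (K > 1L && any(diff(intensities) <= 0))
    stop("intensities must be strictly increasing")
  if (min(intensities) < 0 || max(intensities) > 1)
    stop("intensities must lie in [0, 1]")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  if (noise_sigma > 0 && is.null(seed))
    stop("a seed is required for noisy phantoms")
  structure(list(shape = shape, N = N, K = K, intensities = intensities,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

default_phantom_intensities <- function(K) {
  if (K == 1L) return(0.5)
  c(seq_len(K - 1L) - 1L, K) / K   # 0, 1/K, ..., (K-2)/K, 1
}

#' Generate a piecewise-constant phantom with ground truth
#'
#' Builds the label map for the requested shape, paints it with the
#' phantom intensities, optionally adds seeded Gaussian noise (clipped to
#' `[0, 1]` so min-max normalization remains a no-op), and returns both
#' the image and the truth labels.  The global RNG state is saved and
#' restored, so phantom generation never perturbs user code.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (an [image_field()]), `labels` (integer
#'   matrix, 0-based truth) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec("disk", N = 64, K = 2))
#' table(ph$labels)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  N <- spec$N; K <- spec$K
  lab <- switch(spec$shape,
    disk = phantom_disk_labels(N, K),
    stripes = {
      if (K > N) stop("stripes phantom cannot represent K > N phases")
      col <- matrix(rep(seq_len(N) - 1L, each = N), N, N)
      lab <- (col * K) %/% N
      lab[lab > K - 1L] <- K - 1L
      lab
    },
    checkerboard = {
      if (K != 2L) stop("checkerboard phantom requires K = 2")
      blk <- max(1L, N %/% 8L)
      idx <- function(v) ((v - 1L) %/% blk)
      outer(idx(seq_len(N)), idx(seq_len(N)), `+`) %% 2L
    },
    glyph = {
      if (K != 2L) stop("glyph phantom requires K = 2")
      glyph_labels(default_glyph_strokes(), N)
    }
  )
  storage.mode(lab) <- "integer"
  vals <- matrix(spec$intensities[lab + 1L], N, N)
  if (spec$noise_sigma > 0)
    vals <- add_clipped_noise(vals, spec$noise_sigma, spec$seed)
  list(image = image_field(vals, source_min = 0, source_max = 1),
       labels = lab, spec = spec)
}

# background phase 0 plus K-1 concentric disks; innermost = phase K-1
phantom_disk_labels <- function(N, K) {
  cc <- (seq_len(N) - 0.5) / N
  r <- sqrt(outer((cc - 0.5)^2, (cc - 0.5)^2, `+`))
  lab <- matrix(0L, N, N)
  if (K > 1L) {
    radii <- 0.35 * (K - seq_len(K - 1L)) / (K - 1L)   # decreasing
    for (k in seq_len(K - 1L)) lab[r < radii[k]] <- k
  }
  lab
}

#' Generate a binary glyph (OCR-style) phantom
#'
#' Rasterizes a list of axis-aligned rectangular strokes into a binary
#' foreground/background image with known mask, mimicking printed-character
#' test images.  Intensities are 0 (background) and 1 (strokes) before
#' noise.
#'
#' @param strokes List of numeric vectors `c(x0, x1, y0, y1)` in `[0, 1]`
#'   domain fractions; an empty list gives an all-background image.
#' @param N Image side in pixels.
#' @param noise_sigma,seed As in [phantom_spec()].
#' @return List with `image`, `labels` and `strokes`.
#' @export
generate_glyph <- function(strokes = default_glyph_strokes(), N = 256L,
                           noise_sigma = 0, seed = NULL) {
  N <- as.integer(N)
  if (noise_sigma > 0 && is.null(seed))
    stop("a seed is required for noisy phantoms")
  lab <- glyph_labels(strokes, N)
  vals <- lab * 1.0
  if (noise_sigma > 0) vals <- add_clipped_noise(vals, noise_sigma, seed)
  list(image = image_field(vals, source_min = 0, source_max = 1),
       labels = lab, strokes = strokes)
}

# blocky "H": two full-height vertical bars and a crossbar
default_glyph_strokes <- function() {
  list(c(0.20, 0.32, 0.15, 0.85),
       c(0.68, 0.80, 0.15, 0.85),
       c(0.32, 0.68, 0.44, 0.56))
}

glyph_labels <- function(strokes, N) {
  lab <- matrix(0L, N, N)
  xc <- (seq_len(N) - 0.5) / N   # column (x) centers
  yc <- (seq_len(N) - 0.5) / N   # row (y) centers
  for (s in strokes) {
    if (length(s) != 4L) stop("each stroke must be c(x0, x1, y0, y1)")
    ji <- which(xc >= s[1] & xc < s[2])
    ii <- which(yc >= s[3] & yc < s[4])
    lab[ii, ji] <- 1L
  }
  lab
}

add_clipped_noise <- function(vals, sigma, seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  noisy <- vals + stats::rnorm(length(vals), sd = sigma)
  pmin(pmax(noisy, 0), 1)
}

#' Pixel accuracy of predicted labels against ground truth
#'
#' @param pred,truth Integer label matrices of equal shape.
#' @return Fraction of matching cells in `[0, 1]`.
#' @export
label_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("label maps differ in shape")
  mean(pred == truth)
}
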