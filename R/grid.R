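#' Cell-centered uniform grid
#'
#' Describes the computational domain \eqn{\Omega = (a,b) \times (c,d)}
#' discretized into `nx` by `ny` square cells with mesh size
#' \eqn{h = (b-a)/N_x}; field values live at the cell centers
#' \eqn{x_i = a + (i - 1/2) h}, \eqn{y_j = c + (j - 1/2) h}.  The vertical
#' extent is derived from the common `h`, so pixels are always square.
#'
#' @param nx,ny Number of cells in x (columns) and y (rows).
#' @param a,b Horizontal domain limits; the default is the unit interval.
#' @param c0 Lower vertical limit (the upper one is `c0 + ny * h`).
#' @return A `grid_spec` object: a list with fields `a`, `b`, `c`, `d`,
#'   `nx`, `ny`, `h`.
#' @examples
#' g <- grid_spec(256)
#' g$h  # 1/256
#' @export
grid_spec <- function(nx, ny = nx, a = 0, b = 1, c0 = 0) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("grid dimensions must be positive")
  if (!is.finite(a) || !is.finite(b) || b <= a) stop("need finite b > a")
  h <- (b - a) / nx
  structure(
    list(a = a, b = b, c = c0, d = c0 + ny * h, nx = nx, ny = ny, h = h),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, h = %g, domain (%g,%g) x (%g,%g)\n",
              x$nx, x$ny, x$h, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with numeric vectors `x` (length `nx`) and `y` (length `ny`).
#' @export
cell_centers <- function(grid) {
  list(x = grid$a + (seq_len(grid$nx) - 0.5) * grid$h,
       y = grid$c + (seq_len(grid$ny) - 0.5) * grid$h)
}

#' Normalized image intensity on a grid
#'
#' Container for the normalized intensity \eqn{I_0 \in [0,1]} together with
#' its grid and the original intensity range.  Values are stored as an
#' `ny` x `nx` matrix (rows are image rows).
#'
#' @param values Numeric matrix of intensities in `[0, 1]`.
#' @param grid A [grid_spec()]; defaults to the unit-width domain matching
#'   the matrix dimensions.
#' @param source_min,source_max Intensity range of the raw image the values
#'   were normalized from.
#' @return An `image_field` object.
#' @seealso [normalize_intensity()]
#' @export
image_field <- function(values, grid = NULL,
                        source_min = min(values), source_max = max(values)) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("image values must be finite")
  if (is.null(grid)) grid <- grid_spec(nx = ncol(values), ny = nrow(values))
  check_grid_dims(values, grid)
  structure(list(values = values, grid = grid,
                 source_min = source_min, source_max = source_max),
            class = "image_field")
}

#' Scalar phase field on a grid
#'
#' The phase field \eqn{\phi} encodes segment membership through its
#' near-integer plateaus: cells with \eqn{\phi \approx k} belong to phase
#' `k`, and the half-integer level sets \eqn{\phi = k + 1/2} are the
#' contours separating adjacent phases.
#'
#' @param values Numeric `ny` x `nx` matrix of phase values.
#' @param K Number of phases (>= 1).
#' @param grid A [grid_spec()]; defaults to one matching the matrix.
#' @param time_index Time step index `n` of the discrete evolution.
#' @return A `phase_field` object.
#' @export
phase_field <- function(values, K, grid = NULL, time_index = 0L) {
  values <- as.matrix(values)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (!all(is.finite(values))) stop("phase values must be finite")
  if (is.null(grid)) grid <- grid_spec(nx = ncol(values), ny = nrow(values))
  check_grid_dims(values, grid)
  structure(list(values = values, K = K, grid = grid,
                 time_index = as.integer(time_index)),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %d x %d, K = %d, t-index = %d, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$K, x$time_index,
              min(x$values), max(x$values)))
  invisible(x)
}

check_grid_dims <- function(values, grid) {
  if (nrow(values) != grid$ny || ncol(values) != grid$nx)
    stop(sprintf("array is %d x %d but grid expects %d x %d",
                 nrow(values), ncol(values), grid$ny, grid$nx))
  invisible(TRUE)
}

same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (ga$nx != gb$nx || ga$ny != gb$ny || abs(ga$h - gb$h) > 1e-12)
    stop("objects are defined on different grids")
  invisible(TRUE)
}

# mirror (homogeneous Neumann) padding with `w` ghost layers on each side
pad_mirror <- function(M, w = 1L) {
  ny <- nrow(M); nx <- ncol(M)
  if (w >= ny || w >= nx) stop("padding width exceeds array size")
  ri <- c(w:1, 1:ny, ny:(ny - w + 1L))
  ci <- c(w:1, 1:nx, nx:(nx - w + 1L))
  M[ri, ci, drop = FALSE]
}
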