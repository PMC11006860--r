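#' Region means container
#'
#' Holds the sinc-squared weighted mean intensity \eqn{C_k} of each phase
#' together with the total weight (the denominator of the defining ratio)
#' and a degeneracy flag per phase.
#'
#' @param values Numeric vector of K region means.
#' @param weights_total Numeric vector of K nonnegative total weights.
#' @param degenerate Logical vector marking phases whose total weight fell
#'   below tolerance (their mean was replaced by the global image mean).
#' @return A `region_means` object.
#' @seealso [compute_region_means()]
#' @export
region_means <- function(values, weights_total = rep(NA_real_, length(values)),
                         degenerate = rep(FALSE, length(values))) {
  if (length(values) < 1L) stop("region_means: need K >= 1 values")
  if (!all(is.finite(values))) stop("region_means: values must be finite")
  structure(list(values = as.numeric(values),
                 weights_total = as.numeric(weights_total),
                 degenerate = as.logical(degenerate)),
            class = "region_means")
}

#' @export
print.region_means <- function(x, ...) {
  cat("<region_means> C_k =", paste(sprintf("%.4f", x$values), collapse = ", "))
  if (any(x$degenerate))
    cat("  [degenerate:", paste(which(x$degenerate) - 1L, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

#' Sinc-squared weighted region means
#'
#' Computes for every phase `k = 0, ..., K-1`
#' \deqn{C_k = \frac{\sum_x I_0(x)\,\mathrm{sinc}^2(\phi(x) - k)}
#'                  {\sum_x \mathrm{sinc}^2(\phi(x) - k)},}
#' the weighted least-squares optimal piecewise-constant fit value for
#' phase `k`.  Sums run over all cells (midpoint quadrature on the
#' cell-centered grid; the cell-area factor cancels in the ratio).  The
#' weights are soft: a cell contributes to phase `k` in proportion to how
#' close \eqn{\phi} is to the integer `k`, with zero weight at every other
#' integer.
#'
#' A phase whose denominator falls below `tol` is degenerate (no cell is
#' near its well); its mean is set to the global image mean with a warning
#' so that the flow remains well defined.
#'
#' @param phi A [phase_field()].
#' @param image An [image_field()] on the same grid.
#' @param K Number of phases; defaults to `phi$K`.
#' @param tol Degeneracy tolerance for the total weight.
#' @return A [region_means()] with `values`, `weights_total`, `degenerate`.
#' @export
compute_region_means <- function(phi, image, K = phi$K, tol = 1e-12) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  same_grid(phi, image)
  I0 <- image$values
  vals <- numeric(K)
  wtot <- numeric(K)
  degen <- logical(K)
  gmean <- mean(I0)
  for (k in seq_len(K) - 1L) {
    w <- sinc_sq(phi$values - k)
    wtot[k + 1L] <- sum(w)
    if (wtot[k + 1L] < tol) {
      degen[k + 1L] <- TRUE
      vals[k + 1L] <- gmean
    } else {
      vals[k + 1L] <- sum(I0 * w) / wtot[k + 1L]
    }
  }
  if (any(degen))
    warning("degenerate phase(s) ", paste(which(degen) - 1L, collapse = ", "),
            ": total sinc^2 weight below tolerance; using global mean")
  region_means(vals, wtot, degen)
}

#' Discrete segmentation energy
#'
#' Midpoint-rule discretization of the total energy
#' \deqn{E(\phi) = \int_\Omega \frac{BiC(\langle\phi\rangle)}{\varepsilon^2}
#'   + \frac{|\nabla\phi|^2}{2}
#'   + \frac{\lambda}{2}\sum_k (C_k - I_0)^2 \mathrm{sinc}^2(\phi - k)\,dx,}
#' i.e. `h^2` times the cell sum of potential, gradient and fitting
#' densities.  The gradient uses centered differences with mirrored
#' (homogeneous Neumann) ghost cells.
#'
#' @param phi A [phase_field()].
#' @param image An [image_field()] on the same grid.
#' @param means A [region_means()] for the current `phi`.
#' @param params A [solver_params()]; supplies `epsilon`, `lambda` and the
#'   potential mode.
#' @return A single finite number; nonnegative whenever the selected
#'   potential mode is nonnegative.
#' @export
discrete_energy <- function(phi, image, means, params) {
  same_grid(phi, image)
  h <- phi$grid$h
  eps <- resolve_epsilon(params, h)
  P <- phi$values
  pot <- bicubic_potential(frac_part(P), params$potential)
  Pp <- pad_mirror(P, 1L)
  ny <- nrow(P); nx <- ncol(P)
  ctr <- function(di, dj) Pp[(1:ny) + 1L + di, (1:nx) + 1L + dj, drop = FALSE]
  gx <- (ctr(0L, 1L) - ctr(0L, -1L)) / (2 * h)
  gy <- (ctr(1L, 0L) - ctr(-1L, 0L)) / (2 * h)
  fit <- P * 0
  if (params$lambda > 0) {
    C <- means$values
    for (k in seq_along(C) - 1L)
      fit <- fit + (C[k + 1L] - image$values)^2 * sinc_sq(P - k)
    fit <- 0.5 * params$lambda * fit
  }
  h^2 * sum(pot / eps^2 + 0.5 * (gx^2 + gy^2) + fit)
}
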