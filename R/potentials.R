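#' Potential configuration
#'
#' Selects which form of the piecewise-cubic ("bi-cubic spline") phase
#' transition potential is used and which derivative the solver applies.
#' The two selections are independent.
#'
#' Modes of the potential itself:
#' \describe{
#'   \item{`literal_eq2`}{The five-branch piecewise cubic exactly as the
#'     model states it, supported on `[-1, 1]`.  Note this form has a jump
#'     of `1/150` at `|u| = 1/2`; it is kept verbatim for fidelity.}
#'   \item{`rescaled_bspline`}{A continuity-repaired compressed cubic
#'     B-spline: `(4 - 24 u^2 + 24 |u|^3)/150` for `|u| <= 1/2` and
#'     `(2 - 2|u|)^3 / 150` for `1/2 < |u| <= 1`; continuous on the line.}
#'   \item{`double_well`}{The periodic quartic double well
#'     `0.25 <u>^2 (1 - <u>)^2`, where `<u>` is the fractional part.  This
#'     is the antiderivative of the cubic the solver's default derivative
#'     mode evaluates, so energy-decrease diagnostics are exact with it.}
#' }
#'
#' Derivative modes:
#' \describe{
#'   \item{`double_well_printed`}{The cubic `u^3 - (3/2) u^2 + u/2` applied
#'     to `<phi>` -- the form the discrete scheme actually computes.}
#'   \item{`literal_piecewise`}{The branchwise analytic derivative of the
#'     selected potential `mode`, evaluated at `<phi>`.}
#' }
#'
#' @param mode Potential form; see Details.
#' @param deriv_mode Derivative form used in the evolution equation.
#' @param epsilon Optional interface-energy coefficient \eqn{\varepsilon}
#'   carried along for convenience (solver parameters take precedence).
#' @return A `potential_spec` object.
#' @export
potential_spec <- function(mode = c("literal_eq2", "rescaled_bspline", "double_well"),
                           deriv_mode = c("double_well_printed", "literal_piecewise"),
                           epsilon = NULL) {
  mode <- match.arg(mode)
  deriv_mode <- match.arg(deriv_mode)
  if (!is.null(epsilon)) {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
        epsilon <= 0)
      stop("epsilon must be a positive finite scalar")
  }
  structure(list(mode = mode, deriv_mode = deriv_mode, epsilon = epsilon),
            class = "potential_spec")
}

#' Fractional part
#'
#' \eqn{\langle\phi\rangle = \phi - \lfloor\phi\rfloor}, the fractional part
#' with respect to the largest integer not greater than \eqn{\phi}.  The
#' multi-well potential acts on \eqn{\phi} only through this quantity, which
#' makes every integer level a well bottom.
#'
#' @param phi Numeric vector/matrix of finite values.
#' @return Values in `[0, 1)` with `phi == floor(phi) + frac_part(phi)`.
#' @examples
#' frac_part(c(1.5, -0.3, 2))  # 0.5, 0.7, 0
#' @export
frac_part <- function(phi) {
  if (!all(is.finite(phi))) stop("frac_part: input must be finite")
  phi - floor(phi)
}

#' Piecewise-cubic phase transition potential
#'
#' Evaluates the multi-well transition potential in the form selected by
#' `spec$mode` (see [potential_spec()]).  The argument is taken as-is: for
#' the `literal_eq2` and `rescaled_bspline` modes the support is
#' `[-1, 1]` with value 0 outside, while `double_well` first reduces its
#' argument to the fractional part.  Inside the solver the potential is
#' always composed with [frac_part()].
#'
#' @param u Numeric vector/matrix.
#' @param spec A [potential_spec()].
#' @return Potential values, same shape as `u`.
#' @examples
#' bicubic_potential(0, potential_spec("literal_eq2"))   # 4/150
#' bicubic_potential(1, potential_spec("literal_eq2"))   # 1/150
#' @export
bicubic_potential <- function(u, spec = potential_spec()) {
  if (!all(is.finite(u))) stop("bicubic_potential: input must be finite")
  switch(spec$mode,
    literal_eq2 = {
      out <- u * 0
      i <- u >= -1 & u <= -0.5
      out[i] <- (2 + u[i]^3) / 150
      i <- u > -0.5 & u <= 0
      out[i] <- (4 - 6 * u[i]^2 - 3 * u[i]^3) / 150
      i <- u > 0 & u <= 0.5
      out[i] <- (4 - 6 * u[i]^2 + 3 * u[i]^3) / 150
      i <- u > 0.5 & u <= 1
      out[i] <- (2 - u[i]^3) / 150
      out
    },
    rescaled_bspline = {
      a <- abs(u)
      out <- u * 0
      i <- a <= 0.5
      out[i] <- (4 - 24 * a[i]^2 + 24 * a[i]^3) / 150
      i <- a > 0.5 & a <= 1
      out[i] <- (2 - 2 * a[i])^3 / 150
      out
    },
    double_well = {
      v <- frac_part(u)
      0.25 * v^2 * (1 - v)^2
    },
    stop("unknown potential mode: ", spec$mode)
  )
}

#' Derivative of the transition potential
#'
#' The force the evolution equation derives from the multi-well potential,
#' always evaluated at the fractional part \eqn{\langle\phi\rangle}.  The
#' default `double_well_printed` mode is the cubic
#' \eqn{u^3 - \tfrac32 u^2 + \tfrac12 u}, i.e. the analytic derivative of
#' the quartic well \eqn{\tfrac14 u^2 (1-u)^2}; `literal_piecewise`
#' differentiates the branches of the potential selected by `spec$mode`.
#'
#' @param phi Numeric vector/matrix of finite phase values (any range; the
#'   fractional part is taken internally).
#' @param spec A [potential_spec()].
#' @return Derivative values, same shape as `phi`.
#' @examples
#' bicubic_deriv(c(0, 0.5, 1.5))          # all roots: 0
#' bicubic_deriv(0.25)                    # 0.046875
#' @export
bicubic_deriv <- function(phi, spec = potential_spec()) {
  if (!all(is.finite(phi))) stop("bicubic_deriv: input must be finite")
  v <- frac_part(phi)
  if (spec$deriv_mode == "double_well_printed")
    return(v^3 - 1.5 * v^2 + 0.5 * v)
  # literal_piecewise: branch derivative of the selected mode on [0, 1)
  switch(spec$mode,
    literal_eq2 = {
      out <- v * 0
      i <- v > 0 & v <= 0.5
      out[i] <- (-12 * v[i] + 9 * v[i]^2) / 150
      i <- v > 0.5
      out[i] <- (-3 * v[i]^2) / 150
      out
    },
    rescaled_bspline = {
      out <- v * 0
      i <- v > 0 & v <= 0.5
      out[i] <- (-48 * v[i] + 72 * v[i]^2) / 150
      i <- v > 0.5
      out[i] <- -6 * (2 - 2 * v[i])^2 / 150
      out
    },
    double_well = 0.5 * v * (1 - v) * (1 - 2 * v),
    stop("unknown potential mode: ", spec$mode)
  )
}

#' Normalized sinc function
#'
#' \eqn{\mathrm{sinc}(u) = \sin(\pi u) / (\pi u)} with the removable
#' singularity filled in: arguments smaller than `1e-8` in magnitude return
#' the limit value 1.
#'
#' @param u Numeric vector/matrix of finite values.
#' @return Values in `[-1, 1]`; exactly 0 at nonzero integers.
#' @export
sinc <- function(u) {
  if (!all(is.finite(u))) stop("sinc: input must be finite")
  small <- abs(u) < 1e-8
  out <- u
  out[small] <- 1
  us <- u[!small]
  out[!small] <- sin(pi * us) / (pi * us)
  out
}

#' Squared sinc
#'
#' Convenience wrapper `sinc(u)^2`, the soft region-membership weight of
#' phase `k` when evaluated at `phi - k`.
#'
#' @inheritParams sinc
#' @return Values in `[0, 1]`.
#' @export
sinc_sq <- function(u) sinc(u)^2

#' Derivative of squared sinc
#'
#' \eqn{\frac{d}{du}\,\mathrm{sinc}^2(u) =
#' \sin(2\pi u)/(\pi u^2) - 2\sin^2(\pi u)/(\pi^2 u^3)}.  Arguments smaller
#' than `1e-8` in magnitude return 0, the removable limit at the critical
#' point of \eqn{\mathrm{sinc}^2} at the origin.
#'
#' @inheritParams sinc
#' @return Derivative values; 0 at every integer.
#' @export
sinc_sq_deriv <- function(u) {
  if (!all(is.finite(u))) stop("sinc_sq_deriv: input must be finite")
  small <- abs(u) < 1e-8
  out <- u * 0
  us <- u[!small]
  out[!small] <- sin(2 * pi * us) / (pi * us^2) -
    2 * sin(pi * us)^2 / (pi^2 * us^3)
  out
}

#' Region-fitting force
#'
#' The data-fidelity term of the gradient descent flow:
#' \deqn{\lambda \sum_{k=0}^{K-1} (C_k - I_0)^2 \,
#'       \frac{d}{du}\mathrm{sinc}^2(u)\Big|_{u = \phi - k},}
#' which pulls \eqn{\phi} toward the wells whose fitted mean \eqn{C_k} best
#' matches the local intensity.
#'
#' @param phi Numeric vector/matrix of phase values.
#' @param means A [region_means()] object (or list with a `values` vector).
#' @param I0 Normalized intensity, same shape as `phi` (or scalar).
#' @param lambda Nonnegative fidelity weight \eqn{\lambda}.
#' @return Force values, same shape as `phi`.
#' @export
fitting_force <- function(phi, means, I0, lambda) {
  C <- means$values
  K <- length(C)
  if (K == 0L) stop("fitting_force: region means are empty (K = 0)")
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("lambda must be a nonnegative finite scalar")
  if (lambda == 0) return(phi * 0)
  out <- phi * 0
  for (k in seq_len(K) - 1L)
    out <- out + (C[k + 1L] - I0)^2 * sinc_sq_deriv(phi - k)
  lambda * out
}
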