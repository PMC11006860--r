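#' Solver parameters
#'
#' Collects every knob of the discrete evolution.  When `epsilon` is left
#' `NULL` it is derived from the grid at run time as
#' \eqn{\varepsilon_m = h m / \alpha} with
#' \eqn{\alpha = 4\sqrt{2}\,\mathrm{tanh}^{-1}(\rho)}, which makes the
#' equilibrium interface profile span about `m` grid cells at interfacial
#' concentration rate `rho` (see [epsilon_m()]).
#'
#' @param K Number of phases (>= 1).
#' @param epsilon Interface-energy coefficient \eqn{\varepsilon}; `NULL`
#'   (default) means derive \eqn{\varepsilon_m} from the grid.
#' @param m Subgrid points per cell and interface-width multiple (>= 1;
#'   the subgrid refinement itself requires `m >= 2`).
#' @param rho Interfacial concentration rate in (0, 1); default 0.9.
#' @param lambda Nonnegative data-fidelity weight \eqn{\lambda}.
#' @param dt Time step \eqn{\Delta t}; default `5e-6`.
#' @param n_steps Number of time steps; default 10.
#' @param scheme Time discretization: explicit forward Euler (default) or
#'   the three-level leapfrog-style scheme with the potential term split
#'   across the outer levels.  The leapfrog variant is provided for
#'   fidelity to the scheme the method states, but leapfrog is a known
#'   poor match for parabolic terms and its implicit potential part is
#'   solved by fixed-point iteration that requires
#'   `dt * max|BiC''| / epsilon^2 < 1` to contract.
#' @param subgrid_enabled Refine the potential force on interface cells by
#'   bicubic interpolation through cell centers (default `TRUE`).
#' @param update_means Recompute the region means \eqn{C_k} before every
#'   step (default) or freeze them at their initial values.
#' @param potential A [potential_spec()].
#' @return A `solver_params` object.
#' @export
solver_params <- function(K = 2L, epsilon = NULL, m = 2L, rho = 0.9,
                          lambda = 10, dt = 5e-6, n_steps = 10L,
                          scheme = c("forward_euler", "leapfrog"),
                          subgrid_enabled = TRUE, update_means = TRUE,
                          potential = potential_spec()) {
  scheme <- match.arg(scheme)
  K <- as.integer(K); m <- as.integer(m); n_steps <- as.integer(n_steps)
  if (K < 1L) stop("K must be >= 1")
  if (m < 1L) stop("m must be >= 1")
  if (!is.finite(rho) || rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (n_steps < 0L) stop("n_steps must be >= 0")
  if (!is.null(epsilon) &&
      (!is.numeric(epsilon) || !is.finite(epsilon) || epsilon <= 0))
    stop("epsilon must be positive")
  if (!inherits(potential, "potential_spec"))
    stop("potential must be a potential_spec")
  structure(list(K = K, epsilon = epsilon, m = m, rho = rho, lambda = lambda,
                 dt = dt, n_steps = n_steps, scheme = scheme,
                 subgrid_enabled = isTRUE(subgrid_enabled),
                 update_means = isTRUE(update_means), potential = potential),
            class = "solver_params")
}

resolve_epsilon <- function(params, h) {
  if (!is.null(params$epsilon)) params$epsilon
  else epsilon_m(params$m, h, params$rho)
}

#' Grid-scaled interface coefficient
#'
#' \deqn{\varepsilon_m = \frac{h\,m}{4\sqrt{2}\,\mathrm{tanh}^{-1}(\rho)}.}
#' With this choice the equilibrium tanh-type transition profile reaches
#' concentration `rho` within about `m` grid cells, tying the interface
#' width to the mesh.
#'
#' @param m Number of grid points spanned by the interface (>= 1).
#' @param h Uniform mesh size (> 0).
#' @param rho Interfacial concentration rate in (0, 1).
#' @return \eqn{\varepsilon_m > 0}; linear in `m` and `h`, decreasing in
#'   `rho`.
#' @examples
#' epsilon_m(2, 1 / 256)  # ~9.38e-4
#' @export
epsilon_m <- function(m, h, rho = 0.9) {
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  if (!is.finite(rho) || rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  h * m / (4 * sqrt(2) * atanh(rho))
}

#' Five-point Laplacian with mirrored boundary
#'
#' \eqn{\Delta_d\phi = (\phi_E + \phi_W + \phi_N + \phi_S - 4\phi_C)/h^2}
#' with mirrored ghost cells (homogeneous Neumann), so the discrete mean is
#' conserved: the result sums to zero up to round-off.
#'
#' @param phi A [phase_field()] or a numeric matrix.
#' @param h Mesh size; taken from the grid when `phi` is a phase field.
#' @return Numeric matrix of the same shape.
#' @export
laplacian <- function(phi, h = NULL) {
  if (inherits(phi, "phase_field")) {
    h <- phi$grid$h
    M <- phi$values
  } else {
    if (is.null(h)) stop("h required when phi is a bare matrix")
    M <- as.matrix(phi)
  }
  ny <- nrow(M); nx <- ncol(M)
  Mp <- pad_mirror(M, 1L)
  (Mp[1:ny, (1:nx) + 1L] + Mp[(1:ny) + 2L, (1:nx) + 1L] +
     Mp[(1:ny) + 1L, 1:nx] + Mp[(1:ny) + 1L, (1:nx) + 2L] - 4 * M) / h^2
}

# shared right-hand side pieces: Laplacian and fitting force at phi^n
rhs_explicit <- function(phi, image, means, params) {
  laplacian(phi) - fitting_force(phi$values, means, image$values, params$lambda)
}

#' One forward-Euler step of the gradient descent flow
#'
#' \deqn{\phi^{n+1} = \phi^n + \Delta t\left[
#'   -\frac{BiC'(\langle\phi^n\rangle)}{\varepsilon^2} + \Delta_d\phi^n
#'   - \lambda\sum_k (C_k - I_0)^2\,(\mathrm{sinc}^2)'(\phi^n - k)\right].}
#'
#' @param phi A [phase_field()] at time `n`.
#' @param image The [image_field()] being segmented.
#' @param means Current [region_means()].
#' @param params A [solver_params()].
#' @param pot_deriv Optional precomputed potential-derivative field (e.g.
#'   the subgrid-refined one from [subgrid_refined_force()]); defaults to
#'   the pointwise [bicubic_deriv()] of `phi`.
#' @return The [phase_field()] at time `n + 1`.
#' @export
step_forward_euler <- function(phi, image, means, params, pot_deriv = NULL) {
  same_grid(phi, image)
  eps <- resolve_epsilon(params, phi$grid$h)
  if (is.null(pot_deriv)) pot_deriv <- bicubic_deriv(phi$values, params$potential)
  upd <- params$dt * (-pot_deriv / eps^2 + rhs_explicit(phi, image, means, params))
  new <- phi$values + upd
  if (!all(is.finite(new)))
    stop(sprintf("forward Euler step produced non-finite values (max |update| = %g)",
                 max(abs(upd[is.finite(upd)]), 0)))
  phase_field(new, phi$K, phi$grid, phi$time_index + 1L)
}

#' One step of the three-level leapfrog-style scheme
#'
#' Advances the relation
#' \deqn{\frac{\phi^{n+1} - \phi^{n-1}}{2\Delta t} =
#'   -\frac{BiC'(\langle\phi^{n+1}\rangle) + BiC'(\langle\phi^{n-1}\rangle)}
#'         {2\varepsilon^2} + \Delta_d\phi^n - F(\phi^n),}
#' where `F` is the fitting force.  The implicit dependence on
#' \eqn{\phi^{n+1}} through the potential derivative is resolved by lagged
#' (Picard) fixed-point iteration initialized at \eqn{\phi^n}.  The first
#' step of an evolution is bootstrapped with one forward-Euler step since
#' no \eqn{\phi^{n-1}} exists yet.
#'
#' @param phi_prev [phase_field()] at time `n - 1`.
#' @param phi_curr [phase_field()] at time `n`.
#' @inheritParams step_forward_euler
#' @param max_iters,tol Fixed-point iteration controls (max-norm increment
#'   tolerance).
#' @param pot_deriv_prev Optional precomputed potential-derivative field
#'   for `phi_prev`.
#' @return The [phase_field()] at time `n + 1`; on convergence the residual
#'   of the defining relation is below `tol` per cell.
#' @export
step_leapfrog <- function(phi_prev, phi_curr, image, means, params,
                          max_iters = 50L, tol = 1e-10,
                          pot_deriv_prev = NULL) {
  same_grid(phi_curr, image)
  same_grid(phi_prev, phi_curr)
  eps <- resolve_epsilon(params, phi_curr$grid$h)
  dt <- params$dt
  if (is.null(pot_deriv_prev))
    pot_deriv_prev <- bicubic_deriv(phi_prev$values, params$potential)
  expl <- rhs_explicit(phi_curr, image, means, params)
  base <- phi_prev$values + 2 * dt * (expl - pot_deriv_prev / (2 * eps^2))
  x <- phi_curr$values
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    xn <- base - (dt / eps^2) * bicubic_deriv(x, params$potential)
    if (!all(is.finite(xn)))
      stop("leapfrog step produced non-finite values during fixed-point iteration")
    if (max(abs(xn - x)) < tol) { x <- xn; converged <- TRUE; break }
    x <- xn
  }
  if (!converged) {
    res <- max(abs(base - (dt / eps^2) * bicubic_deriv(x, params$potential) - x))
    stop(sprintf(paste0("leapfrog fixed-point iteration did not converge in %d ",
                        "iterations (residual max-norm %g); reduce dt or ",
                        "increase epsilon"), max_iters, res))
  }
  phase_field(x, phi_curr$K, phi_curr$grid, phi_curr$time_index + 1L)
}

#' Interface (boundary) cell detector
#'
#' Flags every cell separated from one of its 4-neighbors by a half-integer
#' level `k + 1/2` (`k = 0, ..., K-1`), i.e. the cells the phase contours
#' pass between.  These are the cells the subgrid refinement targets.
#'
#' @param phi A [phase_field()].
#' @param K Number of phases; defaults to `phi$K`.
#' @return Logical matrix, `TRUE` on interface cells.
#' @export
detect_boundary_cells <- function(phi, K = phi$K) {
  M <- phi$values
  ny <- nrow(M); nx <- ncol(M)
  mask <- matrix(FALSE, ny, nx)
  for (k in seq_len(K) - 1L) {
    S <- M - (k + 0.5)
    if (nx > 1L) {
      ph <- S[, 1:(nx - 1L), drop = FALSE] * S[, 2:nx, drop = FALSE] < 0
      mask[, 1:(nx - 1L)] <- mask[, 1:(nx - 1L)] | ph
      mask[, 2:nx] <- mask[, 2:nx] | ph
    }
    if (ny > 1L) {
      pv <- S[1:(ny - 1L), , drop = FALSE] * S[2:ny, , drop = FALSE] < 0
      mask[1:(ny - 1L), ] <- mask[1:(ny - 1L), ] | pv
      mask[2:ny, ] <- mask[2:ny, ] | pv
    }
  }
  mask
}

# Catmull-Rom (through-point cubic) interpolation of M shifted by fraction
# t in (-1, 1) of a cell along rows (axis = 1) or columns (axis = 2),
# with 2 mirrored ghost layers.
cr_shift <- function(M, t, axis) {
  j0 <- floor(t)
  s <- t - j0
  w <- 0.5 * c(-s^3 + 2 * s^2 - s,
               3 * s^3 - 5 * s^2 + 2,
               -3 * s^3 + 4 * s^2 + s,
               s^3 - s^2)
  ny <- nrow(M); nx <- ncol(M)
  Mp <- pad_mirror(M, 2L)
  out <- M * 0
  for (q in 0:3) {
    off <- j0 - 1L + q   # offset relative to the cell, in cells
    if (axis == 1L)
      out <- out + w[q + 1] * Mp[(1:ny) + 2L + off, (1:nx) + 2L, drop = FALSE]
    else
      out <- out + w[q + 1] * Mp[(1:ny) + 2L, (1:nx) + 2L + off, drop = FALSE]
  }
  out
}

# phi interpolated at all m x m subcell centers: list of m^2 matrices
subcell_fields <- function(M, m) {
  offs <- (2 * seq_len(m) - m - 1) / (2 * m)   # subcell-center offsets, cell units
  out <- vector("list", m * m)
  idx <- 1L
  for (ty in offs) {
    row_shifted <- cr_shift(M, ty, axis = 1L)
    for (tx in offs) {
      out[[idx]] <- cr_shift(row_shifted, tx, axis = 2L)
      idx <- idx + 1L
    }
  }
  out
}

#' Subgrid-refined potential force
#'
#' Evaluates the potential-derivative field.  On cells flagged by `mask`
#' the phase field is first refined to an `m x m` subcell grid by bicubic
#' (Catmull-Rom through-point) interpolation through the cell centers, the
#' derivative is evaluated on every subcell and averaged back to the cell;
#' on unmasked cells the result is identical (bitwise) to the pointwise
#' [bicubic_deriv()].  This resolves the stiff potential term more
#' accurately across phase interfaces.
#'
#' @param phi A [phase_field()].
#' @param mask Logical matrix from [detect_boundary_cells()] (or any mask).
#' @param params A [solver_params()] with `m >= 2`.
#' @return Numeric matrix of potential-derivative values.
#' @export
subgrid_refined_force <- function(phi, mask, params) {
  if (params$m < 2L)
    stop("subgrid refinement requires m >= 2")
  M <- phi$values
  base <- bicubic_deriv(M, params$potential)
  if (!any(mask)) return(base)
  sub <- subcell_fields(M, params$m)
  acc <- M * 0
  for (S in sub) acc <- acc + bicubic_deriv(S, params$potential)
  refined <- acc / length(sub)
  base[mask] <- refined[mask]
  base
}

#' Evolve a phase field to segment an image
#'
#' Runs the full discrete evolution: initializes \eqn{\phi = K I_0},
#' then for each of `n_steps` steps recomputes the region means \eqn{C_k}
#' (unless frozen), evaluates the potential force (subgrid-refined on
#' interface cells when enabled) and advances one step of the selected
#' scheme.  The energy and the region means are recorded at every step.
#'
#' @param image An [image_field()] with values in `[0, 1]` (see
#'   [normalize_intensity()]).
#' @param params A [solver_params()].
#' @return A `segmentation_result`: list with `phi_final`, `labels` (0 to
#'   K-1), `masks` (list of K logical matrices), `contour_levels`,
#'   `energy_trace` (length `n_steps + 1`), `means_trace`
#'   (`(n_steps + 1) x K` matrix) and the resolved `params`.
#' @export
evolve <- function(image, params) {
  if (min(image$values) < 0 || max(image$values) > 1)
    stop("image must be normalized to [0, 1]; see normalize_intensity()")
  K <- params$K
  h <- image$grid$h
  params$epsilon <- resolve_epsilon(params, h)
  if (params$dt > h^2 / 4)
    warning(sprintf("dt = %g exceeds the explicit diffusion limit h^2/4 = %g",
                    params$dt, h^2 / 4))
  phi <- init_phase(image, K)
  means <- compute_region_means(phi, image, K)
  energy <- numeric(params$n_steps + 1L)
  means_trace <- matrix(NA_real_, params$n_steps + 1L, K)
  energy[1L] <- discrete_energy(phi, image, means, params)
  means_trace[1L, ] <- means$values
  phi_prev <- NULL
  if (params$n_steps > 0L) for (n in seq_len(params$n_steps)) {
    if (params$update_means && n > 1L)
      means <- compute_region_means(phi, image, K)
    pd <- if (params$subgrid_enabled) {
      subgrid_refined_force(phi, detect_boundary_cells(phi, K), params)
    } else NULL
    if (params$scheme == "forward_euler" || is.null(phi_prev)) {
      phi_new <- step_forward_euler(phi, image, means, params, pot_deriv = pd)
    } else {
      pd_prev <- if (params$subgrid_enabled) {
        subgrid_refined_force(phi_prev, detect_boundary_cells(phi_prev, K), params)
      } else NULL
      phi_new <- step_leapfrog(phi_prev, phi, image, means, params,
                                     pot_deriv_prev = pd_prev)
    }
    phi_prev <- phi
    phi <- phi_new
    energy[n + 1L] <- discrete_energy(phi, image, means, params)
    means_trace[n + 1L, ] <- means$values
  }
  ext <- extract_phases(phi, K)
  structure(list(phi_final = phi, labels = ext$labels, masks = ext$masks,
                 contour_levels = ext$contour_levels, energy_trace = energy,
                 means_trace = means_trace, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  n <- length(x$energy_trace)
  cat(sprintf("<segmentation_result> K = %d, %d x %d, %d step(s)\n",
              x$params$K, nrow(x$labels), ncol(x$labels), n - 1L))
  cat(sprintf("  energy: %.6g -> %.6g\n", x$energy_trace[1], x$energy_trace[n]))
  sizes <- vapply(x$masks, sum, numeric(1))
  cat("  phase sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
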