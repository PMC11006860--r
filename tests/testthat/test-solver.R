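test_that("epsilon_m follows the interface-width formula", {
  expect_equal(epsilon_m(2, 1 / 256, 0.9), (2 / 256) / (4 * sqrt(2) * atanh(0.9)))
  expect_equal(epsilon_m(2, 1 / 256, 0.9), 9.3809e-4, tolerance = 1e-4)
  expect_equal(epsilon_m(1, 1, 0.9), 1 / (4 * sqrt(2) * atanh(0.9)))
  expect_equal(epsilon_m(1, 1, 0.9), 0.1201, tolerance = 1e-3)
  expect_equal(epsilon_m(2, 0.3, 0.7), 2 * epsilon_m(1, 0.3, 0.7))
  expect_gt(epsilon_m(2, 1, 0.5), epsilon_m(2, 1, 0.9))
  expect_error(epsilon_m(2, 1, 1.2), "rho")
  expect_error(epsilon_m(2, 1, 0), "rho")
})

test_that("laplacian annihilates constants and linears and matches the stencil oracle", {
  g <- grid_spec(8)
  expect_equal(laplacian(phase_field(matrix(3.2, 8, 8), 2, g)), matrix(0, 8, 8))
  lin <- outer(rep(1, 8), (1:8 - 0.5) * g$h)
  L <- laplacian(lin, h = g$h)
  expect_equal(L[, 2:7], matrix(0, 8, 6), tolerance = 1e-9)
  set.seed(31)
  M <- matrix(rnorm(64), 8, 8)
  expect_equal(laplacian(M, h = g$h), oracle_laplacian(M, g$h), tolerance = 1e-12)
  # mirrored ghosts conserve the mean
  expect_lt(abs(sum(laplacian(M, h = g$h))) * g$h^2, 1e-10 * 64)
})

test_that("forward Euler step reproduces a hand-computed update and fixed points", {
  g <- grid_spec(4)
  img <- image_field(matrix(0.5, 4, 4), g)
  rm <- region_means(c(0.2, 0.9))
  pr <- solver_params(K = 2, epsilon = 0.07, lambda = 3, dt = 1e-4,
                      subgrid_enabled = FALSE)
  set.seed(32)
  phiM <- matrix(runif(16, 0, 2), 4, 4)
  phi <- phase_field(phiM, K = 2, g)
  out <- step_forward_euler(phi, img, rm, pr)
  # scalar-arithmetic oracle at one interior cell
  i <- 2; j <- 3
  lap <- (phiM[1, 3] + phiM[3, 3] + phiM[2, 2] + phiM[2, 4] - 4 * phiM[2, 3]) / g$h^2
  ff <- 3 * ((0.2 - 0.5)^2 * sinc_sq_deriv(phiM[i, j]) +
               (0.9 - 0.5)^2 * sinc_sq_deriv(phiM[i, j] - 1))
  expected <- phiM[i, j] + 1e-4 * (-dw_deriv(phiM[i, j]) / 0.07^2 + lap - ff)
  expect_equal(out$values[i, j], expected, tolerance = 1e-12)
  expect_equal(out$time_index, 1L)
  # well bottom with lambda = 0 is an exact fixed point
  pr0 <- solver_params(K = 2, epsilon = 0.07, lambda = 0, dt = 1e-4)
  flat <- phase_field(matrix(1, 4, 4), 2, g)
  expect_identical(step_forward_euler(flat, img, rm, pr0)$values, flat$values)
  # half-integer flat field is a fixed point too (saddle of the well)
  half <- phase_field(matrix(0.5, 4, 4), 2, g)
  expect_equal(step_forward_euler(half, img, rm, pr0)$values, half$values)
  # a vanishingly small step leaves the field unchanged
  pr_tiny <- solver_params(K = 2, epsilon = 0.07, lambda = 3, dt = 1e-300)
  expect_equal(step_forward_euler(phi, img, rm, pr_tiny)$values, phiM)
})

test_that("leapfrog step satisfies the printed three-level relation", {
  set.seed(33)
  g <- grid_spec(4)
  img <- image_field(matrix(runif(16), 4, 4), g)
  pr <- solver_params(K = 2, epsilon = 0.1, lambda = 2, dt = 1e-5,
                      subgrid_enabled = FALSE)
  phi0 <- phase_field(matrix(runif(16, 0, 2), 4, 4), 2, g)
  rm <- compute_region_means(phi0, img)
  phi1 <- step_forward_euler(phi0, img, rm, pr)
  phi2 <- step_leapfrog(phi0, phi1, img, rm, pr)
  # residual oracle: independent re-evaluation of the defining relation
  lhs <- (phi2$values - phi0$values) / (2 * pr$dt)
  rhs <- -(dw_deriv(phi2$values) + dw_deriv(phi0$values)) / (2 * 0.1^2) +
    oracle_laplacian(phi1$values, g$h) -
    fitting_force(phi1$values, rm, img$values, 2)
  expect_lt(max(abs(lhs - rhs)), 1e-5)   # residual scaled by 1/(2 dt)
  expect_lt(max(abs((phi2$values - phi0$values) - 2 * pr$dt * rhs)), 1e-9)
  # stationary well-bottom input is an exact fixed point
  pr0 <- solver_params(K = 2, epsilon = 0.1, lambda = 0, dt = 1e-5)
  flat <- phase_field(matrix(1, 4, 4), 2, g)
  out <- step_leapfrog(flat, flat, img, rm, pr0)
  expect_equal(out$values, flat$values)
  # divergence of the fixed-point iteration is reported, not silent
  pr_bad <- solver_params(K = 2, epsilon = 1e-4, lambda = 0, dt = 1e-4)
  expect_error(step_leapfrog(phi0, phi1, img, rm, pr_bad), "converge")
})

test_that("interface cells are detected exactly where half-integer levels are crossed", {
  g <- grid_spec(8)
  expect_false(any(detect_boundary_cells(phase_field(matrix(0.2, 8, 8), 2, g))))
  # vertical step 0 -> 1 between columns 4 and 5
  M <- matrix(0, 8, 8); M[, 5:8] <- 1
  mask <- detect_boundary_cells(phase_field(M, 2, g))
  expect_true(all(mask[, 4:5]))
  expect_false(any(mask[, c(1:3, 6:8)]))
  # checkerboard of 0/1 crosses 0.5 everywhere
  cb <- outer(1:8, 1:8, `+`) %% 2
  expect_true(all(detect_boundary_cells(phase_field(cb, 2, g))))
  set.seed(34)
  R <- matrix(runif(64, 0, 3), 8, 8)
  expect_equal(detect_boundary_cells(phase_field(R, 3, g)), oracle_boundary(R, 3))
})

test_that("subgrid refinement is neutral off the mask and matches the interpolation oracle", {
  set.seed(35)
  g <- grid_spec(8)
  M <- matrix(runif(64, 0, 2), 8, 8)
  phi <- phase_field(M, 2, g)
  pr <- solver_params(K = 2, m = 2)
  # all-false mask: bit-identical to the pointwise derivative field
  off <- subgrid_refined_force(phi, matrix(FALSE, 8, 8), pr)
  expect_identical(off, bicubic_deriv(M, pr$potential))
  # full mask, m = 2: brute-force subcell interpolation + average oracle
  on <- subgrid_refined_force(phi, matrix(TRUE, 8, 8), pr)
  expect_equal(on, oracle_subgrid(M, 2, dw_deriv), tolerance = 1e-10)
  # constant field: interpolant is constant, refinement changes nothing
  cst <- phase_field(matrix(0.3, 8, 8), 2, g)
  expect_equal(subgrid_refined_force(cst, matrix(TRUE, 8, 8), pr),
               bicubic_deriv(matrix(0.3, 8, 8)))
  # m >= 2 required
  pr1 <- solver_params(K = 2, m = 1)
  expect_error(subgrid_refined_force(phi, matrix(TRUE, 8, 8), pr1), "m >= 2")
  # the interpolant itself reproduces linear fields at subcell points
  lin <- outer((1:8), (1:8), function(i, j) 0.2 * i - 0.1 * j)
  sub <- phaseseg:::subcell_fields(lin, 2)
  offs <- c(-0.25, 0.25)
  idx <- 1
  for (ty in offs) for (tx in offs) {
    exact <- outer((1:8) + ty, (1:8) + tx, function(i, j) 0.2 * i - 0.1 * j)
    expect_lt(max(abs(sub[[idx]][3:6, 3:6] - exact[3:6, 3:6])), 1e-8)
    idx <- idx + 1
  }
})

test_that("evolution recovers a noiseless two-plateau image and records traces", {
  ph <- generate_phantom(phantom_spec("stripes", N = 64, K = 2))
  pr <- solver_params(K = 2, dt = 2e-6, n_steps = 10)
  res <- suppressWarnings(evolve(ph$image, pr))
  expect_gte(label_accuracy(res$labels, ph$labels), 0.99)
  expect_length(res$energy_trace, 11)
  expect_equal(dim(res$means_trace), c(11, 2))
  # no evolution: phi stays K * I0 and labels are the banded initialization
  pr0 <- solver_params(K = 2, dt = 2e-6, n_steps = 0)
  res0 <- suppressWarnings(evolve(ph$image, pr0))
  expect_equal(res0$phi_final$values, 2 * ph$image$values)
  expect_equal(res0$labels, extract_phases(res0$phi_final)$labels)
})

test_that("frozen-means gradient flow decreases the energy along the evolution", {
  set.seed(36)
  raw <- matrix(runif(32 * 32), 32, 32)
  img <- normalize_intensity(raw)
  pr <- solver_params(K = 2, dt = 1e-6, n_steps = 20, update_means = FALSE,
                      subgrid_enabled = FALSE,
                      potential = potential_spec("double_well"))
  res <- evolve(img, pr)
  expect_true(all(diff(res$energy_trace) <= 1e-12))
})

test_that("a time step past the diffusion limit triggers the stability warning", {
  ph <- generate_phantom(phantom_spec("stripes", N = 64, K = 2))
  pr <- solver_params(K = 2, dt = 1e-3, n_steps = 1)
  w <- capture_warnings(evolve(ph$image, pr))
  expect_match(w, "diffusion limit", all = FALSE)
})
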