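# Independent brute-force oracles used across the suite.  These re-derive
# each quantity from its definition with plain loops and must stay free of
# the package's own vectorized code paths.

# five-branch piecewise cubic, re-evaluated scalar-by-scalar
oracle_literal_eq2 <- function(u) {
  vapply(u, function(x) {
    if (x >= -1 && x <= -0.5) (2 + x^3) / 150
    else if (x > -0.5 && x <= 0) (4 - 6 * x^2 - 3 * x^3) / 150
    else if (x > 0 && x <= 0.5) (4 - 6 * x^2 + 3 * x^3) / 150
    else if (x > 0.5 && x <= 1) (2 - x^3) / 150
    else 0
  }, numeric(1))
}

# five-point Laplacian with mirrored ghost cells, explicit double loop
oracle_laplacian <- function(M, h) {
  ny <- nrow(M); nx <- ncol(M)
  at <- function(i, j) {
    ii <- if (i < 1L) 1L else if (i > ny) ny else i
    jj <- if (j < 1L) 1L else if (j > nx) nx else j
    M[ii, jj]
  }
  out <- M
  for (i in 1:ny) for (j in 1:nx)
    out[i, j] <- (at(i - 1L, j) + at(i + 1L, j) + at(i, j - 1L) +
                    at(i, j + 1L) - 4 * M[i, j]) / h^2
  out
}

# discrete energy by cell-by-cell summation
oracle_energy <- function(phiM, I0, C, h, eps, lambda, potfun) {
  ny <- nrow(phiM); nx <- ncol(phiM)
  at <- function(i, j) {
    ii <- if (i < 1L) 1L else if (i > ny) ny else i
    jj <- if (j < 1L) 1L else if (j > nx) nx else j
    phiM[ii, jj]
  }
  ssq <- function(u) if (abs(u) < 1e-8) 1 else (sin(pi * u) / (pi * u))^2
  tot <- 0
  for (i in 1:ny) for (j in 1:nx) {
    p <- phiM[i, j]
    gx <- (at(i, j + 1L) - at(i, j - 1L)) / (2 * h)
    gy <- (at(i + 1L, j) - at(i - 1L, j)) / (2 * h)
    fit <- 0
    for (k in seq_along(C) - 1L)
      fit <- fit + (C[k + 1L] - I0[i, j])^2 * ssq(p - k)
    tot <- tot + potfun(p - floor(p)) / eps^2 + 0.5 * (gx^2 + gy^2) +
      0.5 * lambda * fit
  }
  h^2 * tot
}

# interface cells by per-cell neighbor scan
oracle_boundary <- function(M, K) {
  ny <- nrow(M); nx <- ncol(M)
  out <- matrix(FALSE, ny, nx)
  for (i in 1:ny) for (j in 1:nx) {
    for (k in 0:(K - 1)) {
      l <- k + 0.5
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx &&
            (M[i, j] - l) * (M[ii, jj] - l) < 0)
          out[i, j] <- TRUE
      }
    }
  }
  out
}

# subgrid refinement: Catmull-Rom interpolation + subcell average, loops
oracle_subgrid <- function(M, m, deriv) {
  crw <- function(s) 0.5 * c(-s^3 + 2 * s^2 - s, 3 * s^3 - 5 * s^2 + 2,
                             -3 * s^3 + 4 * s^2 + s, s^3 - s^2)
  ny <- nrow(M); nx <- ncol(M)
  ri <- c(2, 1, 1:ny, ny, ny - 1)
  ci <- c(2, 1, 1:nx, nx, nx - 1)
  Mp <- M[ri, ci]
  offs <- (2 * seq_len(m) - m - 1) / (2 * m)
  out <- matrix(0, ny, nx)
  for (i in 1:ny) for (j in 1:nx) {
    acc <- 0
    for (ty in offs) for (tx in offs) {
      jy <- floor(ty); sy <- ty - jy
      jx <- floor(tx); sx <- tx - jx
      wy <- crw(sy); wx <- crw(sx)
      val <- 0
      for (a in 0:3) for (b in 0:3)
        val <- val + wy[a + 1] * wx[b + 1] * Mp[i + 2 + jy - 1 + a,
                                                j + 2 + jx - 1 + b]
      acc <- acc + deriv(val)
    }
    out[i, j] <- acc / m^2
  }
  out
}

# printed double-well derivative as a plain scalar function (for oracles)
dw_deriv <- function(x) { v <- x - floor(x); v^3 - 1.5 * v^2 + 0.5 * v }

# count 4-connected components of a logical matrix (simple BFS)
n_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  seen <- matrix(FALSE, ny, nx)
  ncomp <- 0L
  for (i0 in 1:ny) for (j0 in 1:nx) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    ncomp <- ncomp + 1L
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- c0[1] + d[1]; jj <- c0[2] + d[2]
        if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  ncomp
}
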