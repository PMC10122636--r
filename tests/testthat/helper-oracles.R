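# Independent oracles and tiny fixture builders shared across the suite.

# Exact NNLS oracle by enumeration of all active sets (n <= ~10): the NNLS
# optimum is the unconstrained least-squares solution on its positive
# support, so checking every support is exhaustive.
nnls_enum_oracle <- function(A, b) {
  n <- ncol(A)
  best <- list(residual = sum(b^2), x = numeric(n))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    cf <- qr.coef(qr(A[, S, drop = FALSE]), b)
    cf[is.na(cf)] <- 0
    x[S] <- cf
    if (any(x < -1e-12)) next
    r <- sum((A %*% pmax(x, 0) - b)^2)
    if (r < best$residual - 1e-12) best <- list(residual = r, x = pmax(x, 0))
  }
  best
}

# Random volume-weighted IBR problem with known structure.
random_ibr_problem <- function(n, m, seed) {
  set.seed(seed)
  U <- matrix(stats::rexp(m * n), m, n) * 1e-3
  V <- stats::runif(m, 0.5, 2)
  ibr_problem(U, V, tissue_target(m, 0.02))
}

# Dense direct solve of a load case (reference for the sparse path).
dense_solve_oracle <- function(mesh, lc) {
  K <- as.matrix(assemble_stiffness(mesh))
  n_dof <- 3L * nrow(mesh$nodes)
  pd <- 3L * (lc$prescribed$node - 1L) + lc$prescribed$comp
  u <- numeric(n_dof)
  u[pd] <- lc$prescribed$value
  free <- setdiff(seq_len(n_dof), pd)
  u[free] <- solve(K[free, free], -K[free, pd, drop = FALSE] %*% u[pd])
  matrix(u, ncol = 3L, byrow = TRUE)
}

# Small solid-block image fixture.
solid_image <- function(n = 4, spacing = 1) {
  voxel_image(array(1, rep(n, 3)), spacing)
}

# A 1-2-symmetric lattice phantom: rods along all three axes, invariant
# under swapping axes 1 and 2.
symmetric_lattice_image <- function(n = 12, spacing = 0.5) {
  a <- array(0, c(n, n, n))
  ax <- c(3, n - 2)
  a[, ax, ax] <- 1
  a[ax, , ax] <- 1
  a[ax, ax, ] <- 1
  sym <- pmax(a, aperm(a, c(2, 1, 3)))
  voxel_image(sym, spacing)
}

expect_rel_equal <- function(object, expected, tol) {
  scale <- max(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(object - expected)) / scale, tol)
}
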