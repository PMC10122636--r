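#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes ||A x - b||^2 subject to x >= 0 with the classical active-set
#' algorithm. Deterministic for a given input: ties in the entering variable
#' are broken by the lowest column index.
#'
#' @param A m x n design matrix (m >= n in the intended use; n is small).
#' @param b length-m response.
#' @param tol dual-feasibility tolerance; default scales with the problem.
#' @return list with `x` (solution, >= 0), `residual` (||Ax-b||^2) and
#'   `passive` (indices of strictly positive components).
#' @export
nnls <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (length(b) != nrow(A)) stop("dimensions of A and b disagree")
  if (is.null(tol)) tol <- 1e-12 * max(abs(crossprod(A, b)), 1e-300)
  x <- numeric(n)
  P <- rep(FALSE, n)
  w <- as.vector(crossprod(A, b))
  iter <- 0L
  max_iter <- 30L * n + 100L
  while (any(!P) && any(w[!P] > tol)) {
    iter <- iter + 1L
    if (iter > max_iter) stop("nnls failed to converge")
    cand <- which(!P)
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > 0)) break
      neg <- P & (z <= 0)
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
    }
    x <- z
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sum((A %*% x - b)^2), passive = which(x > 0))
}
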