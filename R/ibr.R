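#' Target stimulus model
#'
#' Scalar SED homeostasis target. At the tissue level the target is the
#' constant `U0`; at the continuum level it is density-scaled, U0 * rho^d,
#' which reduces to the tissue target at full density (rho = 1) and for
#' d = 0.
#'
#' @param U0 tissue/continuum stimulus scale, MPa (default 0.02).
#' @param d density exponent (default 1.19, the value calibrated on
#'   KUBC-homogenized trabecular cubes; recalibrate with
#'   [calibrate_exponent()] for other generators/boundary conditions).
#' @return a `stimulus_model` object.
#' @export
stimulus_model <- function(U0 = 0.02, d = 1.19) {
  if (U0 <= 0) stop("U0 must be positive")
  if (d < 0) stop("d must be non-negative")
  structure(list(U0 = U0, d = d), class = "stimulus_model")
}

#' Constant tissue-level target stimulus vector
#'
#' @param m number of elements.
#' @param Ustar tissue target stimulus, MPa (default 0.02).
#' @return length-m constant vector.
#' @export
tissue_target <- function(m, Ustar = 0.02) {
  if (Ustar <= 0) stop("Ustar must be positive")
  rep(Ustar, m)
}

#' Density-dependent continuum target stimulus vector
#'
#' U_e = U0 * rho_e^d per homogenized element. Densities above 1 (possible
#' from mapping overshoot) are clamped to 1 with a warning; non-positive
#' densities are an error (such elements should have been dropped).
#'
#' @param rho per-element relative densities in (0, 1].
#' @param model a [stimulus_model()].
#' @return length(rho) target vector, MPa.
#' @export
continuum_target <- function(rho, model = stimulus_model()) {
  if (any(rho <= 0)) stop("non-positive density: element should not exist")
  if (any(rho > 1)) {
    warning("densities > 1 clamped to 1")
    rho <- pmin(rho, 1)
  }
  model$U0 * rho^model$d
}

#' IBR optimization problem
#'
#' @param U m x n matrix of per-element SED, one column per unit load case
#'   (MPa).
#' @param V length-m element volumes (mm^3).
#' @param target length-m target stimulus (MPa).
#' @return an `ibr_problem` object.
#' @export
ibr_problem <- function(U, V, target) {
  U <- as.matrix(U)
  if (nrow(U) != length(V) || nrow(U) != length(target))
    stop("dimensions of U, V and target disagree")
  if (any(V <= 0)) stop("element volumes must be positive")
  if (any(U < -1e-12 * max(abs(U)))) stop("SED must be non-negative")
  if (any(target < 0)) stop("target must be non-negative")
  structure(list(U = U, V = V, target = target, n = ncol(U)),
            class = "ibr_problem")
}

ibr_residual <- function(problem, s) {
  sum(problem$V * (as.vector(problem$U %*% s) - problem$target)^2)
}

#' Solve the inverse bone (re)modeling optimization
#'
#' Minimizes the volume-weighted squared deviation of the scaled SED field
#' from the target stimulus, r(s) = sum_e V_e (sum_i s_i U_ie - T_e)^2, over
#' s_i >= 0, by non-negative least squares on the sqrt(V_e)-row-weighted
#' system. Load scale factors are alpha_i = sqrt(n * s_i). The coefficient
#' of variation of the scaled SED field (optionally density-normalized) is
#' reported before (all s_i = 1) and after optimization.
#'
#' @param problem an [ibr_problem()].
#' @param forces optional n x 3 matrix of unit reaction forces (N); when
#'   given, `F_unit` and `F_opt` are returned.
#' @param normalizer optional length-m vector (e.g. rho^d) dividing the
#'   scaled SED before the CV is computed (continuum-level CV).
#' @return an `ibr_result`: `s`, `alpha`, `residual`, `residual_unit`,
#'   `cv_before`, `cv_after`, and (with forces) `F_unit`, `F_opt`.
#' @export
ibr_solve <- function(problem, forces = NULL, normalizer = NULL) {
  stopifnot(inherits(problem, "ibr_problem"))
  if (nrow(problem$U) < problem$n)
    stop("fewer elements than load cases")
  if (all(problem$U == 0))
    stop("no load case stimulates the structure")
  w <- sqrt(problem$V)
  fit <- nnls(problem$U * w, problem$target * w)
  s <- fit$x
  res <- structure(list(
    s = s,
    alpha = sqrt(problem$n * s),
    residual = fit$residual,
    residual_unit = ibr_residual(problem, rep(1, problem$n)),
    cv_before = coefficient_of_variation(scaled_sed(problem, rep(1, problem$n)),
                                         problem$V, normalizer),
    cv_after = coefficient_of_variation(scaled_sed(problem, s),
                                        problem$V, normalizer)
  ), class = "ibr_result")
  if (!is.null(forces)) {
    sf <- scale_forces(forces, res$alpha)
    res$F_unit <- sf$F_unit
    res$F_opt <- sf$F_opt
  }
  res
}

#' @export
print.ibr_result <- function(x, ...) {
  cat("ibr_result\n  s     =", paste(signif(x$s, 5), collapse = ", "), "\n")
  cat("  alpha =", paste(signif(x$alpha, 5), collapse = ", "), "\n")
  cat(sprintf("  CV before/after = %.4f / %.4f\n", x$cv_before, x$cv_after))
  if (!is.null(x$F_opt))
    cat(sprintf("  F_opt = (%.4g, %.4g, %.4g) N\n", x$F_opt[1], x$F_opt[2],
                x$F_opt[3]))
  invisible(x)
}

#' Scaled SED field
#'
#' U_scaled(e) = sum_i s_i U_ie: the method's linear superposition of unit
#' load case SED fields. Note this is NOT the SED of the superposed
#' displacement field (cross terms are ignored by construction).
#'
#' @param problem an [ibr_problem()].
#' @param s length-n scale vector.
#' @return length-m scaled SED.
#' @export
scaled_sed <- function(problem, s) as.vector(problem$U %*% s)

#' Volume-weighted coefficient of variation of a SED field
#'
#' Population (n-denominator) standard deviation over mean, both
#' volume-weighted; with a `normalizer` (e.g. rho^d) the CV is computed on
#' field/normalizer, so "homogeneous" means "at target everywhere" for
#' heterogeneous density.
#'
#' @param field per-element scaled SED (MPa).
#' @param V element volumes (mm^3).
#' @param normalizer optional positive per-element divisor.
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(field, V, normalizer = NULL) {
  if (length(field) < 2L) stop("CV needs at least 2 elements")
  if (!is.null(normalizer)) field <- field / normalizer
  mu <- sum(V * field) / sum(V)
  sigma <- sqrt(sum(V * (field - mu)^2) / sum(V))
  sigma / mu
}

#' Unit-scaled and optimally scaled reaction forces
#'
#' F_unit = sum_i F_i and F_opt = sum_i alpha_i F_i.
#'
#' @param forces n x 3 matrix of reaction forces (N), one row per load case.
#' @param alpha length-n load scale factors.
#' @return list with 3-vectors `F_unit` and `F_opt`.
#' @export
scale_forces <- function(forces, alpha) {
  forces <- as.matrix(forces)
  if (nrow(forces) != length(alpha)) stop("forces/alpha length mismatch")
  list(F_unit = colSums(forces), F_opt = colSums(forces * alpha))
}

#' Calibrate the continuum stimulus density exponent
#'
#' Fits d in U_opt = U0 * rho^d to per-cube (rho, U_opt) pairs by
#' one-dimensional nonlinear least squares (U0 is fixed, not fitted, to keep
#' the continuum target compatible with the tissue target at rho = 1):
#' bounded golden-section search on d in [0, 5] followed by a Newton polish.
#'
#' @param rho per-cube relative densities.
#' @param U_opt per-cube optimized continuum stimuli, MPa.
#' @param U0 fixed stimulus scale, MPa (default 0.02).
#' @return list with `model` (a [stimulus_model()]), `d`, and `r2` (fit
#'   coefficient of determination, fraction).
#' @export
calibrate_exponent <- function(rho, U_opt, U0 = 0.02) {
  if (length(rho) < 2L || length(rho) != length(U_opt))
    stop("need >= 2 (rho, U_opt) pairs")
  if (diff(range(rho)) == 0) stop("exponent unidentifiable: all rho identical")
  sse <- function(d) sum((U_opt - U0 * rho^d)^2)
  d <- stats::optimize(sse, interval = c(0, 5), tol = 1e-10)$minimum
  # Newton polish on the stationarity condition g(d) = 0
  lr <- log(rho)
  for (it in 1:50) {
    p <- U0 * rho^d
    g <- -2 * sum((U_opt - p) * p * lr)
    h <- 2 * sum((p - (U_opt - p)) * p * lr^2)
    if (!is.finite(g) || !is.finite(h) || h <= 0) break
    step <- g / h
    d_new <- min(max(d - step, 0), 5)
    if (sse(d_new) <= sse(d)) d <- d_new else break
    if (abs(step) < 1e-12) break
  }
  sst <- sum((U_opt - mean(U_opt))^2)
  r2 <- if (sst > 0) 1 - sse(d) / sst else as.numeric(sse(d) <= 1e-30)
  list(model = stimulus_model(U0, d), d = d, r2 = r2)
}
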