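#' Off-axis angle of a force vector
#'
#' Angle between the force and the (axial) 3-axis, a measure of the ratio of
#' axial to shear loading.
#'
#' @param F 3-vector (N), non-zero.
#' @return angle in degrees, in \[0, 180\].
#' @export
off_axis_angle <- function(F) {
  n <- sqrt(sum(F^2))
  if (n == 0) stop("angle undefined for a zero vector")
  acos(min(max(F[3] / n, -1), 1)) * 180 / pi
}

#' Angle similarity score of two vectors
#'
#' S_a = 1 - acos(a_hat . b_hat) / pi: 1 for parallel, 0.5 for orthogonal,
#' 0 for antiparallel vectors.
#'
#' @param a,b non-zero 3-vectors.
#' @return score in \[0, 1\].
#' @export
angle_score <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("angle score undefined for zero vectors")
  1 - acos(min(max(sum(a * b) / (na * nb), -1), 1)) / pi
}

#' Magnitude similarity score of two vectors
#'
#' S_m = 1 - sqrt((|a| - |b|)^2 / (|a|^2 + |b|^2)): 1 for equal magnitudes,
#' 0 when one vector vanishes.
#'
#' @param a,b 3-vectors, not both zero.
#' @return score in \[0, 1\].
#' @export
magnitude_score <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) stop("magnitude score undefined for two zero vectors")
  1 - sqrt((na - nb)^2 / (na^2 + nb^2))
}

#' Linear regression and concordance statistics for paired forces
#'
#' Ordinary least squares slope and intercept of y on x, the coefficient of
#' determination (squared Pearson correlation) and Lin's concordance
#' correlation coefficient, CCC = 2 cov(x,y) / (var(x) + var(y) +
#' (mean x - mean y)^2) with population (n-denominator) moments. R2 and CCC
#' are reported in percent.
#'
#' @param x,y paired numeric vectors (>= 3 pairs, x not constant).
#' @return list with `slope`, `intercept`, `r2` (percent), `ccc` (percent).
#' @export
regression_stats <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) stop("need >= 3 pairs")
  if (stats::sd(x) == 0) stop("x is constant: regression undefined")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  slope <- cxy / vx
  r2 <- if (vy > 0) cxy^2 / (vx * vy) else 0
  list(slope = slope,
       intercept = my - slope * mx,
       r2 = 100 * r2,
       ccc = 100 * 2 * cxy / (vx + vy + (mx - my)^2))
}

#' Compare two sets of predicted forces
#'
#' Per-specimen off-axis angles and angle/magnitude similarity scores, plus
#' per-component regression statistics of b on a across specimens.
#'
#' @param Fa,Fb n x 3 matrices of paired force vectors (N), e.g. micro-FE
#'   and homogenized-FE predictions.
#' @return a `force_comparison`: `pairs` data.frame (theta_a, theta_b, S_a,
#'   S_m per specimen) and `regression` (per-component stats; requires
#'   >= 3 specimens, otherwise NULL).
#' @export
compare_forces <- function(Fa, Fb) {
  Fa <- as.matrix(Fa); Fb <- as.matrix(Fb)
  stopifnot(ncol(Fa) == 3L, all(dim(Fa) == dim(Fb)))
  n <- nrow(Fa)
  pairs <- data.frame(
    specimen = seq_len(n),
    theta_a = apply(Fa, 1, off_axis_angle),
    theta_b = apply(Fb, 1, off_axis_angle),
    S_a = vapply(seq_len(n), function(i) angle_score(Fa[i, ], Fb[i, ]), 0),
    S_m = vapply(seq_len(n), function(i) magnitude_score(Fa[i, ], Fb[i, ]), 0)
  )
  regression <- NULL
  if (n >= 3L) {
    regression <- lapply(1:3, function(cc) regression_stats(Fa[, cc], Fb[, cc]))
    names(regression) <- c("F1", "F2", "F3")
  }
  structure(list(pairs = pairs, regression = regression, Fa = Fa, Fb = Fb),
            class = "force_comparison")
}

#' Write a force comparison as CSV
#'
#' Per-specimen rows (force components, angles, scores) followed by a
#' summary block with slope/intercept/R2/CCC per component.
#'
#' @param comparison a `force_comparison`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  df <- cbind(comparison$pairs[, "specimen", drop = FALSE],
              Fa1 = comparison$Fa[, 1], Fa2 = comparison$Fa[, 2],
              Fa3 = comparison$Fa[, 3],
              Fb1 = comparison$Fb[, 1], Fb2 = comparison$Fb[, 2],
              Fb3 = comparison$Fb[, 3],
              comparison$pairs[, c("theta_a", "theta_b", "S_a", "S_m")])
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  if (!is.null(comparison$regression)) {
    writeLines("", con)
    writeLines("component,slope,intercept,r2_percent,ccc_percent", con)
    for (nm in names(comparison$regression)) {
      r <- comparison$regression[[nm]]
      writeLines(sprintf("%s,%.9g,%.9g,%.9g,%.9g", nm, r$slope, r$intercept,
                         r$r2, r$ccc), con)
    }
  }
  invisible(path)
}
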