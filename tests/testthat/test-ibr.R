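test_that("target builders follow the stimulus model", {
  expect_equal(tissue_target(3, 0.02), rep(0.02, 3))
  expect_error(tissue_target(3, 0), "positive")
  expect_length(tissue_target(0, 0.02), 0)

  model <- stimulus_model(0.02, 1.19)
  expect_equal(continuum_target(1, model), 0.02)  # compatibility at rho = 1
  expect_equal(continuum_target(0.25, model), 0.02 * 0.25^1.19)
  # d = 0 reduces to the tissue target
  expect_identical(continuum_target(c(0.2, 0.7), stimulus_model(0.02, 0)),
                   tissue_target(2, 0.02))
  expect_error(continuum_target(c(0.5, 0), model), "non-positive")
  expect_warning(continuum_target(1.2, model), "clamped")
})

test_that("single uniform load case is solved exactly", {
  m <- 20
  prob <- ibr_problem(matrix(3e-4, m, 1), rep(0.5, m), tissue_target(m, 0.02))
  res <- ibr_solve(prob)
  expect_equal(res$s, 0.02 / 3e-4)
  expect_equal(res$residual, 0, tolerance = 1e-18)
  expect_equal(res$alpha, sqrt(1 * res$s))
  expect_lt(res$cv_after, 1e-12)
})

test_that("duplicated load cases split the exact total scale", {
  m <- 15
  U1 <- rep(2e-4, m)
  prob <- ibr_problem(cbind(U1, U1), rep(1, m), tissue_target(m, 0.02))
  res <- ibr_solve(prob)
  expect_equal(sum(res$s), 0.02 / 2e-4, tolerance = 1e-9)
  expect_true(all(res$s >= 0))
})

test_that("NNLS solution matches the enumeration oracle with KKT optimality", {
  for (seed in 1:25) {
    prob <- random_ibr_problem(n = 2 + seed %% 3, m = 12 + 3 * seed, seed = seed)
    res <- ibr_solve(prob)
    A <- prob$U * sqrt(prob$V)
    b <- prob$target * sqrt(prob$V)
    oracle <- nnls_enum_oracle(A, b)
    expect_lte(res$residual, oracle$residual + 1e-6 * oracle$residual + 1e-12)
    # KKT: zero gradient on the support, non-negative elsewhere
    g <- 2 * as.vector(crossprod(A, A %*% res$s - b))
    scale <- max(abs(crossprod(A, b)))
    expect_true(all(abs(g[res$s > 0]) <= 1e-6 * scale))
    expect_true(all(g[res$s == 0] >= -1e-6 * scale))
    # never worse than unit scales
    expect_lte(res$residual, res$residual_unit)
  }
})

test_that("optimum beats random feasible scalings", {
  prob <- random_ibr_problem(n = 3, m = 40, seed = 99)
  res <- ibr_solve(prob)
  set.seed(7)
  for (i in 1:1000) {
    s_try <- stats::rexp(3) * mean(res$s + 1e-9)
    expect_gte(boneibr:::ibr_residual(prob, s_try), res$residual - 1e-12)
  }
})

test_that("continuum IBR with d = 0 equals tissue IBR bit-for-bit", {
  prob_args <- random_ibr_problem(n = 3, m = 30, seed = 5)
  rho <- stats::runif(30, 0.1, 1)
  t_tissue <- tissue_target(30, 0.02)
  t_cont <- continuum_target(rho, stimulus_model(0.02, 0))
  p1 <- ibr_problem(prob_args$U, prob_args$V, t_tissue)
  p2 <- ibr_problem(prob_args$U, prob_args$V, t_cont)
  expect_identical(ibr_solve(p1)$s, ibr_solve(p2)$s)
})

test_that("volume weighting: splitting an element in two leaves s unchanged", {
  prob <- random_ibr_problem(n = 3, m = 25, seed = 11)
  s1 <- ibr_solve(prob)$s
  dup <- ibr_problem(rbind(prob$U, prob$U[1, , drop = FALSE]),
                     c(prob$V[1] / 2, prob$V[-1], prob$V[1] / 2),
                     c(prob$target, prob$target[1]))
  expect_equal(ibr_solve(dup)$s, s1, tolerance = 1e-10)
})

test_that("alpha and s round-trip exactly", {
  prob <- random_ibr_problem(n = 4, m = 30, seed = 3)
  res <- ibr_solve(prob)
  expect_equal(res$alpha, sqrt(prob$n * res$s), tolerance = 0)
  expect_equal(res$alpha^2 / prob$n, res$s, tolerance = 1e-15)
})

test_that("scaled SED and CV behave as defined", {
  prob <- random_ibr_problem(n = 2, m = 10, seed = 21)
  expect_equal(scaled_sed(prob, c(0, 0)), rep(0, 10))
  expect_equal(scaled_sed(prob, c(2, 2)), 2 * scaled_sed(prob, c(1, 1)))
  expect_equal(scaled_sed(prob, c(1, 1)), rowSums(prob$U))

  # hand-computed CV: equal volumes, U = (1, 3) -> mean 2, pop sd 1
  expect_equal(coefficient_of_variation(c(1, 3), c(1, 1)), 0.5)
  expect_equal(coefficient_of_variation(rep(4, 6), rep(1, 6)), 0)
  U <- stats::rexp(20) + 0.1
  V <- stats::runif(20, 0.5, 2)
  expect_equal(coefficient_of_variation(5 * U, V),
               coefficient_of_variation(U, V), tolerance = 1e-12)
  # normalizer: perfectly-at-target field has CV 0 at the continuum level
  rho <- stats::runif(20, 0.2, 1)
  expect_lt(coefficient_of_variation(0.02 * rho^1.19, V,
                                     normalizer = rho^1.19), 1e-12)
  expect_error(coefficient_of_variation(1, 1), "2 elements")
})

test_that("scale_forces sums components as defined", {
  F <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  sf <- scale_forces(F, c(2, 1, 0))
  expect_equal(sf$F_opt, c(2, 2, 0))
  expect_equal(sf$F_unit, c(1, 2, 3))
  expect_equal(scale_forces(F, c(1, 1, 1))$F_opt, sf$F_unit)
  expect_equal(scale_forces(F, c(0, 0, 0))$F_opt, c(0, 0, 0))
})

test_that("exponent calibration recovers generating exponents", {
  rho <- seq(0.1, 0.6, length.out = 12)
  fit <- calibrate_exponent(rho, 0.02 * rho^1.5, U0 = 0.02)
  expect_equal(fit$d, 1.5, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # 5% multiplicative lognormal noise, 200 cubes
  set.seed(31)
  rho2 <- stats::runif(200, 0.05, 0.6)
  noisy <- 0.02 * rho2^1.19 * exp(stats::rnorm(200, 0, 0.05))
  fit2 <- calibrate_exponent(rho2, noisy, U0 = 0.02)
  expect_lt(abs(fit2$d - 1.19), 0.05)

  # constant data at U0 -> d = 0
  fit3 <- calibrate_exponent(seq(0.2, 0.8, 0.1), rep(0.02, 7), U0 = 0.02)
  expect_equal(fit3$d, 0, tolerance = 1e-9)

  expect_error(calibrate_exponent(rep(0.3, 5), rep(0.01, 5)),
               "unidentifiable")
})

test_that("degenerate problems are rejected", {
  expect_error(ibr_solve(ibr_problem(matrix(0, 5, 2), rep(1, 5),
                                     tissue_target(5, 0.02))),
               "no load case")
  expect_error(ibr_problem(matrix(1, 5, 2), rep(1, 4), rep(0.02, 5)),
               "dimensions")
  expect_error(ibr_problem(matrix(1, 5, 2), rep(0, 5), rep(0.02, 5)),
               "positive")
})
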