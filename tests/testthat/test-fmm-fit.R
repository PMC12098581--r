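test_that("the concomitant M-step recovers coefficients from exact responsibilities", {
  set.seed(21)
  code <- sample(c(-1, 0, 1), 4000, replace = TRUE)
  P <- class_probabilities(code, -0.048, -0.963)
  ms <- m_step_multinomial(P, code)
  expect_equal(ms$gamma0, -0.048, tolerance = 1e-3)
  expect_equal(ms$gamma1, -0.963, tolerance = 1e-3)

  ## responsibilities independent of the code: slope ~ 0
  R0 <- matrix(c(0.3, 0.7), 500, 2, byrow = TRUE)
  ms0 <- m_step_multinomial(R0, sample(c(-1, 0, 1), 500, replace = TRUE))
  expect_lt(abs(ms0$gamma1), 1e-6)
  expect_equal(ms0$gamma0, log(0.3 / 0.7), tolerance = 1e-6)
})

test_that("the concomitant M-step caps diverging coefficients with a warning", {
  R <- cbind(rep(0, 200), rep(1, 200))   # all mass in the reference class
  code <- rep(c(-1, 0, 1), length.out = 200)
  expect_warning(ms <- m_step_multinomial(R, code), "capped")
  expect_lte(max(abs(c(ms$gamma0, ms$gamma1))), 15)
  bad <- matrix(c(0.9, 0.4), 10, 2)
  expect_error(m_step_multinomial(bad, rep(0, 10)), "sum to 1")
})

test_that("EM is monotone, deterministic, and relabels classes by factor mean", {
  sim <- simulate_fmm1(500, seed = 31)
  fit <- fit_fmm(sim, fmm_spec(2, 1), restarts = 3, seed = 5)
  expect_true(all(diff(fit$ll_hist) > -1e-8))
  expect_true(fit$converged)
  expect_lt(fit$params$alpha[1, 1], fit$params$alpha[2, 1])
  expect_equal(rowSums(fit$responsibilities), rep(1, 500), tolerance = 1e-9)

  fit2 <- fit_fmm(sim, fmm_spec(2, 1), restarts = 3, seed = 5)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$params$alpha, fit2$params$alpha)

  ## information criteria agree with the definition
  ic <- information_criteria(fit$loglik, fit$n_params, fit$n)
  expect_equal(fit$BIC, unname(ic["BIC"]))
  expect_equal(fit$AIC, unname(ic["AIC"]))
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 5, 100)
  expect_equal(unname(ic["AIC"]), 210)
  expect_equal(unname(ic["BIC"]), 200 + 5 * log(100))
  expect_equal(unname(ic["BIC"]), 223.0259, tolerance = 1e-4)
  ic0 <- information_criteria(-50, 0, 20)
  expect_equal(unname(ic0["BIC"]), 100)
  expect_equal(unname(ic0["AIC"]), 100)
  expect_equal(unname(information_criteria(0, 1, exp(1))["BIC"]), 1)
})

test_that("the free-covariance variant never scores below its constrained fit", {
  sim <- simulate_fmm1(400, seed = 33)
  f1 <- fit_fmm(sim, fmm_spec(2, 1, "FMM1"), restarts = 2, seed = 3)
  p1 <- f1$params
  p1$Psi <- NULL
  f2 <- fit_fmm(sim, fmm_spec(2, 1, "FMM2"), restarts = 2, seed = 3,
                init = p1)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("single-class spec coincides with factor analysis", {
  sim <- simulate_fmm1(300, seed = 35)
  f1 <- fit_fmm(sim, fmm_spec(1, 1, "FMM1"), restarts = 2, seed = 2)
  fa <- fit_fa(sim, 1, seed = 2, restarts = 2)
  expect_equal(f1$loglik, fa$loglik, tolerance = 1e-4)
  expect_equal(f1$spec$variant, "FA")
})

test_that("factor analysis recovers a uniform 0.6 loading", {
  ## one-factor data: eta ~ N(0, 1), binary items with loading 0.6
  set.seed(41)
  n <- 2000; J <- 12
  tau <- rnorm(J, 0, 0.3)
  eta <- rnorm(n)
  P <- plogis(outer(eta, rep(0.6, J)) +
                matrix(tau, n, J, byrow = TRUE))
  X <- matrix(rbinom(n * J, 1, P), n, J)
  fa <- fit_fa(X, 1, seed = 4, restarts = 2)
  lam <- fa$params$Lambda[, 1]
  s <- sign(mean(lam))
  expect_lt(abs(mean(s * lam) - 0.6), 0.1)
  fa2 <- fit_fa(X, 1, seed = 4, restarts = 2)
  expect_identical(fa$BIC, fa2$BIC)
})

test_that("expected response profiles track loading signs", {
  sim <- simulate_fmm1(500, seed = 37)
  fit <- fit_fmm(sim, fmm_spec(2, 1), restarts = 2, seed = 1)
  prof <- expected_response_profiles(fit)
  lam <- fit$params$Lambda[, 1]
  bin <- fit$bin_idx
  pos <- bin[lam[bin] > 0.2]
  neg <- bin[lam[bin] < -0.2]
  ## alpha ascending: class 2 higher on positive loadings, reversed on
  ## negative loadings
  expect_true(all(prof[2, pos] > prof[1, pos]))
  if (length(neg)) expect_true(all(prof[1, neg] > prof[2, neg]))
  zero_fit <- fit
  zero_fit$params$Lambda[, 1] <- 0
  prof0 <- expected_response_profiles(zero_fit)
  expect_equal(prof0[1, ], prof0[2, ], tolerance = 1e-12)
})

test_that("odds-ratio arithmetic matches the closed form", {
  or <- odds_ratio_from_coefficient(-0.963)
  expect_equal(or$odds_ratio, 0.382, tolerance = 1e-3)
  expect_equal(or$percent_change, -61.8, tolerance = 0.1)
  expect_equal(odds_ratio_from_coefficient(0)$odds_ratio, 1)
  expect_equal(odds_ratio_from_coefficient(0)$percent_change, 0)
  expect_equal(odds_ratio_from_coefficient(-0.048)$odds_ratio, 0.953,
               tolerance = 1e-3)
})

test_that("permuting the initial labels leaves the selected loglik unchanged", {
  sim <- simulate_fmm1(300, seed = 39)
  f_a <- fit_fmm(sim, fmm_spec(2, 1), restarts = 4, seed = 11)
  f_b <- fit_fmm(sim, fmm_spec(2, 1), restarts = 4, seed = 99)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-3)
  expect_equal(f_a$params$alpha, f_b$params$alpha, tolerance = 0.05)
})
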