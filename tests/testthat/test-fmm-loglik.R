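## Enumeration oracle: per-person mixture density computed by plain loops,
## independent of the package's cell/quadrature machinery.
enum_loglik_fmm1 <- function(X, tau, lambda, alpha, Pi) {
  ll <- 0
  for (i in seq_len(nrow(X))) {
    lik <- 0
    for (k in seq_along(alpha)) {
      p <- plogis(tau + lambda * alpha[k])
      contrib <- prod(ifelse(X[i, ] == 1, p, 1 - p))
      lik <- lik + Pi[i, k] * contrib
    }
    ll <- ll + log(lik)
  }
  ll
}

test_that("marginal log-likelihood matches exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    J <- sample(3:6, 1)
    n <- sample(4:8, 1)
    X <- matrix(rbinom(n * J, 1, 0.5), n, J)
    tau <- rnorm(J, 0, 1)
    lambda <- rnorm(J, 0.4, 0.3)
    alpha <- sort(rnorm(2, 0, 1.2))
    g0 <- rnorm(1, 0, 0.5); g1 <- rnorm(1, 0, 0.5)
    code <- sample(c(-1, 0, 1), n, replace = TRUE)
    spec <- fmm_spec(2, 1, "FMM1", covariate = TRUE)
    params <- cogmix:::new_fmm_params(tau, matrix(lambda), matrix(alpha),
                                      gamma0 = g0, gamma1 = g1)
    ll <- fmm_loglik(X, params, spec, covariate = code,
                     binary = rep(TRUE, J))
    Pi <- class_probabilities(code, g0, g1)
    expect_equal(ll, enum_loglik_fmm1(X, tau, lambda, alpha, Pi),
                 tolerance = 1e-10)
  }
})

test_that("single-class, zero-loading model reduces to independent Bernoulli/Gaussian", {
  set.seed(12)
  Xb <- matrix(rbinom(20 * 3, 1, 0.6), 20, 3)
  Xc <- matrix(rnorm(20, 1, 0.5), 20, 1)
  X <- cbind(Xb, Xc)
  tau <- c(0.2, -0.1, 0.5, 1.0)
  spec <- fmm_spec(1, 1, "FMM1", covariate = FALSE)
  params <- cogmix:::new_fmm_params(tau, matrix(rep(0, 4)), matrix(0),
                                    sigma2 = 0.25, pi = 1)
  ll <- fmm_loglik(X, params, spec, binary = c(TRUE, TRUE, TRUE, FALSE))
  p <- plogis(tau[1:3])
  ll_hand <- sum(Xb %*% log(p) + (1 - Xb) %*% log(1 - p)) +
    sum(dnorm(Xc, tau[4], 0.5, log = TRUE))
  expect_equal(ll, ll_hand, tolerance = 1e-10)
})

test_that("free-covariance likelihood approaches the degenerate one as Psi -> 0", {
  set.seed(13)
  J <- 6
  X <- matrix(rbinom(20 * J, 1, 0.5), 20, J)
  tau <- rnorm(J, 0, 0.5)
  lambda <- runif(J, 0.3, 0.7)
  params1 <- cogmix:::new_fmm_params(tau, matrix(lambda),
                                     matrix(c(-1, 1)), pi = c(0.4, 0.6))
  params2 <- params1
  params2$Psi <- array(1e-8, c(2, 1, 1))
  ll1 <- fmm_loglik(X, params1, fmm_spec(2, 1, "FMM1", covariate = FALSE),
                    binary = rep(TRUE, J))
  ll2 <- fmm_loglik(X, params2, fmm_spec(2, 1, "FMM2", covariate = FALSE),
                    binary = rep(TRUE, J))
  expect_lt(abs(ll1 - ll2), 1e-6)
})

test_that("non-PSD Psi is rejected", {
  params <- cogmix:::new_fmm_params(rep(0, 3), matrix(rep(0.5, 3)),
                                    matrix(c(-1, 1)), pi = c(0.5, 0.5))
  params$Psi <- array(-0.5, c(2, 1, 1))
  expect_error(
    fmm_loglik(matrix(0, 2, 3), params,
               fmm_spec(2, 1, "FMM2", covariate = FALSE),
               binary = rep(TRUE, 3)),
    "positive semidefinite")
})

test_that("E-step reproduces the hand-computed Bayes posterior", {
  ## two persons, two items, two classes, no covariate
  X <- rbind(c(1, 1), c(0, 0))
  tau <- c(0, 0)
  lambda <- c(1, 1)
  alpha <- c(-1, 1)
  Pi <- c(0.3, 0.7)
  params <- cogmix:::new_fmm_params(tau, matrix(lambda), matrix(alpha),
                                    pi = Pi)
  spec <- fmm_spec(2, 1, "FMM1", covariate = FALSE)
  R <- e_step(X, params, spec, binary = c(TRUE, TRUE))
  hand <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (k in 1:2) {
      p <- plogis(tau + lambda * alpha[k])
      hand[i, k] <- Pi[k] * prod(ifelse(X[i, ] == 1, p, 1 - p))
    }
  }
  hand <- hand / rowSums(hand)
  expect_equal(R, hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rowSums(R), c(1, 1), tolerance = 1e-12)
})

test_that("E-step degenerate cases: K = 1 and identical classes", {
  X <- matrix(rbinom(10 * 3, 1, 0.5), 10, 3)
  p1 <- cogmix:::new_fmm_params(rep(0, 3), matrix(rep(0.5, 3)), matrix(0),
                                pi = 1)
  R1 <- e_step(X, p1, fmm_spec(1, 1, "FMM1", covariate = FALSE),
               binary = rep(TRUE, 3))
  expect_equal(drop(R1), rep(1, 10))

  ## identical class parameters: responsibilities equal the priors
  p2 <- cogmix:::new_fmm_params(rep(0, 3), matrix(rep(0.5, 3)),
                                matrix(c(0.5, 0.5)), pi = c(0.25, 0.75))
  R2 <- e_step(X, p2, fmm_spec(2, 1, "FMM1", covariate = FALSE),
               binary = rep(TRUE, 3))
  expect_equal(R2, matrix(c(0.25, 0.75), 10, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("E-step survives extreme linear predictors without NaN", {
  X <- matrix(c(1, 0), 50, 6)
  params <- cogmix:::new_fmm_params(rep(30, 6), matrix(rep(10, 6)),
                                    matrix(c(-8, 8)), pi = c(0.5, 0.5))
  R <- e_step(X, params, fmm_spec(2, 1, "FMM1", covariate = FALSE),
              binary = rep(TRUE, 6))
  expect_false(any(is.nan(R)))
  expect_equal(rowSums(R), rep(1, 50), tolerance = 1e-9)
})
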