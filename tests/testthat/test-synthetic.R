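test_that("generated datasets conserve the 54-column schema and ranges", {
  sim <- simulate_fmm1(200, seed = 3)
  sch <- item_schema()
  expect_true(all(sch$name %in% names(sim$data)))
  X <- as.matrix(sim$data[, sch$name])
  expect_true(all(X[, sch$scale == "binary"] %in% c(0, 1)))
  vis <- X[, sch$scale == "unit_interval"]
  expect_true(all(vis >= 0 & vis <= 1))
  expect_true(all(X[, sch$scale == "nonnegative_continuous"] >= 0))

  simp <- simulate_profiles(200, seed = 3)
  Xp <- as.matrix(simp$data[, sch$name])
  expect_true(all(Xp[, sch$scale == "binary"] %in% c(0, 1)))
})

test_that("identical seeds reproduce identical datasets", {
  expect_identical(simulate_fmm1(100, seed = 5), simulate_fmm1(100, seed = 5))
  expect_identical(simulate_profiles(100, seed = 5),
                   simulate_profiles(100, seed = 5))
})

test_that("class assignment follows the multinomial logistic model", {
  tr <- fmm_truth()
  ## closed form at the printed coefficients, middle age bin
  expect_equal(class_probabilities(0, tr$gamma0, tr$gamma1)[1, 1],
               plogis(-0.048), tolerance = 1e-12)
  expect_equal(plogis(-0.048), 0.488, tolerance = 1e-3)

  ## empirical class-1 share per bin converges to the model probabilities
  sim <- simulate_fmm1(10000, seed = 21)
  for (b in 0:2) {
    idx <- sim$bin == b
    p_hat <- mean(sim$class[idx] == 1)
    p_true <- class_probabilities(b - 1, tr$gamma0, tr$gamma1)[1, 1]
    se <- sqrt(p_true * (1 - p_true) / sum(idx))
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("zero loading means no class separation; positive loading favors the higher class", {
  tr <- fmm_truth()
  tr$loadings[] <- 0
  tr$loadings[2] <- 0.9
  sim <- simulate_fmm1(8000, tr, seed = 9)
  X <- as.matrix(sim$data[, item_schema()$name])
  m1 <- colMeans(X[sim$class == 1, , drop = FALSE])
  m2 <- colMeans(X[sim$class == 2, , drop = FALSE])
  ## item 1 has zero loading: identical distribution across classes
  expect_lt(abs(m1[1] - m2[1]), 0.04)
  ## item 2 has a strong positive loading: class 2 mean is clearly higher
  expect_gt(m2[2] - m1[2], 0.2)
})

test_that("profile mode recovers separable labels and bin-specific weights", {
  ## G = 1: every label identical
  bank1 <- profile_bank(matrix(0, 1, 54))
  sim1 <- simulate_profiles(50, bank1, seed = 2)
  expect_true(all(sim1$profile == 1L))

  ## maximally separated pair: nearest-centroid recovers labels
  offs <- rbind(rep(3, 54), rep(-3, 54))
  bank <- profile_bank(offs, baseline = rep(0, 54))
  sim <- simulate_profiles(600, bank, seed = 4)
  X <- as.matrix(sim$data[, item_schema()$name])
  cen <- rbind(colMeans(X[sim$profile == 1, ]), colMeans(X[sim$profile == 2, ]))
  d1 <- rowSums(sweep(X, 2, cen[1, ])^2)
  d2 <- rowSums(sweep(X, 2, cen[2, ])^2)
  pred <- ifelse(d1 < d2, 1L, 2L)
  expect_gt(mean(pred == sim$profile), 0.95)

  ## bin-varying weights are matched empirically at n = 10,000
  w <- rbind(c(0.44, 0.56), c(0.48, 0.52), c(0.54, 0.46))
  bankw <- profile_bank(offs, weights = w)
  simw <- simulate_profiles(10000, bankw, seed = 6)
  for (b in 0:2) {
    share <- mean(simw$profile[simw$bin == b] == 1L)
    expect_lt(abs(share - w[b + 1, 1]), 0.03)
  }
})

test_that("profile banks validate their weights", {
  offs <- matrix(0, 2, 54)
  expect_error(profile_bank(offs, weights = c(0.7, 0.7)), "sum to 1")
  bad <- rbind(c(0.5, 0.5), c(0.9, 0.2), c(0.5, 0.5))
  expect_error(profile_bank(offs, weights = bad), "sum to 1")
  expect_error(profile_bank(matrix(0, 0, 54)), "empty")
})

test_that("datasets round-trip through CSV", {
  sim <- simulate_fmm1(40, seed = 8)
  f <- tempfile(fileext = ".csv")
  lf <- tempfile(fileext = ".csv")
  write_dataset(sim, f, lf)
  back <- load_dataset(f)
  expect_equal(as.matrix(back[, item_schema()$name]),
               as.matrix(sim$data[, item_schema()$name]),
               tolerance = 1e-12, ignore_attr = TRUE)
  lab <- utils::read.csv(lf)
  expect_equal(lab$label, sim$class)
})
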