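## Small configurations keep the autodiff graphs cheap; the clustering
## recovery runs at desk scale in the acceptance suite.

tiny_state <- function(seed = 1, K = 2, D = 3, P = 7, C = 2, H = 6) {
  cf <- cgmvae_config(input_dim = P, condition_dim = C, hidden_dim = H,
                      latent_dim = D, n_components = K, seed = seed)
  cogmix:::with_seed(seed, cogmix:::init_cgmvae_state(cf))
}

test_that("reverse-mode gradients match finite differences", {
  st <- tiny_state()
  set.seed(2)
  n <- 5
  x <- matrix(runif(n * 7), n, 7)
  cond <- cogmix:::one_hot_bins(sample(0:1, n, TRUE), 2L)
  eps <- lapply(1:2, function(k) matrix(rnorm(n * 3), n, 3))
  fw <- cogmix:::cg_forward(st, x, cond, training = TRUE, eps = eps)
  cogmix:::ad_backward(fw$total)
  g <- lapply(fw$pl, function(nd) if (is.null(nd$grad)) nd$value * 0 else
    nd$grad)
  h <- 1e-6
  for (nm in c("enc_W1", "enc_bn1_g", "head_mu_W", "head_lv_b",
               "dec_W2", "dec_out_W", "prior_mu", "prior_lv",
               "head_logit_W")) {
    i <- sample(length(st$params[[nm]]), 1)
    num <- vapply(c(h, -h), function(dd) {
      s2 <- st
      s2$params[[nm]][i] <- s2$params[[nm]][i] + dd
      s2$bn <- new.env(parent = emptyenv())
      cogmix:::cg_forward(s2, x, cond, training = TRUE,
                          eps = eps)$total$value[1]
    }, 0)
    fd <- (num[1] - num[2]) / (2 * h)
    expect_equal(g[[nm]][i], fd, tolerance = 1e-5)
  }
})

test_that("encoder output is a proper mixture posterior", {
  st <- tiny_state()
  set.seed(3)
  x <- matrix(runif(21), 3, 7)
  cond <- cogmix:::one_hot_bins(c(0, 1, 0), 2L)
  obj <- list(params = st$params, bn = st$bn, config = st$config)
  enc <- cgmvae_encode(obj, x, cond)
  expect_equal(rowSums(enc$q_y), rep(1, 3), tolerance = 1e-6)
  expect_equal(dim(enc$mu), c(3, 2, 3))
  expect_equal(dim(enc$logvar), c(3, 2, 3))
  expect_error(cgmvae_encode(obj, x * NaN, cond), "NaN")

  ## K = 1: the mixture weight is identically 1
  st1 <- tiny_state(K = 1)
  obj1 <- list(params = st1$params, bn = st1$bn, config = st1$config)
  enc1 <- cgmvae_encode(obj1, x, cond)
  expect_equal(drop(enc1$q_y), rep(1, 3), tolerance = 1e-9)

  ## flipping the condition changes the encoder output
  enc_flip <- cgmvae_encode(obj, x, cond[, 2:1])
  expect_gt(mean(abs(enc_flip$q_y - enc$q_y)) +
              mean(abs(enc_flip$mu - enc$mu)), 0)
})

test_that("reparameterization is exact and unbiased", {
  mu <- matrix(c(1, -2), 2, 4)
  lv <- matrix(0, 2, 4)
  expect_equal(reparameterize(mu, lv, matrix(0, 2, 4)), mu)
  expect_equal(reparameterize(mu, lv, matrix(1, 2, 4)), mu + 1)
  set.seed(5)
  draws <- replicate(10000, reparameterize(1.5, log(4), rnorm(1)))
  expect_lt(abs(mean(draws) - 1.5), 3 * 2 / sqrt(10000))
})

test_that("latent aggregation is the membership-weighted sum", {
  q <- rbind(c(1, 0), c(0.5, 0.5))
  z <- array(0, c(2, 2, 3))
  z[, 1, ] <- 0
  z[, 2, ] <- 2
  agg <- aggregate_latent(q, z)
  expect_equal(agg[1, ], rep(0, 3))
  expect_equal(agg[2, ], rep(1, 3))
  ## identical components: aggregation ignores the weights
  z[, 1, ] <- 2
  expect_true(all(aggregate_latent(q, z) == 2))
})

test_that("mixture KL closed form: zero at equality, mu^2/2 for unit Gaussians", {
  q <- matrix(1, 4, 1)
  mu <- array(1, c(4, 1, 1))
  lv <- array(0, c(4, 1, 1))
  kl <- kl_mixture(q, mu, lv, mu_prior = matrix(0, 1, 1),
                   logvar_prior = matrix(0, 1, 1))
  expect_equal(kl$gaussian, 0.5, tolerance = 1e-12)
  klz <- kl_mixture(q, mu, lv, mu_prior = matrix(1, 1, 1),
                    logvar_prior = matrix(0, 1, 1))
  expect_equal(klz$gaussian, 0, tolerance = 1e-12)
  ## uniform memberships: categorical part vanishes
  qu <- matrix(0.5, 4, 2)
  mu2 <- array(0, c(4, 2, 1)); lv2 <- array(0, c(4, 2, 1))
  klu <- kl_mixture(qu, mu2, lv2, matrix(0, 2, 1), matrix(0, 2, 1))
  expect_equal(klu$categorical, 0, tolerance = 1e-12)
})

test_that("loss decomposes exactly and respects the free-bits floor", {
  st <- tiny_state()
  set.seed(7)
  x <- matrix(runif(8 * 7), 8, 7)
  cond <- cogmix:::one_hot_bins(sample(0:1, 8, TRUE), 2L)
  obj <- list(params = st$params, bn = st$bn, config = st$config)
  for (beta in c(0.051, 0.5)) {
    l <- elbo_loss(x, cond, obj, beta = beta, free_bits = 0.048)
    expect_equal(l$total,
                 l$reconstruction + beta * (l$kl_gaussian_clamped +
                                              l$kl_categorical),
                 tolerance = 1e-6)
    expect_gte(l$kl_gaussian_clamped, 3 * 0.048)   # D * free_bits
    expect_gte(l$total, l$reconstruction)
  }
  ## beta -> 0 limit: only reconstruction remains (beta must stay positive)
  l0 <- elbo_loss(x, cond, obj, beta = 1e-12, free_bits = 0.048)
  expect_equal(l0$total, l0$reconstruction, tolerance = 1e-9)
  ## posterior pinned to the prior: the Gaussian KL sits on the clamp floor
  st2 <- tiny_state()
  st2$params$head_mu_W[] <- 0; st2$params$head_mu_b[] <- 0
  st2$params$head_lv_W[] <- 0; st2$params$head_lv_b[] <- 0
  st2$params$prior_mu[] <- 0; st2$params$prior_lv[] <- 0
  obj2 <- list(params = st2$params, bn = st2$bn, config = st2$config)
  l2 <- elbo_loss(x, cond, obj2, beta = 0.051, free_bits = 0.048)
  expect_equal(l2$kl_gaussian_pre, 0, tolerance = 1e-9)
  expect_equal(l2$kl_gaussian_clamped, 3 * 0.048, tolerance = 1e-9)
})

test_that("decoder output respects the sigmoid codomain and shape", {
  st <- tiny_state()
  obj <- list(params = st$params, bn = st$bn, config = st$config)
  set.seed(8)
  z <- matrix(rnorm(12), 4, 3)
  cond <- cogmix:::one_hot_bins(rep(0:1, 2), 2L)
  xhat <- cgmvae_decode(obj, z, cond)
  expect_equal(dim(xhat), c(4, 7))
  expect_true(all(xhat >= 0 & xhat <= 1))
})

test_that("training is deterministic, frozen at lr 0, and can overfit a tiny batch", {
  set.seed(9)
  x <- matrix(runif(8 * 6), 8, 6)
  dat <- list(x = x, cond = cogmix:::one_hot_bins(rep(0:1, 4), 2L))
  cf <- cgmvae_config(input_dim = 6, condition_dim = 2, hidden_dim = 16,
                      latent_dim = 2, n_components = 2, epochs = 8,
                      batch_size = 4, seed = 42, val_fraction = 0.25)
  f1 <- cgmvae(dat, cf)
  f2 <- cgmvae(dat, cf)
  expect_identical(f1$history, f2$history)

  cf0 <- cf; cf0$learning_rate <- 0
  f0 <- cgmvae(dat, cf0)
  expect_equal(f0$params, cogmix:::with_seed(
    42, cogmix:::init_cgmvae_state(cf0))$params, tolerance = 1e-12)
  ## with frozen parameters the history is flat up to batch-norm
  ## running-statistic settling
  expect_lt(max(abs(diff(f0$history$val_total))), 0.1)

  ## overfit-one-batch sanity: the mean-aggregate autoencoding path
  ## reconstructs 8 inputs through a 2-D latent space
  cfo <- cgmvae_config(input_dim = 6, condition_dim = 2, hidden_dim = 32,
                       latent_dim = 2, n_components = 2, epochs = 400,
                       batch_size = 8, seed = 7, val_fraction = 0.25,
                       learning_rate = 5e-3, beta = 0.01,
                       scheduler_patience = 100000L)
  fo <- cgmvae(dat, cfo)
  enc <- cgmvae_encode(fo$final, dat$x, dat$cond)
  xhat <- cgmvae_decode(fo$final, aggregate_latent(enc$q_y, enc$mu),
                        dat$cond)
  expect_lt(mean((dat$x - xhat)^2), 0.05)
})

test_that("per-step invariants and the gradient-clip contract hold while training", {
  sim <- simulate_profiles(300, default_profile_bank(3, separation = 2),
                           seed = 91)
  cf <- cgmvae_config(hidden_dim = 24, latent_dim = 4, n_components = 3,
                      epochs = 5, batch_size = 64, seed = 3,
                      grad_clip = 0.644)
  fit <- cgmvae(sim, cf)
  expect_lt(fit$diagnostics$decomposition_max_error, 1e-6)
  expect_gte(fit$diagnostics$free_bits_min_slack, -1e-9)
  expect_lte(fit$diagnostics$max_post_clip_norm, 0.644 + 1e-6)
  expect_equal(nrow(fit$history), 5L)
  ## memberships and embeddings: valid and deterministic
  U <- membership(fit)
  expect_equal(rowSums(U), rep(1, 300), tolerance = 1e-6)
  E1 <- latent_embedding(fit)
  E2 <- latent_embedding(fit)
  expect_identical(E1, E2)
  expect_equal(dim(E1), c(300L, 4L))
})

test_that("hyperparameter search honors trivial spaces and the min definition", {
  set.seed(10)
  x <- matrix(runif(60 * 5), 60, 5)
  dat <- list(x = x, cond = cogmix:::one_hot_bins(sample(0:2, 60, TRUE), 3L))
  base <- cgmvae_config(input_dim = 5, condition_dim = 3, hidden_dim = 8,
                        latent_dim = 2, n_components = 2, epochs = 3,
                        batch_size = 16)
  point <- list(latent_dim = c(3L, 3L), n_components = c(2L, 2L),
                learning_rate = c(1e-3, 1e-3), free_bits = c(0.05, 0.05))
  s1 <- cgmvae_search(dat, n_trials = 1, space = point, config = base,
                      seed = 5)
  expect_equal(s1$best_config$latent_dim, 3L)
  expect_equal(s1$best_config$free_bits, 0.05)
  s3 <- cgmvae_search(dat, n_trials = 3, space = point, config = base,
                      seed = 6)
  expect_lte(s3$trials$val_loss[which.min(s3$trials$val_loss)],
             stats::median(s3$trials$val_loss, na.rm = TRUE))
})
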