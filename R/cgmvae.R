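## Conditional Gaussian-Mixture Variational Autoencoder.
##
## Recognition model: encoder trunk on concat(x, c) -> mixture logits,
## per-component posterior means and log-variances. Latent sample: the
## reparameterization trick per component, aggregated by the mixture
## probabilities. Generative model: decoder on concat(z, c). Prior: a
## learnable Gaussian mixture (per-component means and log-variances) with
## uniform component weights. Loss: MSE reconstruction + beta * (mixture
## Gaussian KL with a per-dimension free-bits floor + categorical KL).

#' CGMVAE configuration
#'
#' Defaults are the package's tuned settings:
#' hidden width 201, latent dimension 58, 10 mixture components,
#' \eqn{\beta} = 0.051, free-bits threshold 0.048, Adam learning rate
#' 9.68e-4 with weight decay 4.0e-5, gradient clipping at 0.644.
#'
#' @param input_dim number of input features.
#' @param condition_dim length of the one-hot condition (3 age bins).
#' @param hidden_dim trunk width.
#' @param latent_dim latent dimensionality D.
#' @param n_components mixture components K.
#' @param beta KL weight, in (0, 1].
#' @param free_bits per-latent-dimension KL floor (nats).
#' @param learning_rate,weight_decay,grad_clip Adam settings; `grad_clip`
#'   bounds the global gradient norm (`Inf` disables).
#' @param batch_size,epochs training loop size.
#' @param n_blocks fully connected blocks (linear-ReLU-batchnorm) in the
#'   encoder trunk and mirrored decoder.
#' @param output_head `"sigmoid"` (all features binary or normalized to
#'   `[0, 1]`) or `"linear"`.
#' @param val_fraction held-out share for validation, stratified by
#'   condition.
#' @param scheduler_factor,scheduler_patience reduce-on-plateau settings
#'   for the validation total loss.
#' @param seed master seed for initialization, split, shuffling and
#'   sampling.
#' @return Object of class `cgmvae_config`.
#' @export
cgmvae_config <- function(input_dim = 54L, condition_dim = 3L,
                          hidden_dim = 201L, latent_dim = 58L,
                          n_components = 10L, beta = 0.051,
                          free_bits = 0.048, learning_rate = 9.68e-4,
                          weight_decay = 4.0e-5, grad_clip = 0.644,
                          batch_size = 64L, epochs = 30L, n_blocks = 2L,
                          output_head = c("sigmoid", "linear"),
                          val_fraction = 0.2, scheduler_factor = 0.5,
                          scheduler_patience = 5L, seed = 1L) {
  output_head <- match.arg(output_head)
  stopifnot(beta > 0, beta <= 1, n_components >= 1L, latent_dim >= 1L,
            free_bits >= 0, val_fraction > 0, val_fraction < 1)
  structure(as.list(environment()), class = "cgmvae_config")
}

## ---- state ----------------------------------------------------------------

.init_linear <- function(fan_in, fan_out, gain = 1) {
  matrix(stats::rnorm(fan_in * fan_out, 0, gain * sqrt(2 / fan_in)),
         fan_in, fan_out)
}

init_cgmvae_state <- function(config) {
  P <- config$input_dim + config$condition_dim
  H <- config$hidden_dim
  D <- config$latent_dim
  K <- config$n_components
  params <- list()
  dims_in <- c(P, rep(H, config$n_blocks - 1L))
  for (b in seq_len(config$n_blocks)) {
    params[[paste0("enc_W", b)]] <- .init_linear(dims_in[b], H)
    params[[paste0("enc_b", b)]] <- matrix(0, 1L, H)
    params[[paste0("enc_bn", b, "_g")]] <- matrix(1, 1L, H)
    params[[paste0("enc_bn", b, "_b")]] <- matrix(0, 1L, H)
  }
  params$head_logit_W <- .init_linear(H, K, gain = 0.5)
  params$head_logit_b <- matrix(0, 1L, K)
  params$head_mu_W <- .init_linear(H, K * D, gain = 0.5)
  params$head_mu_b <- matrix(0, 1L, K * D)
  params$head_lv_W <- .init_linear(H, K * D, gain = 0.05)
  params$head_lv_b <- matrix(0, 1L, K * D)
  dims_in <- c(D + config$condition_dim, rep(H, config$n_blocks - 1L))
  for (b in seq_len(config$n_blocks)) {
    params[[paste0("dec_W", b)]] <- .init_linear(dims_in[b], H)
    params[[paste0("dec_b", b)]] <- matrix(0, 1L, H)
    params[[paste0("dec_bn", b, "_g")]] <- matrix(1, 1L, H)
    params[[paste0("dec_bn", b, "_b")]] <- matrix(0, 1L, H)
  }
  params$dec_out_W <- .init_linear(H, config$input_dim)
  params$dec_out_b <- matrix(0, 1L, config$input_dim)
  params$prior_mu <- matrix(stats::rnorm(K * D, 0, 1), K, D)
  params$prior_lv <- matrix(0, K, D)
  bn <- new.env(parent = emptyenv())
  list(params = params, bn = bn, config = config)
}

## ---- forward graph --------------------------------------------------------

.cg_trunk <- function(h, pl, bn, prefix, n_blocks, training) {
  for (b in seq_len(n_blocks)) {
    h <- ad_linear(h, pl[[paste0(prefix, "_W", b)]],
                   pl[[paste0(prefix, "_b", b)]])
    h <- ad_relu(h)
    h <- ad_batchnorm(h, pl[[paste0(prefix, "_bn", b, "_g")]],
                      pl[[paste0(prefix, "_bn", b, "_b")]],
                      bn, paste0(prefix, b), training)
  }
  h
}

## Full loss graph. `eps` is a list of K n x D noise matrices (NULL for
## the deterministic posterior-mean pass used by membership/embedding).
cg_forward <- function(state, x, cond, training = TRUE, eps = NULL,
                       beta = NULL, free_bits = NULL, sample = TRUE) {
  cf <- state$config
  beta <- beta %||% cf$beta
  free_bits <- free_bits %||% cf$free_bits
  K <- cf$n_components
  D <- cf$latent_dim
  n <- nrow(x)
  tape <- ad_tape()
  pl <- lapply(state$params, function(p) ad_leaf(tape, p))
  xin <- ad_leaf(tape, x)
  cin <- ad_leaf(tape, cond)
  h <- .cg_trunk(ad_cbind(xin, cin), pl, state$bn, "enc", cf$n_blocks,
                 training)
  logits <- ad_linear(h, pl$head_logit_W, pl$head_logit_b)
  logq <- ad_logsoftmax_rows(logits)
  q <- ad_exp(logq)
  mu_all <- ad_linear(h, pl$head_mu_W, pl$head_mu_b)
  lv_all <- ad_linear(h, pl$head_lv_W, pl$head_lv_b)
  if (sample && is.null(eps)) {
    eps <- lapply(seq_len(K), function(k) matrix(stats::rnorm(n * D), n, D))
  }
  z <- NULL
  klw <- NULL
  mus <- vector("list", K)
  lvs <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- (k - 1L) * D + seq_len(D)
    mu_k <- ad_cols(mu_all, idx)
    lv_k <- ad_cols(lv_all, idx)
    mus[[k]] <- mu_k; lvs[[k]] <- lv_k
    z_k <- if (sample) {
      ad_add(mu_k, ad_mul(ad_exp(ad_scale(lv_k, 0.5)),
                          ad_leaf(tape, eps[[k]])))
    } else {
      mu_k
    }
    zc <- ad_mulcol(z_k, ad_col(q, k))
    z <- if (is.null(z)) zc else ad_add(z, zc)
    ## closed-form Gaussian KL to prior component k, per dimension
    mu_p <- ad_row(pl$prior_mu, k)
    lv_p <- ad_row(pl$prior_lv, k)
    dmu <- ad_subrow(mu_k, mu_p)
    num <- ad_add(ad_exp(lv_k), ad_mul(dmu, dmu))
    frac <- ad_mulrow(num, ad_exp(ad_scale(lv_p, -1)))
    kl_k <- ad_scale(ad_shift(ad_addrow(ad_sub(frac, lv_k), lv_p), -1), 0.5)
    klc <- ad_mulcol(kl_k, ad_col(q, k))
    klw <- if (is.null(klw)) klc else ad_add(klw, klc)
  }
  hd <- .cg_trunk(ad_cbind(z, cin), pl, state$bn, "dec", cf$n_blocks,
                  training)
  xhat <- ad_linear(hd, pl$dec_out_W, pl$dec_out_b)
  if (cf$output_head == "sigmoid") xhat <- ad_sigmoid(xhat)
  diff <- ad_sub(xin, xhat)
  recon <- ad_mean(ad_mul(diff, diff))
  kl_dim <- ad_colmeans(klw)                 # 1 x D, batch-averaged
  kl_pre <- ad_sum(kl_dim)
  kl_clamped <- ad_sum(ad_clamp_min(kl_dim, free_bits))
  qlq <- ad_mul(q, logq)
  kl_cat <- ad_shift(ad_scale(ad_sum(qlq), 1 / n), log(K))
  total <- ad_add(recon, ad_scale(ad_add(kl_clamped, kl_cat), beta))
  list(tape = tape, pl = pl, total = total, recon = recon,
       kl_pre = kl_pre, kl_clamped = kl_clamped, kl_cat = kl_cat,
       kl_dim = kl_dim, q = q, mus = mus, lvs = lvs, z = z, xhat = xhat)
}

## ---- numeric building blocks (exported operations) ------------------------

#' Reparameterization trick
#'
#' \eqn{z = \mu + \sigma \odot \epsilon} with
#' \eqn{\sigma = \exp(\log\sigma^2 / 2)}.
#'
#' @param mu,logvar,eps conformable numeric arrays.
#' @export
reparameterize <- function(mu, logvar, eps) {
  mu + exp(logvar / 2) * eps
}

#' Mixture-weighted latent aggregation
#'
#' \eqn{z = \sum_k q_k z_k}: the final latent representation is the
#' mixture-probability-weighted sum of the per-component samples.
#'
#' @param q_y n x K mixture probabilities.
#' @param z_components n x K x D array (or list of K n x D matrices).
#' @return n x D matrix.
#' @export
aggregate_latent <- function(q_y, z_components) {
  q_y <- as.matrix(q_y)
  if (is.list(z_components)) {
    z_components <- simplify2array(z_components)    # n x D x K
    z_components <- aperm(z_components, c(1L, 3L, 2L))
  }
  K <- ncol(q_y)
  D <- dim(z_components)[3L]
  z <- matrix(0, nrow(q_y), D)
  for (k in seq_len(K)) {
    z <- z + q_y[, k] * matrix(z_components[, k, ], nrow(q_y), D)
  }
  z
}

#' Closed-form KL terms of the mixture posterior
#'
#' Gaussian part: \eqn{\sum_k q_k \mathrm{KL}(N(\mu_k, \sigma_k^2) \,\|\,
#' N(\mu_{p,k}, \sigma_{p,k}^2))} per latent dimension (batch-averaged);
#' categorical part: \eqn{\mathrm{KL}(q_y \| \mathrm{uniform}(K))}.
#'
#' @param q_y n x K mixture probabilities.
#' @param mu,logvar n x K x D posterior arrays.
#' @param mu_prior,logvar_prior K x D prior parameters.
#' @return List with `per_dim` (length D), `gaussian` (their sum) and
#'   `categorical`.
#' @export
kl_mixture <- function(q_y, mu, logvar, mu_prior, logvar_prior) {
  q_y <- as.matrix(q_y)
  n <- nrow(q_y); K <- ncol(q_y); D <- dim(mu)[3L]
  per_dim <- rep(0, D)
  for (k in seq_len(K)) {
    mk <- matrix(mu[, k, ], n, D)
    lk <- matrix(logvar[, k, ], n, D)
    mp <- matrix(mu_prior[k, ], n, D, byrow = TRUE)
    lp <- matrix(logvar_prior[k, ], n, D, byrow = TRUE)
    kl <- 0.5 * (lp - lk + (exp(lk) + (mk - mp)^2) / exp(lp) - 1)
    per_dim <- per_dim + colMeans(q_y[, k] * kl)
  }
  cat_kl <- mean(rowSums(q_y * ifelse(q_y > 0, log(q_y), 0))) + log(K)
  list(per_dim = per_dim, gaussian = sum(per_dim),
       categorical = max(cat_kl, 0))
}

## ---- data interface -------------------------------------------------------

## Normalize inputs: schema data gets the working-memory score scaled to
## [0, 1] by its max and the age bin one-hot encoded; otherwise a list
## with `x` (and optional `cond`) passes through.
cgmvae_data <- function(data, wm_max = NULL) {
  if (inherits(data, "cogmix_sim")) {
    b <- list(bin = data$bin)
    df <- data$data
  } else if (is.data.frame(data) && all(item_schema()$name %in% names(data))) {
    df <- data
    b <- bin_ages(df$age)
  } else if (is.list(data) && !is.null(data$x)) {
    x <- as.matrix(data$x)
    cond <- if (is.null(data$cond)) matrix(0, nrow(x), 0L) else
      as.matrix(data$cond)
    return(list(x = x, cond = cond, wm_max = NULL))
  } else {
    stop("unsupported data for the CGMVAE; pass schema data or list(x, cond)",
         call. = FALSE)
  }
  sch <- item_schema()
  X <- as.matrix(df[, sch$name])
  wm <- which(sch$scale == "nonnegative_continuous")
  wm_max <- wm_max %||% max(X[, wm], 1e-8)
  X[, wm] <- pmin(X[, wm] / wm_max, 1)
  cond <- one_hot_bins(b$bin)
  list(x = X, cond = cond, wm_max = wm_max)
}

## ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

## Clip the global gradient norm, then Adam with (coupled) weight decay.
adam_step <- function(params, grads, opt, lr, weight_decay, grad_clip,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(grad_clip) && gn > grad_clip) {
    grads <- lapply(grads, function(g) g * (grad_clip / (gn + 1e-12)))
  }
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt,
       post_clip_norm = min(gn, grad_clip))
}

## ---- training -------------------------------------------------------------

#' Fit a Conditional Gaussian-Mixture Variational Autoencoder
#'
#' Trains the CGMVAE by minibatch Adam on the beta-weighted ELBO with a
#' per-dimension free-bits floor on the Gaussian KL. The data are split
#' into training and validation sets (stratified by the condition),
#' validation loss drives a reduce-on-plateau learning-rate schedule, and
#' the weights with minimal validation loss are retained.
#'
#' @param data schema data frame / `cogmix_sim` (age bin becomes the
#'   one-hot condition; the working-memory score is max-normalized), or a
#'   `list(x = , cond = )` of numeric matrices.
#' @param config a [cgmvae_config()]; `input_dim`/`condition_dim` are
#'   corrected to the data automatically.
#' @return Object of class `cgmvae`: best `params` and batch-norm state,
#'   per-epoch `history`, `best_epoch`, structural `diagnostics`
#'   (loss-decomposition error, free-bits slack, post-clip gradient norms)
#'   and the preprocessing constants.
#' @examples
#' \donttest{
#' sim <- simulate_profiles(400, default_profile_bank(4, separation = 3),
#'                          seed = 1)
#' cfg <- cgmvae_config(latent_dim = 8, n_components = 4, hidden_dim = 32,
#'                      epochs = 10, seed = 1)
#' fit <- cgmvae(sim, cfg)
#' table(predict(fit, type = "class"))
#' }
#' @export
cgmvae <- function(data, config = cgmvae_config()) {
  d <- cgmvae_data(data)
  config$input_dim <- ncol(d$x)
  config$condition_dim <- ncol(d$cond)
  n <- nrow(d$x)
  K <- config$n_components
  D <- config$latent_dim
  with_seed(config$seed, {
    state <- init_cgmvae_state(config)
    opt <- adam_init(state$params)
    ## stratified split by condition column (falls back to plain split)
    strat <- if (ncol(d$cond)) max.col(d$cond, "first") else rep(1L, n)
    val_idx <- unlist(lapply(split(seq_len(n), strat), function(ix) {
      nv <- max(1L, round(length(ix) * config$val_fraction))
      sample(ix, nv)
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)
    ## fixed validation noise: epoch-to-epoch validation losses stay
    ## comparable, so checkpointing tracks the model, not the draw
    val_eps <- lapply(seq_len(K), function(k) {
      matrix(stats::rnorm(length(val_idx) * D), length(val_idx), D)
    })
    lr <- config$learning_rate
    best_val <- Inf
    best <- NULL
    wait <- 0L
    hist <- vector("list", config$epochs)
    decomp_err <- 0
    floor_slack <- Inf
    max_postclip <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / config$batch_size)
      tr_tot <- tr_rec <- tr_kl <- 0
      for (bi in seq_len(nb)) {
        ix <- ord[((bi - 1L) * config$batch_size + 1L):
                    min(bi * config$batch_size, length(ord))]
        fw <- cg_forward(state, d$x[ix, , drop = FALSE],
                         d$cond[ix, , drop = FALSE], training = TRUE)
        tot <- fw$total$value[1L]
        if (!is.finite(tot)) {
          stop(sprintf(paste0("CGMVAE training diverged (non-finite loss ",
                              "at epoch %d, batch %d); reduce the learning ",
                              "rate or increase grad_clip"), ep, bi),
               call. = FALSE)
        }
        ## structural invariants, tracked at every step
        dec <- abs(tot - (fw$recon$value[1L] +
                            config$beta * (fw$kl_clamped$value[1L] +
                                             fw$kl_cat$value[1L])))
        decomp_err <- max(decomp_err, dec)
        floor_slack <- min(floor_slack,
                           fw$kl_clamped$value[1L] - D * config$free_bits)
        ad_backward(fw$total)
        grads <- lapply(fw$pl, function(nd) {
          if (is.null(nd$grad)) nd$value * 0 else nd$grad
        })
        st <- adam_step(state$params, grads, opt, lr, config$weight_decay,
                        config$grad_clip)
        state$params <- st$params
        opt <- st$opt
        max_postclip <- max(max_postclip, st$post_clip_norm)
        w <- length(ix) / length(tr_idx)
        tr_tot <- tr_tot + w * tot
        tr_rec <- tr_rec + w * fw$recon$value[1L]
        tr_kl <- tr_kl + w * (fw$kl_clamped$value[1L] + fw$kl_cat$value[1L])
      }
      vw <- cg_forward(state, d$x[val_idx, , drop = FALSE],
                       d$cond[val_idx, , drop = FALSE], training = FALSE,
                       eps = val_eps)
      val_tot <- vw$total$value[1L]
      hist[[ep]] <- data.frame(
        epoch = ep, train_total = tr_tot, train_recon = tr_rec,
        train_kl = tr_kl, val_total = val_tot,
        val_recon = vw$recon$value[1L],
        val_kl = vw$kl_clamped$value[1L] + vw$kl_cat$value[1L], lr = lr)
      if (val_tot < best_val - 1e-12) {
        best_val <- val_tot
        best <- list(params = state$params,
                     bn = as.list(state$bn), epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$scheduler_patience) {
          lr <- lr * config$scheduler_factor
          wait <- 0L
        }
      }
    }
    history <- do.call(rbind, hist)
    if (is.null(best)) best <- list(params = state$params,
                                    bn = as.list(state$bn),
                                    epoch = config$epochs)
    bn_env <- new.env(parent = emptyenv())
    for (nm in names(best$bn)) bn_env[[nm]] <- best$bn[[nm]]
    final <- list(params = state$params, bn = state$bn, config = config)
    structure(list(params = best$params, bn = bn_env, config = config,
                   final = final,
                   history = history, best_epoch = best$epoch,
                   best_val = best_val,
                   diagnostics = list(decomposition_max_error = decomp_err,
                                      free_bits_min_slack = floor_slack,
                                      max_post_clip_norm = max_postclip),
                   wm_max = d$wm_max,
                   train_idx = tr_idx, val_idx = val_idx,
                   data_cache = d),
              class = "cgmvae")
  })
}

#' Loss breakdown of a batch under a fitted (or fresh) CGMVAE
#'
#' @param x n x P feature matrix (already normalized).
#' @param cond n x C condition matrix.
#' @param object a `cgmvae` fit or the state returned by the internal
#'   initializer.
#' @param beta,free_bits optional overrides of the stored configuration.
#' @param eps optional list of K noise matrices for a deterministic pass.
#' @return List with `total`, `reconstruction`, `kl_gaussian_pre`,
#'   `kl_gaussian_clamped`, `kl_categorical` and `kl_per_dimension`.
#' @export
elbo_loss <- function(x, cond, object, beta = NULL, free_bits = NULL,
                      eps = NULL) {
  state <- list(params = object$params, bn = object$bn,
                config = object$config)
  fw <- cg_forward(state, as.matrix(x), as.matrix(cond), training = FALSE,
                   eps = eps, beta = beta, free_bits = free_bits)
  list(total = fw$total$value[1L],
       reconstruction = fw$recon$value[1L],
       kl_gaussian_pre = fw$kl_pre$value[1L],
       kl_gaussian_clamped = fw$kl_clamped$value[1L],
       kl_categorical = fw$kl_cat$value[1L],
       kl_per_dimension = drop(fw$kl_dim$value))
}

#' Encoder pass of a fitted CGMVAE
#'
#' @inheritParams elbo_loss
#' @return List with `q_y` (n x K), `mu` and `logvar` (n x K x D arrays).
#' @export
cgmvae_encode <- function(object, x, cond) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("NaN/Inf in encoder input", call. = FALSE)
  state <- list(params = object$params, bn = object$bn,
                config = object$config)
  fw <- cg_forward(state, x, as.matrix(cond), training = FALSE,
                   sample = FALSE)
  K <- object$config$n_components
  D <- object$config$latent_dim
  n <- nrow(x)
  mu <- array(0, c(n, K, D)); lv <- array(0, c(n, K, D))
  for (k in seq_len(K)) {
    mu[, k, ] <- fw$mus[[k]]$value
    lv[, k, ] <- fw$lvs[[k]]$value
  }
  list(q_y = fw$q$value, mu = mu, logvar = lv)
}

#' Decoder pass of a fitted CGMVAE
#'
#' @param object a `cgmvae` fit.
#' @param z n x D latent matrix.
#' @param cond n x C condition matrix.
#' @return n x P reconstruction.
#' @export
cgmvae_decode <- function(object, z, cond) {
  cf <- object$config
  tape <- ad_tape()
  pl <- lapply(object$params, function(p) ad_leaf(tape, p))
  zc <- ad_cbind(ad_leaf(tape, as.matrix(z)),
                 ad_leaf(tape, as.matrix(cond)))
  state_bn <- object$bn
  hd <- .cg_trunk(zc, pl, state_bn, "dec", cf$n_blocks, training = FALSE)
  xhat <- ad_linear(hd, pl$dec_out_W, pl$dec_out_b)
  if (cf$output_head == "sigmoid") xhat <- ad_sigmoid(xhat)
  xhat$value
}

#' Fuzzy memberships from the recognition network
#'
#' Posterior mixture probabilities \eqn{q(y = k \mid x, c)}; hard labels
#' are the row-wise argmax (lowest index on ties).
#'
#' @param object a fitted `cgmvae`.
#' @param data optional new data (training data by default).
#' @return n x K membership matrix.
#' @export
membership <- function(object, data = NULL) {
  d <- if (is.null(data)) object$data_cache else
    cgmvae_data(data, wm_max = object$wm_max)
  cgmvae_encode(object, d$x, d$cond)$q_y
}

#' Deterministic latent embedding
#'
#' \eqn{z_i = \sum_k q_{ik} \mu_k(x_i, c_i)}: posterior means aggregated by
#' the mixture probabilities, with no sampling, so repeated calls agree.
#'
#' @inheritParams membership
#' @return n x D matrix.
#' @export
latent_embedding <- function(object, data = NULL) {
  d <- if (is.null(data)) object$data_cache else
    cgmvae_data(data, wm_max = object$wm_max)
  enc <- cgmvae_encode(object, d$x, d$cond)
  aggregate_latent(enc$q_y, enc$mu)
}

#' @export
predict.cgmvae <- function(object, newdata = NULL,
                           type = c("membership", "class", "embedding",
                                    "reconstruction"), ...) {
  type <- match.arg(type)
  if (type == "membership") return(membership(object, newdata))
  if (type == "class") {
    return(max.col(membership(object, newdata), ties.method = "first"))
  }
  if (type == "embedding") return(latent_embedding(object, newdata))
  d <- if (is.null(newdata)) object$data_cache else
    cgmvae_data(newdata, wm_max = object$wm_max)
  z <- latent_embedding(object, newdata)
  out <- cgmvae_decode(object, z, d$cond)
  if (!is.null(object$wm_max)) {
    wm <- which(item_schema()$scale == "nonnegative_continuous")
    if (ncol(out) == 54L) out[, wm] <- out[, wm] * object$wm_max
  }
  out
}

#' @export
print.cgmvae <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0("CGMVAE: D = %d latent dims, K = %d components, ",
                     "hidden %d x %d\n"),
              cf$latent_dim, cf$n_components, cf$hidden_dim, cf$n_blocks))
  cat(sprintf("  beta %.3f, free bits %.3f, lr %.2e, clip %.3f\n",
              cf$beta, cf$free_bits, cf$learning_rate, cf$grad_clip))
  cat(sprintf("  best validation loss %.4f at epoch %d/%d\n",
              x$best_val, x$best_epoch, cf$epochs))
  invisible(x)
}

#' @export
plot.cgmvae <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_total, h$val_total), type = "l",
                    lty = 1:2, xlab = "epoch", ylab = "total loss",
                    main = "CGMVAE training history", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Random hyperparameter search
#'
#' Seeded random search over latent dimension, component count, learning
#' rate (log-uniform) and free-bits threshold, scored by best validation
#' loss; the winning configuration is refit on the full data.
#'
#' @param data training data (as for [cgmvae()]).
#' @param n_trials number of sampled configurations (>= 1).
#' @param space list of ranges: `latent_dim`, `n_components` (integer
#'   ranges), `learning_rate` (log-uniform bounds), `free_bits` (uniform
#'   bounds).
#' @param config base configuration supplying all other settings.
#' @param seed search seed.
#' @return List with `best_config`, `best_fit` (refit on all data),
#'   `trials` (data frame of sampled settings and validation losses).
#' @export
cgmvae_search <- function(data, n_trials = 10L,
                          space = list(latent_dim = c(4L, 64L),
                                       n_components = c(2L, 15L),
                                       learning_rate = c(1e-4, 1e-2),
                                       free_bits = c(0.01, 0.2)),
                          config = cgmvae_config(), seed = 1L) {
  stopifnot(n_trials >= 1L)
  sample_range <- function(r, n) {
    if (r[1L] == r[2L]) rep(r[1L], n) else sample(r[1L]:r[2L], n,
                                                  replace = TRUE)
  }
  draws <- with_seed(seed, data.frame(
    latent_dim = sample_range(space$latent_dim, n_trials),
    n_components = sample_range(space$n_components, n_trials),
    learning_rate = exp(stats::runif(n_trials,
                                     log(space$learning_rate[1L]),
                                     log(space$learning_rate[2L]))),
    free_bits = stats::runif(n_trials, space$free_bits[1L],
                             space$free_bits[2L]),
    trial_seed = sample.int(1e6, n_trials)))
  draws$val_loss <- NA_real_
  best <- NULL
  for (i in seq_len(n_trials)) {
    cf <- config
    cf$latent_dim <- draws$latent_dim[i]
    cf$n_components <- draws$n_components[i]
    cf$learning_rate <- draws$learning_rate[i]
    cf$free_bits <- draws$free_bits[i]
    cf$seed <- draws$trial_seed[i]
    fit <- tryCatch(cgmvae(data, cf), error = function(e) NULL)
    if (is.null(fit)) next
    draws$val_loss[i] <- fit$best_val
    if (is.null(best) || fit$best_val < best$val) {
      best <- list(config = cf, val = fit$best_val)
    }
  }
  if (is.null(best)) stop("all hyperparameter trials failed", call. = FALSE)
  final <- cgmvae(data, best$config)
  list(best_config = best$config, best_fit = final, trials = draws)
}
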