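## Factor mixture model fitting (EM) and the classed model object.

## Resolve an input object into an item matrix plus scale bookkeeping.
## Accepts a data frame following the instrument schema (participant_id /
## age columns optional) or a plain numeric matrix with `binary` either
## given or auto-detected (columns whose values are all 0/1).
resolve_items <- function(data, binary = NULL) {
  if (inherits(data, "cogmix_sim")) data <- data$data
  if (is.data.frame(data)) {
    sch <- item_schema()
    if (all(sch$name %in% names(data))) {
      X <- as.matrix(data[, sch$name])
      bin <- sch$scale == "binary"
      return(list(X = X, bin_idx = which(bin), cont_idx = which(!bin),
                  age = if ("age" %in% names(data)) data$age else NULL))
    }
    data <- as.matrix(data[, setdiff(names(data),
                                     c("participant_id", "age"))])
  }
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("item data must be numeric", call. = FALSE)
  if (is.null(binary)) {
    binary <- apply(X, 2L, function(v) all(v %in% c(0, 1)))
  }
  list(X = X, bin_idx = which(binary), cont_idx = which(!binary),
       age = NULL)
}

## Assemble a parameter list; minimal validation.
new_fmm_params <- function(tau, Lambda, alpha, Psi = NULL, sigma2 = NULL,
                           pi = NULL, gamma0 = NULL, gamma1 = NULL) {
  structure(list(tau = tau, Lambda = as.matrix(Lambda),
                 alpha = as.matrix(alpha), Psi = Psi, sigma2 = sigma2,
                 pi = pi, gamma0 = gamma0, gamma1 = gamma1),
            class = "fmm_params")
}

#' Marginal log-likelihood of a factor mixture model
#'
#' For the degenerate-factor variant the within-class density is evaluated
#' at the class factor mean (no integration); otherwise the factor is
#' integrated out by Gauss-Hermite quadrature (21 nodes for one factor,
#' 9 per dimension for two or three, Monte Carlo beyond). Class weights are
#' person-specific when the concomitant covariate model is active.
#'
#' @param data item responses (schema data frame or numeric matrix).
#' @param params an `fmm_params` list (`tau`, `Lambda`, `alpha`, optionally
#'   `Psi`, `sigma2`, and `pi` or `gamma0`/`gamma1`).
#' @param spec an [fmm_spec()].
#' @param covariate centered age-bin code vector (required when
#'   `spec$covariate` is `TRUE`).
#' @param binary optional logical vector flagging binary columns when
#'   `data` is a plain matrix.
#' @return The observed-data log-likelihood (scalar).
#' @export
fmm_loglik <- function(data, params, spec, covariate = NULL, binary = NULL) {
  d <- resolve_items(data, binary)
  if (!is.null(params$Psi) && spec$variant == "FMM2") {
    for (k in seq_len(spec$K)) {
      Psi_k <- matrix(params$Psi[k, , ], spec$F, spec$F)
      ev <- eigen(Psi_k, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev < -1e-10)) {
        stop("Psi must be positive semidefinite", call. = FALSE)
      }
    }
  }
  cells <- fmm_cells(params, spec)
  LL <- cell_loglik(d$X, d$bin_idx, d$cont_idx, params, cells$H)
  CLL <- class_loglik(LL, cells, spec$K)
  logPi <- log_class_prior(params, spec, covariate, nrow(d$X))
  sum(logsumexp_rows(logPi + CLL))
}

#' E-step: posterior class responsibilities
#'
#' \eqn{r_{ik} \propto P(\mathrm{class}\,k \mid c_i)\, P(x_i \mid
#' \mathrm{class}\,k)}, computed on the log scale with log-sum-exp so that
#' finite inputs never produce NaN.
#'
#' @inheritParams fmm_loglik
#' @return n x K matrix with rows summing to 1.
#' @export
e_step <- function(data, params, spec, covariate = NULL, binary = NULL) {
  d <- resolve_items(data, binary)
  cells <- fmm_cells(params, spec)
  LL <- cell_loglik(d$X, d$bin_idx, d$cont_idx, params, cells$H)
  CLL <- class_loglik(LL, cells, spec$K)
  logPi <- log_class_prior(params, spec, covariate, nrow(d$X))
  softmax_rows(logPi + CLL)
}

#' Information criteria
#'
#' `BIC = -2 loglik + p log n`; `AIC = -2 loglik + 2 p`.
#'
#' @param loglik fitted log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size.
#' @return Named numeric vector with elements `BIC` and `AIC`.
#' @export
information_criteria <- function(loglik, n_params, n) {
  stopifnot(n >= 1)
  c(BIC = -2 * loglik + n_params * log(n),
    AIC = -2 * loglik + 2 * n_params)
}

## Free-parameter count per specification (identification constraints
## deducted; mixing model counted as 2(K-1) with covariate, K-1 without).
count_params <- function(spec, J, n_bin, n_cont) {
  K <- spec$K; F <- spec$F
  mix <- if (K == 1L) 0L else if (spec$covariate) 2L * (K - 1L) else K - 1L
  meas <- switch(spec$variant,
    FMM1 = J + J * F + K * F - 2L * F,
    FMM2 = J + J * F - F + K * F - F + K * F * (F + 1L) / 2L,
    FA   = J + J * F - F * (F - 1L) / 2L)
  meas + n_cont + mix
}

## Identification transforms (log-likelihood invariant reparameterizations).
identify_fmm1 <- function(params, wbar) {
  alpha <- params$alpha
  for (f in seq_len(ncol(alpha))) {
    m <- sum(wbar * alpha[, f])
    s <- sqrt(sum(wbar * (alpha[, f] - m)^2))
    params$tau <- params$tau + params$Lambda[, f] * m
    if (s > 1e-8) {
      alpha[, f] <- (alpha[, f] - m) / s
      params$Lambda[, f] <- params$Lambda[, f] * s
    } else {
      alpha[, f] <- alpha[, f] - m
    }
  }
  params$alpha <- alpha
  params
}

identify_fmm2 <- function(params, wbar, anchors) {
  alpha <- params$alpha
  F <- ncol(alpha)
  for (f in seq_len(F)) {
    m <- sum(wbar * alpha[, f])
    params$tau <- params$tau + params$Lambda[, f] * m
    alpha[, f] <- alpha[, f] - m
    ## rescale only when the anchor loading is well away from zero;
    ## dividing by a tiny loading would blow the remaining loadings up
    s <- params$Lambda[anchors[f], f]
    if (abs(s) > 0.2) {
      params$Lambda[, f] <- params$Lambda[, f] / s
      alpha[, f] <- alpha[, f] * s
      params$Psi[, f, ] <- params$Psi[, f, ] * s
      params$Psi[, , f] <- params$Psi[, , f] * s
    }
  }
  params$alpha <- alpha
  params
}

## Initial parameters from (possibly perturbed) k-means responsibilities.
init_fmm_params <- function(X, bin_idx, cont_idx, spec, perturb) {
  n <- nrow(X); J <- ncol(X); K <- spec$K; F <- spec$F
  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  if (K > 1L) {
    km <- tryCatch(stats::kmeans(Xs, centers = K, nstart = 2L),
                   error = function(e) NULL)
    lab <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
    R <- matrix(0.1 / max(K - 1L, 1L), n, K)
    R[cbind(seq_len(n), lab)] <- 0.9
    if (perturb > 0) {
      R <- R + matrix(stats::runif(n * K, 0, perturb), n, K)
      R <- R / rowSums(R)
    }
  } else {
    R <- matrix(1, n, 1L)
  }
  ## crude factor score: standardized mean of standardized items
  score <- rowMeans(Xs)
  score <- (score - mean(score)) / max(stats::sd(score), 1e-8)
  tau <- numeric(J)
  tau[bin_idx] <- stats::qlogis(pmin(pmax(colMeans(
    X[, bin_idx, drop = FALSE]), 0.02), 0.98))
  if (length(cont_idx)) tau[cont_idx] <- colMeans(X[, cont_idx, drop = FALSE])
  Lambda <- matrix(stats::rnorm(J * F, 0, 0.1), J, F)
  Lambda[, 1L] <- Lambda[, 1L] + 0.5
  alpha <- matrix(0, K, F)
  for (k in seq_len(K)) {
    alpha[k, 1L] <- stats::weighted.mean(score, R[, k])
  }
  if (F > 1L) alpha[, -1L] <- stats::rnorm(K * (F - 1L), 0, 0.3)
  if (spec$variant == "FA") alpha[] <- 0
  ord <- order(alpha[, 1L])
  alpha <- alpha[ord, , drop = FALSE]
  R <- R[, ord, drop = FALSE]
  Psi <- NULL
  if (spec$variant %in% c("FMM2", "FA")) {
    Psi <- array(0, c(K, F, F))
    for (k in seq_len(K)) Psi[k, , ] <- diag(F)
  }
  sigma2 <- if (length(cont_idx)) {
    pmax(apply(X[, cont_idx, drop = FALSE], 2L, stats::var), 1e-3)
  } else {
    numeric(0)
  }
  list(params = new_fmm_params(tau, Lambda, alpha, Psi, sigma2,
                               pi = rep(1 / K, K),
                               gamma0 = rep(0, K - 1L),
                               gamma1 = rep(0, K - 1L)),
       R = R)
}

## Parameter warm start from a latent class solution (one factor): class
## profiles on the link scale are reduced to a one-dimensional score by a
## rank-1 least-squares fit, giving thresholds, loadings and class means
## that reproduce the LCA class profiles as closely as a single factor can.
lca_warm_params <- function(lca, X, bin_idx, cont_idx, code, covariate) {
  K <- lca$K
  Y <- matrix(0, ncol(X), K)
  Y[bin_idx, ] <- stats::qlogis(pmin(pmax(lca$params$p, 0.02), 0.98))
  if (length(cont_idx)) Y[cont_idx, ] <- lca$params$mu
  tau <- rowMeans(Y)
  Yc <- Y - tau
  sv <- svd(Yc)
  lambda <- sv$u[, 1L] * sv$d[1L]
  alpha <- sv$v[, 1L]
  ## orient so class order matches ascending factor mean
  if (is.unsorted(alpha)) { alpha <- -alpha; lambda <- -lambda }
  sigma2 <- if (length(cont_idx)) {
    pmax(rowMeans(lca$params$sigma2), 1e-4)
  } else {
    numeric(0)
  }
  g <- if (covariate && K > 1L) {
    withCallingHandlers(m_step_multinomial(lca$responsibilities, code),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else {
    list(gamma0 = rep(0, K - 1L), gamma1 = rep(0, K - 1L))
  }
  new_fmm_params(tau, matrix(lambda), matrix(alpha, K, 1L),
                 sigma2 = sigma2, pi = lca$params$pi,
                 gamma0 = g$gamma0, gamma1 = g$gamma1)
}

## Single EM run from one initialization (or a supplied warm start).
fit_fmm_once <- function(X, bin_idx, cont_idx, spec, code, perturb,
                         tol, max_iter, init_params = NULL) {
  n <- nrow(X)
  params <- if (is.null(init_params)) {
    init_fmm_params(X, bin_idx, cont_idx, spec, perturb)$params
  } else {
    init_params
  }
  anchors <- seq_len(spec$F)   # anchor items for FMM2 factor scales
  ll_hist <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cells <- fmm_cells(params, spec)
    LL <- cell_loglik(X, bin_idx, cont_idx, params, cells$H)
    CLL <- class_loglik(LL, cells, spec$K)
    logPi <- log_class_prior(params, spec, code, n)
    ll <- sum(logsumexp_rows(logPi + CLL))
    if (!is.finite(ll)) break
    ll_hist <- c(ll_hist, ll)
    if (it > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    ## joint posterior weights over cells
    logW <- logPi[, cells$cls, drop = FALSE] +
      matrix(cells$logw, n, length(cells$logw), byrow = TRUE) + LL
    W <- softmax_rows(logW)
    R <- softmax_rows(logPi + CLL)
    ss <- cell_suffstats(X, W)
    ## measurement update (skips loadings when factor is fixed at 0 with K=1
    ## classes and no spread: FMM1 K=1 has eta == alpha == 0 identically)
    upd <- update_binary_items(params$tau, params$Lambda, bin_idx,
                               cells$H, ss$Wc, ss$S)
    params$tau <- upd$tau; params$Lambda <- upd$Lambda
    updc <- update_cont_items(params$tau, params$Lambda, params$sigma2,
                              cont_idx, cells$H, ss$Wc, ss$S, ss$T2)
    params$tau <- updc$tau; params$Lambda <- updc$Lambda
    params$sigma2 <- updc$sigma2
    ## structural update
    if (spec$variant == "FMM1") {
      Sr <- crossprod(X, R); Wr <- colSums(R)
      for (k in seq_len(spec$K)) {
        a0 <- params$alpha[k, ]
        fn <- function(a) -alpha_objective(a, params$tau, params$Lambda,
                                           params$sigma2, bin_idx, cont_idx,
                                           Sr[, k], Wr[k])$value
        gr <- function(a) -alpha_objective(a, params$tau, params$Lambda,
                                           params$sigma2, bin_idx, cont_idx,
                                           Sr[, k], Wr[k])$grad
        opt <- tryCatch(stats::optim(a0, fn, gr, method = "BFGS",
                                     control = list(maxit = 50)),
                        error = function(e) list(par = a0))
        params$alpha[k, ] <- opt$par
      }
    } else if (spec$variant == "FMM2") {
      Q <- length(cells$logw) / spec$K
      for (k in seq_len(spec$K)) {
        idx <- which(cells$cls == k)
        wk <- ss$Wc[idx]
        tot <- sum(wk)
        if (tot < 1e-8) next
        mu <- colSums(cells$H[idx, , drop = FALSE] * wk) / tot
        Dv <- sweep(cells$H[idx, , drop = FALSE], 2L, mu)
        Ps <- crossprod(Dv * wk, Dv) / tot
        params$alpha[k, ] <- mu
        params$Psi[k, , ] <- Ps   # may collapse to the ψ = 0 boundary
      }
    }
    ## mixing update
    if (spec$K > 1L) {
      if (spec$covariate) {
        ms <- withCallingHandlers(
          m_step_multinomial(R, code),
          warning = function(w) invokeRestart("muffleWarning"))
        params$gamma0 <- ms$gamma0
        params$gamma1 <- ms$gamma1
      } else {
        params$pi <- pmax(colMeans(R), 1e-8)
        params$pi <- params$pi / sum(params$pi)
      }
    }
    ## identification (exact reparameterization; loglik unchanged)
    wbar <- colMeans(R)
    if (spec$variant == "FMM1" && spec$K > 1L) {
      params <- identify_fmm1(params, wbar)
    } else if (spec$variant == "FMM2") {
      params <- identify_fmm2(params, wbar, anchors)
    }
  }
  list(params = params, loglik = if (length(ll_hist)) ll_hist[length(ll_hist)]
       else -Inf,
       ll_hist = ll_hist, converged = converged, n_iter = length(ll_hist))
}

#' Fit a factor mixture model by EM
#'
#' Alternates an exact E-step with block-coordinate M-steps: per-item
#' Newton updates of the invariant thresholds and loadings, class factor
#' means by quasi-Newton (degenerate-factor variant) or quadrature moment
#' updates (free factor covariances), and a multinomial-logistic update of
#' the concomitant class-membership model on the centered age-bin code.
#' The best of `restarts` seeded initializations is kept and classes are
#' relabeled so first-factor means ascend (class 1 = lowest performing).
#'
#' @param data item responses: a schema data frame (an `age` column
#'   supplies the covariate via [bin_ages()]), a `cogmix_sim`, or a plain
#'   numeric matrix.
#' @param spec an [fmm_spec()].
#' @param covariate optional centered age-bin code; derived from the data's
#'   `age` column when absent and `spec$covariate` is `TRUE`.
#' @param restarts number of EM restarts (k-means initialization plus
#'   random perturbation).
#' @param seed integer seed controlling all randomness.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param binary optional logical vector for plain-matrix input.
#' @param init optional `fmm_params` warm start, run in addition to the
#'   seeded restarts. A degenerate-factor (`Psi = 0`) parameter set may be
#'   supplied for the free-covariance variant; a tiny within-class
#'   variance is substituted so the constrained solution is the starting
#'   point.
#' @return An object of class `fmm_fit` with components `params`,
#'   `loglik`, `n_params`, `BIC`, `AIC`, `responsibilities`, `spec`,
#'   `converged`, `n_restarts_used` and the per-iteration `ll_hist` of the
#'   winning run.
#' @examples
#' sim <- simulate_fmm1(300, seed = 1)
#' fit <- fit_fmm(sim, fmm_spec(K = 2, F = 1), restarts = 2, seed = 1)
#' coef(fit)$alpha
#' @export
fit_fmm <- function(data, spec = fmm_spec(), covariate = NULL,
                    restarts = 10L, seed = NULL, tol = 1e-6,
                    max_iter = 500L, binary = NULL, init = NULL) {
  if (inherits(data, "cogmix_sim") && is.null(covariate)) {
    covariate <- data$code
  }
  d <- resolve_items(data, binary)
  if (is.null(covariate) && spec$covariate && !is.null(d$age)) {
    covariate <- bin_ages(d$age)$code
  }
  if (spec$covariate && is.null(covariate)) {
    stop("spec requests the concomitant model but no covariate is available",
         call. = FALSE)
  }
  if (spec$K == 1L && spec$variant == "FMM1") {
    ## single class: the degenerate factor carries no information, so the
    ## model coincides with plain factor analysis
    spec <- fmm_spec(1L, spec$F, "FA", covariate = FALSE)
  }
  X <- d$X
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perturb <- if (r == 1L) 0 else 0.5
      fit <- tryCatch(
        fit_fmm_once(X, d$bin_idx, d$cont_idx, spec, covariate,
                     perturb, tol, max_iter),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$loglik) &&
          (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    warm <- list()
    if (!is.null(init)) warm <- c(warm, list(init))
    if (spec$variant == "FMM1" && spec$K > 1L && spec$F == 1L &&
        is.null(init)) {
      ## latent-class warm start: rank-1 reduction of the LCA profiles
      lca <- tryCatch(fit_lca(X, spec$K, seed = NULL, restarts = 2L,
                              binary = seq_len(ncol(X)) %in% d$bin_idx),
                      error = function(e) NULL)
      if (!is.null(lca)) {
        wp <- tryCatch(lca_warm_params(lca, X, d$bin_idx, d$cont_idx,
                                       covariate, spec$covariate),
                       error = function(e) NULL)
        if (!is.null(wp)) warm <- c(warm, list(wp))
      }
    }
    if (spec$variant == "FMM2" && is.null(init)) {
      ## warm start at the constrained (degenerate-factor) solution with a
      ## tiny within-class variance: the free-covariance model nests it,
      ## so EM from here can only do at least as well
      f1 <- tryCatch(
        fit_fmm(X, fmm_spec(spec$K, spec$F, "FMM1", spec$covariate),
                covariate = covariate,
                restarts = max(2L, restarts %/% 2L), seed = NULL,
                tol = tol, max_iter = max_iter,
                binary = seq_len(ncol(X)) %in% d$bin_idx),
        error = function(e) NULL)
      if (!is.null(f1)) warm <- c(warm, list(f1$params))
    }
    for (wp in warm) {
      if (spec$variant == "FMM2") {
        if (is.null(wp$Psi)) {
          ## start on the ψ = 0 boundary: evaluated exactly as the
          ## degenerate model, so the warm run never scores below it
          wp$Psi <- array(0, c(spec$K, spec$F, spec$F))
        }
      }
      fit <- tryCatch(
        fit_fmm_once(X, d$bin_idx, d$cont_idx, spec, covariate, 0,
                     tol, max_iter, init_params = wp),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$loglik) &&
          (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best) || !is.finite(best$loglik)) {
    stop("no EM restart converged to a finite log-likelihood; ",
         "check the data for degenerate columns", call. = FALSE)
  }
  params <- best$params
  ## relabel classes by ascending first-factor mean
  if (spec$K > 1L) {
    ord <- order(params$alpha[, 1L])
    params$alpha <- params$alpha[ord, , drop = FALSE]
    if (!is.null(params$Psi)) params$Psi <- params$Psi[ord, , , drop = FALSE]
    if (!is.null(params$pi)) params$pi <- params$pi[ord]
  }
  R <- e_step(X, params, spec, covariate, binary = seq_len(ncol(X)) %in%
                d$bin_idx)
  if (spec$covariate && spec$K > 1L) {
    ms <- withCallingHandlers(m_step_multinomial(R, covariate),
                              warning = function(w)
                                invokeRestart("muffleWarning"))
    params$gamma0 <- ms$gamma0
    params$gamma1 <- ms$gamma1
  }
  ll <- fmm_loglik(X, params, spec, covariate,
                   binary = seq_len(ncol(X)) %in% d$bin_idx)
  np <- count_params(spec, ncol(X), length(d$bin_idx), length(d$cont_idx))
  ic <- information_criteria(ll, np, nrow(X))
  structure(list(params = params, spec = spec, loglik = ll,
                 n_params = np, BIC = unname(ic["BIC"]),
                 AIC = unname(ic["AIC"]), responsibilities = R,
                 covariate = covariate, converged = best$converged,
                 ll_hist = best$ll_hist,
                 n_restarts_used = restarts, n = nrow(X),
                 bin_idx = d$bin_idx, cont_idx = d$cont_idx),
            class = "fmm_fit")
}

#' Expected response profile per class and item
#'
#' Binary items: \eqn{\mathrm{logit}^{-1}(\tau_j + \lambda_j' \alpha_k)};
#' continuous items: the linear predictor mapped back to its scale (clipped
#' to \eqn{[0,1]} for the unit-interval items, floored at 0 for the
#' nonnegative score).
#'
#' @param object an `fmm_fit` or `fmm_params` (with `spec`/index info for
#'   the latter supplied via `...`).
#' @param ... unused.
#' @return K x J matrix of expected responses.
#' @export
expected_response_profiles <- function(object, ...) {
  if (inherits(object, "fmm_fit")) {
    params <- object$params
    bin_idx <- object$bin_idx
    cont_idx <- object$cont_idx
  } else {
    stop("need an `fmm_fit` object", call. = FALSE)
  }
  eta <- params$alpha %*% t(params$Lambda) +
    matrix(params$tau, nrow(params$alpha), length(params$tau), byrow = TRUE)
  out <- eta
  out[, bin_idx] <- stats::plogis(eta[, bin_idx, drop = FALSE])
  if (length(cont_idx)) {
    sch <- item_schema()
    for (j in cont_idx) {
      nm <- colnames(out)[j]
      sc <- if (!is.null(nm) && nm %in% sch$name) {
        sch$scale[match(nm, sch$name)]
      } else {
        "nonnegative_continuous"
      }
      if (sc == "unit_interval") out[, j] <- pmin(pmax(eta[, j], 0), 1)
      else out[, j] <- pmax(eta[, j], 0)
    }
  }
  colnames(out) <- colnames(params$Lambda) %||% colnames(out)
  out
}

#' Odds ratio from a log-odds coefficient
#'
#' @param b coefficient on the log-odds scale.
#' @return List with `odds_ratio = exp(b)` and
#'   `percent_change = (exp(b) - 1) * 100`.
#' @examples
#' odds_ratio_from_coefficient(-0.963)  # OR ~ 0.382, ~ -61.8%
#' @export
odds_ratio_from_coefficient <- function(b) {
  stopifnot(is.finite(b))
  list(odds_ratio = exp(b), percent_change = (exp(b) - 1) * 100)
}

## ---- S3 methods -----------------------------------------------------------

#' @export
print.fmm_fit <- function(x, ...) {
  cat(sprintf("%s fit: K = %d class(es), F = %d factor(s)%s\n",
              x$spec$variant, x$spec$K, x$spec$F,
              if (x$spec$covariate) " + age-bin concomitant model" else ""))
  cat(sprintf("  logLik %.3f on %d parameters (n = %d)\n",
              x$loglik, x$n_params, x$n))
  cat(sprintf("  BIC %.2f   AIC %.2f   converged: %s\n",
              x$BIC, x$AIC, x$converged))
  if (x$spec$K > 1L) {
    cat("  class factor means (ascending):",
        paste(sprintf("%.3f", x$params$alpha[, 1L]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.fmm_fit <- function(object, ...) {
  p <- object$params
  list(tau = p$tau, Lambda = p$Lambda, alpha = p$alpha, Psi = p$Psi,
       sigma2 = p$sigma2, pi = p$pi, gamma0 = p$gamma0, gamma1 = p$gamma1)
}

#' @export
logLik.fmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
summary.fmm_fit <- function(object, ...) {
  prop <- colMeans(object$responsibilities)
  ors <- if (object$spec$covariate && object$spec$K > 1L) {
    vapply(object$params$gamma1,
           function(b) odds_ratio_from_coefficient(b)$odds_ratio, 0)
  } else {
    NULL
  }
  out <- list(spec = object$spec, loglik = object$loglik, BIC = object$BIC,
              AIC = object$AIC, class_proportions = prop,
              alpha = object$params$alpha, gamma0 = object$params$gamma0,
              gamma1 = object$params$gamma1, odds_ratios = ors,
              converged = object$converged)
  class(out) <- "summary.fmm_fit"
  out
}

#' @export
print.summary.fmm_fit <- function(x, ...) {
  cat(sprintf("%s, K = %d, F = %d\n", x$spec$variant, x$spec$K, x$spec$F))
  cat(sprintf("logLik %.3f  BIC %.2f  AIC %.2f\n", x$loglik, x$BIC, x$AIC))
  cat("class proportions:",
      paste(sprintf("%.1f%%", 100 * x$class_proportions), collapse = ", "),
      "\n")
  if (!is.null(x$odds_ratios)) {
    for (k in seq_along(x$odds_ratios)) {
      cat(sprintf(
        "class %d vs %d: intercept %.3f, age slope %.3f (OR %.3f)\n",
        k, length(x$odds_ratios) + 1L, x$gamma0[k], x$gamma1[k],
        x$odds_ratios[k]))
    }
  }
  invisible(x)
}

#' Posterior predictions from a fitted factor mixture model
#'
#' @param object an `fmm_fit`.
#' @param newdata optional new item responses (defaults to refusing:
#'   responsibilities of the training data are stored on the object).
#' @param covariate centered age-bin code for `newdata`.
#' @param type `"responsibilities"` (posterior class probabilities),
#'   `"class"` (their argmax) or `"factor_score"` (posterior expected
#'   factor score \eqn{\sum_k r_{ik} \alpha_k}, the latent space used for
#'   cluster-quality evaluation).
#' @param ... unused.
#' @export
predict.fmm_fit <- function(object, newdata = NULL, covariate = NULL,
                            type = c("responsibilities", "class",
                                     "factor_score"), ...) {
  type <- match.arg(type)
  R <- if (is.null(newdata)) {
    object$responsibilities
  } else {
    if (inherits(newdata, "cogmix_sim") && is.null(covariate)) {
      covariate <- newdata$code
    }
    e_step(newdata, object$params, object$spec, covariate)
  }
  switch(type,
         responsibilities = R,
         class = max.col(R, ties.method = "first"),
         factor_score = R %*% object$params$alpha)
}

#' Simulate item responses from a fitted degenerate-factor mixture
#'
#' @param object an `fmm_fit` with variant `"FMM1"`.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param n rows per dataset (defaults to the training size).
#' @param covariate centered age-bin codes (recycled training codes by
#'   default).
#' @param ... unused.
#' @export
simulate.fmm_fit <- function(object, nsim = 1, seed = NULL,
                             n = object$n, covariate = object$covariate,
                             ...) {
  if (object$spec$variant != "FMM1") {
    stop("simulate() supports the degenerate-factor variant", call. = FALSE)
  }
  p <- object$params
  sch_bin <- object$bin_idx
  with_seed(seed, {
    replicate(nsim, simplify = FALSE, {
      code <- if (is.null(covariate)) rep(0, n) else
        sample(covariate, n, replace = TRUE)
      P <- if (object$spec$covariate) {
        class_probabilities(code, p$gamma0, p$gamma1)
      } else {
        matrix(p$pi %||% rep(1 / object$spec$K, object$spec$K),
               n, object$spec$K, byrow = TRUE)
      }
      cls <- apply(P, 1L, function(pr) sample.int(length(pr), 1L, prob = pr))
      eta <- matrix(p$tau, n, length(p$tau), byrow = TRUE) +
        p$alpha[cls, , drop = FALSE] %*% t(p$Lambda)
      X <- eta
      X[, sch_bin] <- stats::rbinom(length(eta[, sch_bin]), 1L,
                                    stats::plogis(eta[, sch_bin]))
      if (length(object$cont_idx)) {
        for (idx in seq_along(object$cont_idx)) {
          j <- object$cont_idx[idx]
          X[, j] <- eta[, j] + stats::rnorm(n, 0, sqrt(p$sigma2[idx]))
        }
      }
      list(items = X, class = cls, code = code)
    })
  })
}

#' @export
plot.fmm_fit <- function(x, ...) {
  prof <- expected_response_profiles(x)
  graphics::matplot(t(prof), type = "b", pch = seq_len(nrow(prof)),
                    lty = 1, xlab = "item", ylab = "expected response",
                    main = "Expected response profiles by class", ...)
  graphics::legend("bottomright", legend = paste("class", seq_len(nrow(prof))),
                   col = seq_len(nrow(prof)), pch = seq_len(nrow(prof)),
                   lty = 1, bty = "n")
  invisible(x)
}
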