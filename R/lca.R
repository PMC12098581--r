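## Latent class analysis baseline: class-conditional independent Bernoulli
## (binary items) / Gaussian (continuous items) mixture, closed-form EM.

lca_loglik_parts <- function(X, bin_idx, cont_idx, p, mu, s2, log_pi) {
  n <- nrow(X)
  K <- length(log_pi)
  LL <- matrix(log_pi, n, K, byrow = TRUE)
  if (length(bin_idx)) {
    Xb <- X[, bin_idx, drop = FALSE]
    LL <- LL + Xb %*% log(p) + (1 - Xb) %*% log1p(-p)
  }
  if (length(cont_idx)) {
    Xc <- X[, cont_idx, drop = FALSE]
    quad <- matrix(0, n, K)
    for (k in seq_len(K)) {
      quad[, k] <- colSums((t(Xc) - mu[, k])^2 / s2[, k])
    }
    LL <- LL - 0.5 * (quad +
      matrix(colSums(log(2 * pi * s2)), n, K, byrow = TRUE))
  }
  LL
}

#' Fit a latent class analysis model by EM
#'
#' Class-conditional independence model: Bernoulli response probabilities
#' for binary items, Gaussian means for continuous items. Continuous
#' variances are class-invariant by default (the usual latent-profile
#' default); set `equal_variances = FALSE` to free them per class.
#' Restarts guard against empty-class collapse; the best log-likelihood
#' wins.
#'
#' @inheritParams fit_fmm
#' @param K number of latent classes.
#' @param equal_variances constrain continuous item variances to be equal
#'   across classes.
#' @return An object of class `lca_fit` with `params` (`p`, `mu`,
#'   `sigma2`, `pi`), `loglik`, `n_params`, `BIC`, `AIC`,
#'   `responsibilities`, `converged`.
#' @export
fit_lca <- function(data, K, seed = NULL, restarts = 10L, tol = 1e-8,
                    max_iter = 500L, binary = NULL,
                    equal_variances = TRUE) {
  stopifnot(K >= 1L)
  d <- resolve_items(data, binary)
  X <- d$X
  n <- nrow(X)
  best <- NULL
  one_run <- function(perturb) {
    ## initialize from perturbed global margins
    nb <- length(d$bin_idx); nc <- length(d$cont_idx)
    p <- matrix(pmin(pmax(colMeans(X[, d$bin_idx, drop = FALSE]), 0.05),
                     0.95), nb, K)
    if (nb) {
      p <- pmin(pmax(p + matrix(stats::runif(length(p), -perturb, perturb),
                                nb, K), 0.02), 0.98)
    }
    mu <- matrix(colMeans(X[, d$cont_idx, drop = FALSE]), nc, K)
    if (nc) {
      mu <- mu + matrix(stats::rnorm(length(mu), 0, perturb + 1e-3), nc, K)
    }
    s2 <- matrix(pmax(apply(X[, d$cont_idx, drop = FALSE], 2L, stats::var),
                      1e-3), nc, K)
    pi_k <- rep(1 / K, K)
    ll_old <- -Inf
    ll_hist <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      LL <- lca_loglik_parts(X, d$bin_idx, d$cont_idx, p, mu, s2, log(pi_k))
      ll <- sum(logsumexp_rows(LL))
      if (!is.finite(ll)) break
      ll_hist <- c(ll_hist, ll)
      if (it > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      R <- softmax_rows(LL)
      W <- colSums(R)
      if (any(W < 1e-6)) break            # empty class: restart
      pi_k <- W / n
      if (length(d$bin_idx)) {
        p <- pmin(pmax(crossprod(X[, d$bin_idx, drop = FALSE], R) /
                         rep(W, each = length(d$bin_idx)), 1e-6), 1 - 1e-6)
        dim(p) <- c(length(d$bin_idx), K)
      }
      if (length(d$cont_idx)) {
        Xc <- X[, d$cont_idx, drop = FALSE]
        mu <- crossprod(Xc, R) / rep(W, each = length(d$cont_idx))
        for (k in seq_len(K)) {
          s2[, k] <- pmax(colSums(R[, k] * (t(t(Xc) - mu[, k]))^2) / W[k],
                          1e-4)
        }
        if (equal_variances) {
          pooled <- drop(s2 %*% (W / n))
          s2 <- matrix(pooled, length(d$cont_idx), K)
        }
      }
    }
    list(p = p, mu = mu, s2 = s2, pi = pi_k,
         loglik = if (length(ll_hist)) ll_hist[length(ll_hist)] else -Inf,
         ll_hist = ll_hist, converged = converged)
  }
  with_seed(seed, {
    for (r in seq_len(max(restarts, 1L))) {
      fit <- one_run(if (r == 1L) 0 else 0.25)
      if (is.finite(fit$loglik) &&
          (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("LCA: no restart reached a finite log-likelihood", call. = FALSE)
  }
  ## sort classes by overall expected performance (mean response prob)
  if (K > 1L) {
    score <- colMeans(best$p)
    ord <- order(score)
    best$p <- best$p[, ord, drop = FALSE]
    best$mu <- best$mu[, ord, drop = FALSE]
    best$s2 <- best$s2[, ord, drop = FALSE]
    best$pi <- best$pi[ord]
  }
  LL <- lca_loglik_parts(X, d$bin_idx, d$cont_idx, best$p, best$mu, best$s2,
                         log(best$pi))
  R <- softmax_rows(LL)
  np <- (K - 1L) + K * length(d$bin_idx) +
    K * length(d$cont_idx) +
    (if (equal_variances) 1L else K) * length(d$cont_idx)
  ic <- information_criteria(best$loglik, np, n)
  structure(list(params = list(p = best$p, mu = best$mu, sigma2 = best$s2,
                               pi = best$pi),
                 K = K, loglik = best$loglik, n_params = np,
                 BIC = unname(ic["BIC"]), AIC = unname(ic["AIC"]),
                 responsibilities = R, converged = best$converged,
                 ll_hist = best$ll_hist, n = n),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("LCA fit: K = %d, logLik %.3f, BIC %.2f, AIC %.2f\n",
              x$K, x$loglik, x$BIC, x$AIC))
  invisible(x)
}

#' Fit a one-class full-information factor model
#'
#' Factor analysis for mixed binary/continuous outcomes: standard-normal
#' latent factors integrated out by Gauss-Hermite quadrature, logistic link
#' for binary items, Gaussian for continuous items. Serves as the
#' factor-count baseline of the model ladder.
#'
#' @inheritParams fit_fmm
#' @param F number of factors.
#' @return An `fmm_fit` with variant `"FA"`.
#' @export
fit_fa <- function(data, F = 1L, seed = NULL, restarts = 3L, tol = 1e-6,
                   max_iter = 500L, binary = NULL) {
  fit_fmm(data, fmm_spec(1L, F, "FA", covariate = FALSE),
          covariate = NULL, restarts = restarts, seed = seed, tol = tol,
          max_iter = max_iter, binary = binary)
}
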