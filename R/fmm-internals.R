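## EM internals for the factor mixture models.
##
## The whole EM exploits one structural fact: the latent linear predictor
## tau_j + lambda_j' eta takes only `n_cells` distinct values -- one per
## class for the degenerate-factor variant, one per (class, quadrature
## node) otherwise. E- and M-steps therefore reduce to a handful of
## n x 54 by 54 x n_cells matrix products plus tiny per-item Newton
## solves on cell-level sufficient statistics.

#' Model specification for the factor mixture family
#'
#' @param K number of latent classes (>= 1).
#' @param F number of latent factors (>= 1).
#' @param variant `"FMM1"` (within-class factor covariance fixed at zero,
#'   classes differ only in factor mean), `"FMM2"` (class-specific factor
#'   covariances, freely estimated), or `"FA"` (single class, standard
#'   normal factor). Thresholds and loadings are class-invariant in all
#'   variants.
#' @param covariate whether class membership is modeled by multinomial
#'   logistic regression on the centered age-bin code.
#' @return Object of class `fmm_spec`.
#' @export
fmm_spec <- function(K = 2L, F = 1L,
                     variant = c("FMM1", "FMM2", "FA"),
                     covariate = TRUE) {
  variant <- match.arg(variant)
  K <- as.integer(K); F <- as.integer(F)
  stopifnot(K >= 1L, F >= 1L)
  if (variant == "FA") K <- 1L
  if (K == 1L) covariate <- FALSE
  structure(list(K = K, F = F, variant = variant, covariate = covariate),
            class = "fmm_spec")
}

## Gauss-Hermite rule (probabilists' form) for E[f(Z)], Z ~ N(0, 1):
## nodes z and weights w with sum w = 1. Golub-Welsch via the symmetric
## tridiagonal Jacobi matrix.
gh_rule <- function(n) {
  if (n == 1L) return(list(z = 0, w = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i)
  J[cbind(i + 1L, i)] <- sqrt(i)
  e <- eigen(J, symmetric = TRUE)
  list(z = rev(e$values), w = rev(e$vectors[1L, ]^2))
}

.n_gh_nodes <- function(F) {
  if (F == 1L) 21L else if (F <= 3L) 9L else 0L  # 0 => Monte Carlo
}

## Quadrature/evaluation cells: factor values H (n_cells x F), log prior
## node weight within class, and owning class per cell.
fmm_cells <- function(params, spec, n_mc = 2000L, mc_seed = 7L) {
  K <- spec$K; F <- spec$F
  alpha <- matrix(params$alpha, K, F)
  if (spec$variant == "FMM1") {
    return(list(H = alpha, logw = rep(0, K), cls = seq_len(K)))
  }
  nod <- .n_gh_nodes(F)
  if (nod > 0L) {
    r <- gh_rule(nod)
    grids <- do.call(expand.grid, rep(list(seq_len(nod)), F))
    Z <- matrix(r$z[as.matrix(grids)], ncol = F)
    lw <- rowSums(matrix(log(r$w)[as.matrix(grids)], ncol = F))
  } else {
    Z <- with_seed(mc_seed,
                   matrix(stats::rnorm(n_mc * F), n_mc, F))
    lw <- rep(-log(n_mc), n_mc)
  }
  Hs <- list(); lws <- list(); cls <- list()
  for (k in seq_len(K)) {
    Psi_k <- if (spec$variant == "FA") diag(F) else
      matrix(params$Psi[k, , ], F, F)
    if (spec$variant != "FA" && all(diag(Psi_k) < 1e-9)) {
      ## degenerate component: the exact limit of the quadrature is a
      ## point evaluation at the class mean
      Hs[[k]] <- matrix(alpha[k, ], 1L, F)
      lws[[k]] <- 0
      cls[[k]] <- k
    } else {
      L <- chol(Psi_k + diag(1e-10, F))
      Hs[[k]] <- Z %*% L + matrix(alpha[k, ], nrow(Z), F, byrow = TRUE)
      lws[[k]] <- lw
      cls[[k]] <- rep(k, nrow(Z))
    }
  }
  list(H = do.call(rbind, Hs), logw = unlist(lws), cls = unlist(cls))
}

## Per-cell conditional log-likelihood matrix (n x n_cells).
cell_loglik <- function(X, bin_idx, cont_idx, params, H) {
  n <- nrow(X)
  nc <- nrow(H)
  LL <- matrix(0, n, nc)
  Lam <- matrix(params$Lambda, ncol = ncol(H))
  eta <- matrix(params$tau, length(params$tau), nc) + Lam %*% t(H)  # J x cells
  if (length(bin_idx)) {
    P <- plogis_safe(eta[bin_idx, , drop = FALSE])
    Xb <- X[, bin_idx, drop = FALSE]
    LL <- LL + Xb %*% log(P) + (1 - Xb) %*% log1p(-P)
  }
  if (length(cont_idx)) {
    M <- eta[cont_idx, , drop = FALSE]
    s2 <- params$sigma2
    Xc <- X[, cont_idx, drop = FALSE]
    quad <- matrix(rowSums(sweep(Xc^2, 2L, 1 / s2, `*`)), n, nc) -
      2 * (Xc %*% (M / s2)) +
      matrix(colSums(M^2 / s2), n, nc, byrow = TRUE)
    LL <- LL - 0.5 * (quad + sum(log(2 * pi * s2)))
  }
  LL
}

## n x K log prior class probabilities (person-specific with covariate).
log_class_prior <- function(params, spec, code, n) {
  if (spec$K == 1L) return(matrix(0, n, 1L))
  if (spec$covariate) {
    log(pmax(class_probabilities(code, params$gamma0, params$gamma1), 1e-300))
  } else {
    matrix(log(pmax(params$pi, 1e-300)), n, spec$K, byrow = TRUE)
  }
}

## Marginal per-class log-likelihood (n x K) from the cell matrix.
class_loglik <- function(LL, cells, K) {
  out <- matrix(0, nrow(LL), K)
  for (k in seq_len(K)) {
    idx <- which(cells$cls == k)
    if (length(idx) == 1L) {
      out[, k] <- LL[, idx] + cells$logw[idx]
    } else {
      out[, k] <- logsumexp_rows(sweep(LL[, idx, drop = FALSE], 2L,
                                       cells$logw[idx], `+`))
    }
  }
  out
}

## Cell-level sufficient statistics given joint posterior cell weights.
cell_suffstats <- function(X, W) {
  list(Wc = colSums(W), S = crossprod(X, W), T2 = crossprod(X^2, W))
}

## One Newton update (with per-item step halving) of (tau_j, lambda_j.)
## for all binary items, on cell-level stats. Z = cbind(1, H).
update_binary_items <- function(tau, Lam, bin_idx, H, Wc, S,
                                max_iter = 30L, tol = 1e-9, cap = 12) {
  if (!length(bin_idx)) return(list(tau = tau, Lambda = Lam))
  Z <- cbind(1, H)                       # cells x (1+F)
  Th <- cbind(tau[bin_idx], matrix(Lam[bin_idx, ], length(bin_idx)))
  ## clamp incoming parameters to the box first, so that capping inside
  ## the line search can never undo a zero-length step
  Th[Th > cap] <- cap; Th[Th < -cap] <- -cap
  Sb <- S[bin_idx, , drop = FALSE]       # items x cells
  qfun <- function(Th) {
    P <- plogis_safe(Z %*% t(Th))        # cells x items
    colSums(t(Sb) * log(P) + (Wc - t(Sb)) * log1p(-P))
  }
  qcur <- qfun(Th)
  for (it in seq_len(max_iter)) {
    P <- plogis_safe(Z %*% t(Th))
    R <- t(Sb) - Wc * P                  # cells x items
    G <- crossprod(Z, R)                 # (1+F) x items
    step <- matrix(0, nrow(Th), ncol(Th))
    for (j in seq_len(nrow(Th))) {
      wpq <- Wc * P[, j] * (1 - P[, j])
      Hm <- crossprod(Z * wpq, Z)
      step[j, ] <- tryCatch(solve(Hm + diag(1e-10, ncol(Z)), G[, j]),
                            error = function(e) rep(0, ncol(Z)))
    }
    scl <- rep(1, nrow(Th))
    halvings <- 0L
    repeat {
      Tn <- Th + step * scl
      Tn[Tn > cap] <- cap; Tn[Tn < -cap] <- -cap
      qn <- qfun(Tn)
      worse <- qn < qcur - 1e-12
      halvings <- halvings + 1L
      if (!any(worse) || halvings > 60L) break
      scl[worse] <- scl[worse] / 2
    }
    ## never accept a worse point (guarantees the M-step ascends)
    worse <- qn < qcur
    if (any(worse)) {
      Tn[worse, ] <- Th[worse, ]
      qn[worse] <- qcur[worse]
    }
    moved <- max(abs(Tn - Th))
    Th <- Tn; qcur <- qn
    if (moved < tol) break
  }
  tau[bin_idx] <- Th[, 1L]
  Lam[bin_idx, ] <- Th[, -1L, drop = FALSE]
  list(tau = tau, Lambda = Lam)
}

## Closed-form weighted least squares for the continuous items.
update_cont_items <- function(tau, Lam, sigma2, cont_idx, H, Wc, S, T2,
                              s2_floor = 1e-4) {
  if (!length(cont_idx)) {
    return(list(tau = tau, Lambda = Lam, sigma2 = sigma2))
  }
  Z <- cbind(1, H)
  A <- crossprod(Z * Wc, Z)
  B <- crossprod(Z, t(S[cont_idx, , drop = FALSE]))  # (1+F) x items
  Th <- tryCatch(solve(A + diag(1e-10, ncol(Z)), B),
                 error = function(e) NULL)
  if (is.null(Th)) return(list(tau = tau, Lambda = Lam, sigma2 = sigma2))
  W_tot <- sum(Wc)
  for (idx in seq_along(cont_idx)) {
    j <- cont_idx[idx]
    th <- Th[, idx]
    rss <- sum(T2[j, ]) - 2 * sum(th * B[, idx]) + drop(th %*% A %*% th)
    tau[j] <- th[1L]
    Lam[j, ] <- th[-1L]
    sigma2[idx] <- max(rss / W_tot, s2_floor)
  }
  list(tau = tau, Lambda = Lam, sigma2 = sigma2)
}

## Expected complete-data objective for a candidate class mean `a` (FMM1),
## with gradient; used by the structural M-step.
alpha_objective <- function(a, tau, Lam, sigma2, bin_idx, cont_idx,
                            S_k, W_k) {
  eta <- tau + drop(Lam %*% a)
  val <- 0; grad <- rep(0, length(a))
  if (length(bin_idx)) {
    p <- plogis_safe(eta[bin_idx])
    s <- S_k[bin_idx]
    val <- val + sum(s * log(p) + (W_k - s) * log1p(-p))
    grad <- grad + drop(crossprod(Lam[bin_idx, , drop = FALSE], s - W_k * p))
  }
  if (length(cont_idx)) {
    m <- eta[cont_idx]
    s <- S_k[cont_idx]
    ## quadratic part of the Gaussian expected loglik in m
    val <- val - 0.5 * sum((W_k * m^2 - 2 * m * s) / sigma2)
    grad <- grad + drop(crossprod(Lam[cont_idx, , drop = FALSE],
                                  (s - W_k * m) / sigma2))
  }
  list(value = val, grad = grad)
}

#' Concomitant-model M-step: weighted multinomial logistic regression
#'
#' Maximizes the expected complete-data multinomial log-likelihood
#' \eqn{\sum_i \sum_k r_{ik} \log p_k(c_i)} over intercepts and slopes of
#' the class-membership model (reference class = last) by Newton's method
#' with step halving. Under (quasi-)separation, coefficients are capped at
#' +/-15 with a warning.
#'
#' @param resp n x K responsibility matrix, rows summing to 1.
#' @param code centered age-bin code per person.
#' @param max_iter,tol Newton controls.
#' @return List with `gamma0`, `gamma1` (length `K - 1`) and the achieved
#'   expected log-likelihood `value`.
#' @export
m_step_multinomial <- function(resp, code, max_iter = 100L, tol = 1e-12) {
  resp <- as.matrix(resp)
  K <- ncol(resp)
  if (any(abs(rowSums(resp) - 1) > 1e-6)) {
    stop("responsibility rows must sum to 1", call. = FALSE)
  }
  if (K == 1L) return(list(gamma0 = numeric(0), gamma1 = numeric(0),
                           value = 0))
  cap <- 15
  Xd <- cbind(1, code)                    # n x 2
  B <- matrix(0, K - 1L, 2L)              # coefficients, ref = class K
  obj <- function(B) {
    P <- class_probabilities(code, B[, 1L], B[, 2L])
    sum(resp * log(pmax(P, 1e-300)))
  }
  cur <- obj(B)
  capped <- FALSE
  for (it in seq_len(max_iter)) {
    P <- class_probabilities(code, B[, 1L], B[, 2L])
    ## gradient: for k < K, sum_i (r_ik - p_ik) x_i; as.vector stacks the
    ## 2 x (K-1) matrix column-major, i.e. per class, matching the blocks
    G <- crossprod(Xd, resp[, -K, drop = FALSE] - P[, -K, drop = FALSE])
    gv <- as.vector(G)
    d <- 2L * (K - 1L)
    Hm <- matrix(0, d, d)
    for (k in seq_len(K - 1L)) {
      for (l in seq_len(K - 1L)) {
        wkl <- P[, k] * ((k == l) - P[, l])
        Hm[(2 * k - 1):(2 * k), (2 * l - 1):(2 * l)] <-
          -crossprod(Xd * wkl, Xd)
      }
    }
    step <- tryCatch(solve(-Hm + diag(1e-10, d), gv),
                     error = function(e) rep(0, d))
    scl <- 1
    repeat {
      Bn <- B + matrix(step * scl, K - 1L, 2L, byrow = TRUE)
      over <- abs(Bn) > cap
      if (any(over)) { Bn[over] <- sign(Bn[over]) * cap; capped <- TRUE }
      nxt <- obj(Bn)
      if (nxt >= cur - 1e-12 || scl < 1e-6) break
      scl <- scl / 2
    }
    if (nxt < cur) break                  # no ascent step found: stop
    moved <- max(abs(Bn - B))
    B <- Bn; cur <- nxt
    if (moved < tol) break
  }
  if (capped) {
    warning("multinomial M-step: coefficients capped at +/-15 ",
            "(responsibilities nearly separated)", call. = FALSE)
  }
  list(gamma0 = B[, 1L], gamma1 = B[, 2L], value = cur)
}
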