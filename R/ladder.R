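## Stepwise model ladder: LCA baselines over a class grid, FA baselines
## over a factor grid, then both factor-mixture variants over the
## class x factor grid; comparison by BIC (AIC reported alongside).

#' Run the model ladder and select by BIC
#'
#' Fits LCA models over `class_grid`, FA models over `factor_grid`, then
#' FMM-1 and FMM-2 over the product grid, and returns the comparison table
#' with the BIC winner among converged fits. With
#' `bound_by_baselines = TRUE` the mixture grids are truncated at the
#' BIC-optimal LCA class count (never below 2) and FA factor count, the
#' stopping heuristic of the stepwise procedure.
#'
#' @inheritParams fit_fmm
#' @param class_grid integer vector of class counts to explore.
#' @param factor_grid integer vector of factor counts to explore.
#' @param bound_by_baselines truncate the FMM grids at the baseline optima.
#' @param restarts EM restarts per cell.
#' @param keep_fits retain every fitted object (memory-heavy); the winner
#'   is always retained.
#' @return Object of class `fmm_ladder`: a list with `table` (data frame of
#'   model, K, F, loglik, n_params, BIC, AIC, converged), `winner` (row of
#'   the winning spec) and `winner_fit`.
#' @export
model_ladder <- function(data, covariate = NULL, class_grid = 1:3,
                         factor_grid = 1:2, seed = NULL, restarts = 3L,
                         bound_by_baselines = FALSE, tol = 1e-6,
                         max_iter = 100L, keep_fits = FALSE) {
  stopifnot(length(class_grid) >= 1L, length(factor_grid) >= 1L)
  if (inherits(data, "cogmix_sim") && is.null(covariate)) {
    covariate <- data$code
  }
  rows <- list()
  fits <- list()
  best_fit <- NULL
  best_bic <- Inf
  add_row <- function(model, K, F, fit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, K = K, F = F,
      loglik = fit$loglik, n_params = fit$n_params,
      BIC = fit$BIC, AIC = fit$AIC, converged = fit$converged,
      stringsAsFactors = FALSE)
    if (fit$converged && fit$BIC < best_bic) {
      best_bic <<- fit$BIC
      best_fit <<- fit
    }
    key <- sprintf("%s_K%d_F%d", model, K, F)
    if (keep_fits) fits[[key]] <<- fit
    key
  }
  seeds <- with_seed(seed, sample.int(1e6, 2L + length(class_grid) +
                                        length(factor_grid) +
                                        2L * length(class_grid) *
                                        length(factor_grid)))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  for (K in class_grid) {
    fit <- tryCatch(fit_lca(data, K, seed = next_seed(),
                            restarts = restarts),
                    error = function(e) NULL)
    if (!is.null(fit)) add_row("LCA", K, NA_integer_, fit)
  }
  for (F in factor_grid) {
    fit <- tryCatch(fit_fa(data, F, seed = next_seed(), restarts = restarts,
                           tol = tol, max_iter = max_iter),
                    error = function(e) NULL)
    if (!is.null(fit)) add_row("FA", NA_integer_, F, fit)
  }
  tab0 <- do.call(rbind, rows)
  kmax <- max(class_grid)
  fmax <- max(factor_grid)
  if (bound_by_baselines) {
    lca_rows <- tab0[tab0$model == "LCA" & tab0$converged, , drop = FALSE]
    fa_rows <- tab0[tab0$model == "FA" & tab0$converged, , drop = FALSE]
    if (nrow(lca_rows)) kmax <- max(2L, lca_rows$K[which.min(lca_rows$BIC)])
    if (nrow(fa_rows)) fmax <- fa_rows$F[which.min(fa_rows$BIC)]
  }
  for (variant in c("FMM1", "FMM2")) {
    for (K in class_grid[class_grid <= kmax]) {
      for (F in factor_grid[factor_grid <= fmax]) {
        sd_i <- next_seed()
        if (K == 1L) next                  # K = 1 duplicates the FA baseline
        fit <- tryCatch(
          fit_fmm(data, fmm_spec(K, F, variant,
                                 covariate = !is.null(covariate)),
                  covariate = covariate, restarts = restarts, seed = sd_i,
                  tol = tol, max_iter = max_iter),
          error = function(e) NULL)
        if (is.null(fit)) next
        add_row(variant, K, F, fit)
      }
    }
  }
  tab <- do.call(rbind, rows)
  conv <- tab[tab$converged, , drop = FALSE]
  if (!nrow(conv)) stop("model ladder: no cell converged", call. = FALSE)
  winner <- conv[which.min(conv$BIC), , drop = FALSE]
  structure(list(table = tab, winner = winner, winner_fit = best_fit,
                 fits = if (keep_fits) fits else NULL),
            class = "fmm_ladder")
}

#' @export
print.fmm_ladder <- function(x, digits = 2, ...) {
  tab <- x$table
  tab$BIC <- round(tab$BIC, digits)
  tab$AIC <- round(tab$AIC, digits)
  tab$loglik <- round(tab$loglik, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nwinner by BIC: %s (K = %s, F = %s), BIC = %.2f\n",
              x$winner$model, x$winner$K, x$winner$F, x$winner$BIC))
  invisible(x)
}
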