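#' @keywords internal
"_PACKAGE"

## Numerically safe helpers shared across the EM and VAE code paths.

#' Row-wise log-sum-exp
#'
#' @param m numeric matrix; the reduction runs over columns within each row.
#' @return numeric vector, `log(rowSums(exp(m)))` computed stably.
#' @keywords internal
logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

#' Row-wise softmax
#' @keywords internal
softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

## Logistic helpers with probabilities bounded away from 0/1 so that
## Bernoulli log-likelihoods stay finite under extreme linear predictors.
plogis_safe <- function(x, eps = 1e-12) {
  pmin(pmax(stats::plogis(x), eps), 1 - eps)
}

softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Draw a reproducible local RNG state
#'
#' Runs `expr` under a temporary `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so package functions never clobber user seeds.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
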