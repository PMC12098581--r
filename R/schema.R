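## Instrument schema and age model.
##
## The assessment battery contains 54 items across six subtests. All items
## are binary correct/incorrect except the three visuospatial-attention
## scores (continuous in [0, 1]) and the single backward-span working-memory
## score (continuous, >= 0).

#' Item schema of the cognitive assessment battery
#'
#' Describes the 54-item battery: item names, parent subtest and measurement
#' scale. Six subtests are covered: logical reasoning (15 binary items),
#' visuospatial attention (3 continuous items in \eqn{[0,1]}), motion
#' perception (5 binary), phonological awareness (13 binary), verbal
#' comprehension (17 binary) and working memory (1 continuous, nonnegative).
#'
#' @return A data frame with one row per item and columns `name`, `subtest`
#'   and `scale` (`"binary"`, `"unit_interval"` or `"nonnegative_continuous"`).
#' @examples
#' sch <- item_schema()
#' table(sch$subtest)
#' @export
item_schema <- function() {
  counts <- c(logical = 15L, visuospatial = 3L, motion = 5L,
              phonological = 13L, verbal = 17L, working_memory = 1L)
  scales <- c(logical = "binary", visuospatial = "unit_interval",
              motion = "binary", phonological = "binary", verbal = "binary",
              working_memory = "nonnegative_continuous")
  subtest <- rep(names(counts), counts)
  idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  out <- data.frame(
    name = paste(subtest, idx, sep = "_"),
    subtest = subtest,
    scale = unname(scales[subtest]),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(out) == 54L)
  out
}

#' Trimodal age model
#'
#' A three-component Gaussian mixture over ages, truncated to the cohort
#' age support, reproducing the trimodal age distribution of the sampled
#' cohort it emulates. Default component weights are calibrated so that the implied
#' age-bin probabilities equal the observed bin composition (670/821/1079
#' of 2570 participants), accounting for the mass each truncated component
#' spills across the bin edges.
#'
#' @param means component means in years.
#' @param sds component standard deviations in years.
#' @param weights component mixing weights; must sum to 1.
#' @param support inclusive truncation range in years.
#' @param bin_edges left-closed cut points defining the age bins
#'   \eqn{[0, e_1)}, \eqn{[e_1, e_2)}, \eqn{[e_2, 100)}.
#' @return An object of class `age_model`.
#' @export
age_model <- function(means = c(6.5, 10.0, 13.5),
                      sds = c(1.0, 1.0, 1.0),
                      weights = c(0.2725555, 0.2842756, 0.4431689),
                      support = c(4, 16),
                      bin_edges = c(8, 12)) {
  if (length(means) != length(sds) || length(means) != length(weights)) {
    stop("`means`, `sds` and `weights` must have equal length", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("invalid mixture weights: must be nonnegative and sum to 1",
         call. = FALSE)
  }
  if (any(sds < 0)) stop("component sds must be nonnegative", call. = FALSE)
  structure(list(means = means, sds = sds, weights = weights,
                 support = support, bin_edges = bin_edges),
            class = "age_model")
}

#' Sample ages from the trimodal age model
#'
#' @param n number of participants.
#' @param model an [age_model()].
#' @param seed optional integer seed; identical seeds give identical draws.
#' @return Numeric vector of `n` ages within the model support.
#' @export
sample_ages <- function(n, model = age_model(), seed = NULL) {
  stopifnot(inherits(model, "age_model"))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  with_seed(seed, {
    comp <- sample.int(length(model$weights), n, replace = TRUE,
                       prob = model$weights)
    ages <- stats::rnorm(n, model$means[comp], model$sds[comp])
    ## truncate by redrawing; degenerate (sd = 0) components pass through
    bad <- which(ages < model$support[1] | ages > model$support[2])
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      ages[bad] <- stats::rnorm(length(bad), model$means[comp[bad]],
                                model$sds[comp[bad]])
      bad <- bad[ages[bad] < model$support[1] | ages[bad] > model$support[2]]
      guard <- guard + 1L
    }
    if (length(bad) > 0L) {
      ages[bad] <- pmin(pmax(model$means[comp[bad]], model$support[1]),
                        model$support[2])
    }
    ages
  })
}

#' Bin ages into the three cohort categories
#'
#' Ages are grouped into left-closed, right-open intervals
#' \eqn{[0, 8)}, \eqn{[8, 12)} and \eqn{[12, 100)}. The centered code
#' \eqn{\{-1, 0, +1\}} (bin index minus one) is the covariate entering the
#' concomitant class-membership model, so that code 0 is the middle bin.
#'
#' @param ages numeric vector of nonnegative ages in years.
#' @param edges the two interior cut points (default `c(8, 12)`).
#' @return A list with integer `bin` in `{0, 1, 2}` and numeric `code` in
#'   `{-1, 0, +1}`.
#' @examples
#' bin_ages(c(7.9, 8, 12))$bin   # 0 1 2
#' @export
bin_ages <- function(ages, edges = c(8, 12)) {
  if (any(!is.finite(ages)) || any(ages < 0)) {
    stop("ages must be finite and nonnegative", call. = FALSE)
  }
  stopifnot(length(edges) == 2L, edges[1] < edges[2])
  bin <- findInterval(ages, edges)          # left-closed: x >= edge -> upper
  list(bin = as.integer(bin), code = as.numeric(bin - 1L))
}

#' One-hot encode the age bin
#' @param bin integer vector in `{0, 1, 2}`.
#' @return n x 3 matrix of 0/1 indicators.
#' @keywords internal
one_hot_bins <- function(bin, n_bins = 3L) {
  m <- matrix(0, length(bin), n_bins)
  m[cbind(seq_along(bin), bin + 1L)] <- 1
  m
}
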