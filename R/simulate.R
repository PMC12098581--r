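## Synthetic item-response generator.
##
## Two generating modes mirror the two analysis tracks:
##   * `simulate_fmm1()` draws from a one-factor measurement model with
##     K latent classes that differ only in factor mean, class membership
##     depending on binned age through a multinomial-logistic model --
##     exactly the structure the FMM track assumes.
##   * `simulate_profiles()` draws from a bank of discrete response
##     profiles whose mixing weights may vary by age bin -- a multi-cluster
##     world for exercising the CGMVAE track.

.frozen_truth_seed <- 160451L  # freezes the default loadings/thresholds

#' Generative truth for the one-factor, K-class measurement model
#'
#' Bundles the measurement and structural parameters used by
#' [simulate_fmm1()]. Defaults are the package's two-class generating truth:
#' class factor means \eqn{\alpha = (-1.451, 0.657)}, concomitant
#' coefficients \eqn{\gamma_0 = -0.048}, \eqn{\gamma_1 = -0.963} (log-odds
#' of class 1 versus class 2 per unit of centered age code), and six
#' anchored loadings (`logical_6` 0.73, `logical_11` 0.72, `logical_12`
#' 0.69, `phonological_9` 0.65, `phonological_1` -0.41, `phonological_4`
#' -0.21). Remaining loadings are drawn once from U(0.30, 0.70) and item
#' thresholds from N(0, 0.5^2) under a fixed internal seed, then frozen as
#' package defaults.
#'
#' @param alpha class factor means, strictly increasing (class 1 lowest).
#' @param gamma0,gamma1 multinomial-logistic intercepts/slopes for classes
#'   `1..K-1` against reference class `K`; length `K - 1`.
#' @param loadings,thresholds optional length-54 overrides.
#' @param residual_sd Gaussian noise sd on the linear predictor of the four
#'   continuous items before their range transform.
#' @return An object of class `fmm_truth`.
#' @export
fmm_truth <- function(alpha = c(-1.451, 0.657),
                      gamma0 = -0.048, gamma1 = -0.963,
                      loadings = NULL, thresholds = NULL,
                      residual_sd = 0.3) {
  schema <- item_schema()
  K <- length(alpha)
  if (K < 1L) stop("need at least one class", call. = FALSE)
  if (is.unsorted(alpha, strictly = TRUE)) {
    stop("`alpha` must be strictly increasing (class 1 = lowest)",
         call. = FALSE)
  }
  if (length(gamma0) != K - 1L || length(gamma1) != K - 1L) {
    stop("`gamma0`/`gamma1` must have length K - 1", call. = FALSE)
  }
  if (is.null(loadings) || is.null(thresholds)) {
    frozen <- with_seed(.frozen_truth_seed, {
      lam <- stats::runif(54L, 0.30, 0.70)
      tau <- stats::rnorm(54L, 0, 0.5)
      list(lam = lam, tau = tau)
    })
    if (is.null(loadings)) {
      loadings <- frozen$lam
      names(loadings) <- schema$name
      loadings[c("logical_6", "logical_11", "logical_12")] <- c(0.73, 0.72, 0.69)
      loadings["phonological_9"] <- 0.65
      loadings["phonological_1"] <- -0.41
      loadings["phonological_4"] <- -0.21
    }
    if (is.null(thresholds)) {
      thresholds <- frozen$tau
      names(thresholds) <- schema$name
    }
  }
  stopifnot(length(loadings) == 54L, length(thresholds) == 54L)
  structure(list(alpha = alpha, gamma0 = gamma0, gamma1 = gamma1,
                 loadings = as.numeric(loadings),
                 thresholds = as.numeric(thresholds),
                 residual_sd = residual_sd, schema = schema),
            class = "fmm_truth")
}

#' Class-membership probabilities given the centered age code
#'
#' Multinomial logistic with the last class as reference:
#' \eqn{\log P(k)/P(K) = \gamma_{0k} + \gamma_{1k} c}.
#'
#' @param code numeric vector of centered bin codes.
#' @param gamma0,gamma1 coefficient vectors of length `K - 1`.
#' @return n x K matrix of probabilities, rows summing to 1.
#' @export
class_probabilities <- function(code, gamma0, gamma1) {
  K <- length(gamma0) + 1L
  eta <- cbind(outer(code, gamma1) + matrix(gamma0, length(code), K - 1L,
                                            byrow = TRUE),
               0)
  softmax_rows(eta)
}

## Map linear predictors to item responses per measurement scale.
.response_mean <- function(eta, scale) {
  switch(scale,
         binary = stats::plogis(eta),
         unit_interval = stats::plogis(eta),
         nonnegative_continuous = softplus(eta),
         stop("unknown scale: ", scale))
}

.draw_items <- function(eta, schema, residual_sd) {
  ## eta: n x 54 linear predictors
  n <- nrow(eta)
  out <- matrix(0, n, 54L, dimnames = list(NULL, schema$name))
  for (j in seq_len(54L)) {
    sc <- schema$scale[j]
    if (sc == "binary") {
      out[, j] <- stats::rbinom(n, 1L, stats::plogis(eta[, j]))
    } else if (sc == "unit_interval") {
      out[, j] <- stats::plogis(eta[, j] + stats::rnorm(n, 0, residual_sd))
    } else {
      out[, j] <- softplus(eta[, j] + stats::rnorm(n, 0, residual_sd))
    }
  }
  out
}

#' Simulate from the one-factor, K-class measurement model
#'
#' Draws ages from `age_model`, assigns each participant to a latent class
#' by multinomial logistic regression on the centered age-bin code, and
#' generates the 54 item responses from the class factor mean:
#' binary items are Bernoulli with success probability
#' \eqn{\mathrm{logit}^{-1}(\tau_j + \lambda_j \alpha_k)}; the continuous
#' visuospatial and working-memory scores pass the noisy linear predictor
#' through a logistic squash (range \eqn{[0,1]}) and a softplus
#' (nonnegative), respectively.
#'
#' @param n number of participants.
#' @param truth an [fmm_truth()].
#' @param model an [age_model()].
#' @param seed optional integer seed.
#' @return An object of class `cogmix_sim`: a list with `data` (data frame
#'   with `participant_id`, `age` and the 54 item columns), `class` (true
#'   class labels, 1-based), `bin`, `code` and the generating `truth`.
#' @export
simulate_fmm1 <- function(n, truth = fmm_truth(), model = age_model(),
                          seed = NULL) {
  stopifnot(inherits(truth, "fmm_truth"))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  with_seed(seed, {
    ages <- sample_ages(n, model)
    b <- bin_ages(ages, model$bin_edges)
    P <- class_probabilities(b$code, truth$gamma0, truth$gamma1)
    K <- ncol(P)
    cls <- apply(P, 1L, function(p) sample.int(K, 1L, prob = p))
    eta <- matrix(truth$thresholds, n, 54L, byrow = TRUE) +
      outer(truth$alpha[cls], truth$loadings)
    items <- .draw_items(eta, truth$schema, truth$residual_sd)
    data <- data.frame(participant_id = seq_len(n), age = ages,
                       items, check.names = FALSE)
    structure(list(data = data, class = cls, bin = b$bin, code = b$code,
                   truth = truth),
              class = "cogmix_sim")
  })
}

#' A bank of discrete response profiles
#'
#' Each profile is a 54-vector of offsets (logit / linear-predictor scale)
#' added to a common baseline; mixing weights may differ by age bin to
#' emulate developmental trends in cluster prevalence.
#'
#' @param offsets G x 54 matrix of per-item profile offsets.
#' @param weights either a length-G vector or a 3 x G matrix of bin-specific
#'   mixing weights; each bin's weights must sum to 1.
#' @param baseline length-54 baseline linear predictors; defaults to the
#'   frozen item thresholds of [fmm_truth()].
#' @param residual_sd noise sd for the continuous items.
#' @return Object of class `profile_bank`.
#' @export
profile_bank <- function(offsets, weights = NULL, baseline = NULL,
                         residual_sd = 0.3) {
  offsets <- as.matrix(offsets)
  if (nrow(offsets) < 1L) stop("profile bank is empty", call. = FALSE)
  if (ncol(offsets) != 54L) stop("offsets must have 54 columns", call. = FALSE)
  G <- nrow(offsets)
  if (is.null(weights)) weights <- rep(1 / G, G)
  if (is.matrix(weights)) {
    stopifnot(ncol(weights) == G, nrow(weights) == 3L)
    if (any(abs(rowSums(weights) - 1) > 1e-8)) {
      stop("bin-specific weights must sum to 1 within each bin",
           call. = FALSE)
    }
  } else {
    stopifnot(length(weights) == G)
    if (abs(sum(weights) - 1) > 1e-8) {
      stop("profile weights must sum to 1", call. = FALSE)
    }
    weights <- matrix(weights, 3L, G, byrow = TRUE)
  }
  if (is.null(baseline)) baseline <- fmm_truth()$thresholds
  stopifnot(length(baseline) == 54L)
  structure(list(offsets = offsets, weights = weights, baseline = baseline,
                 residual_sd = residual_sd, G = G),
            class = "profile_bank")
}

#' Default multi-profile bank
#'
#' `G` profiles with blockwise offsets of magnitude `separation` assigned by
#' a fixed internal seed, giving distinct strengths/weaknesses per profile
#' across the six subtests.
#'
#' @param G number of profiles (>= 2).
#' @param separation absolute offset magnitude on the logit scale.
#' @param weights optional mixing weights passed to [profile_bank()].
#' @export
default_profile_bank <- function(G = 4L, separation = 2.0, weights = NULL) {
  stopifnot(G >= 2L)
  offs <- with_seed(.frozen_truth_seed + G, {
    matrix(sample(c(-1, 1), G * 54L, replace = TRUE), G, 54L) * separation
  })
  profile_bank(offs, weights = weights)
}

#' Simulate from a profile bank
#'
#' Per participant: draw an age, look up its bin, draw a profile from that
#' bin's mixing weights, then generate responses from the baseline rates
#' shifted by the profile's offsets (same scale transforms as
#' [simulate_fmm1()]).
#'
#' @inheritParams simulate_fmm1
#' @param bank a [profile_bank()].
#' @return Object of class `cogmix_sim` with `profile` labels (1-based).
#' @export
simulate_profiles <- function(n, bank = default_profile_bank(),
                              model = age_model(), seed = NULL) {
  stopifnot(inherits(bank, "profile_bank"))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  schema <- item_schema()
  with_seed(seed, {
    ages <- sample_ages(n, model)
    b <- bin_ages(ages, model$bin_edges)
    prof <- integer(n)
    for (bi in 0:2) {
      idx <- which(b$bin == bi)
      if (length(idx)) {
        prof[idx] <- sample.int(bank$G, length(idx), replace = TRUE,
                                prob = bank$weights[bi + 1L, ])
      }
    }
    eta <- matrix(bank$baseline, n, 54L, byrow = TRUE) + bank$offsets[prof, , drop = FALSE]
    items <- .draw_items(eta, schema, bank$residual_sd)
    data <- data.frame(participant_id = seq_len(n), age = ages,
                       items, check.names = FALSE)
    structure(list(data = data, profile = prof, bin = b$bin, code = b$code,
                   bank = bank),
              class = "cogmix_sim")
  })
}

#' Write a simulated dataset (and optional truth labels) to CSV
#'
#' @param sim a `cogmix_sim` object.
#' @param path output CSV path for the dataset.
#' @param labels_path optional sidecar CSV for the true labels.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(sim, path, labels_path = NULL) {
  stopifnot(inherits(sim, "cogmix_sim"))
  utils::write.csv(sim$data, path, row.names = FALSE)
  if (!is.null(labels_path)) {
    lab <- sim$class %||% sim$profile
    utils::write.csv(data.frame(participant_id = sim$data$participant_id,
                                label = lab),
                     labels_path, row.names = FALSE)
  }
  invisible(path)
}
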