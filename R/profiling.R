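## Feature-focused cluster interpretation: per-cluster z-score profiles
## against global statistics, age-bin x cluster distribution tables, and
## the small-cluster reporting filter.

#' Per-cluster z-score profiles against global statistics
#'
#' For each cluster and item: the cluster mean expressed in global
#' standard-deviation units, \eqn{z = (\bar x_{k} - \bar x)/s} with `s`
#' the full-sample sd (denominator `n - 1`). Zero-variance items get
#' `z = 0` and are flagged. Narrative bands label deviations as
#' `average`, `slight`, `moderate` or `severe` at configurable |z|
#' thresholds.
#'
#' @param data item responses (schema data frame, `cogmix_sim`, or numeric
#'   matrix).
#' @param labels cluster labels aligned with rows.
#' @param bin optional age-bin index per row; adds the bin x cluster
#'   distribution via [age_cluster_distribution()].
#' @param bands |z| thresholds for the slight/moderate/severe bands.
#' @return Object of class `cluster_profile`: per-cluster sizes, per-item
#'   means and z-scores, band labels, flags, and optionally the age-bin
#'   distribution.
#' @export
cluster_feature_zscores <- function(data, labels, bin = NULL,
                                    bands = c(slight = 0.2, moderate = 0.5,
                                              severe = 1.0)) {
  d <- resolve_items(data)
  X <- d$X
  if (length(labels) != nrow(X)) {
    stop("labels must align with data rows", call. = FALSE)
  }
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  gm <- colMeans(X)
  gs <- apply(X, 2L, stats::sd)
  zero_var <- gs < 1e-12
  counts <- table(factor(labels, levels = lv))
  empty <- lv[counts == 0]
  if (length(empty)) {
    warning("empty cluster(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
    lv <- setdiff(lv, empty)
  }
  means <- t(sapply(lv, function(k) colMeans(X[labels == k, , drop = FALSE])))
  if (length(lv) == 1L) means <- matrix(means, 1L, ncol(X),
                                        dimnames = list(NULL, colnames(X)))
  z <- sweep(means, 2L, gm)
  z[, !zero_var] <- sweep(z[, !zero_var, drop = FALSE], 2L,
                          gs[!zero_var], `/`)
  z[, zero_var] <- 0
  band_of <- function(v) {
    a <- abs(v)
    ifelse(a >= bands["severe"], "severe",
           ifelse(a >= bands["moderate"], "moderate",
                  ifelse(a >= bands["slight"], "slight", "average")))
  }
  band <- apply(z, c(1L, 2L), band_of)
  rownames(means) <- rownames(z) <- rownames(band) <- as.character(lv)
  out <- list(clusters = lv, n = as.integer(counts[as.character(lv)]),
              total_n = nrow(X), means = means, z = z, bands = band,
              zero_variance_items = colnames(X)[zero_var],
              band_thresholds = bands, min_n = NULL)
  if (!is.null(bin)) {
    out$age_distribution <- age_cluster_distribution(labels, bin)
  }
  structure(out, class = "cluster_profile")
}

#' Age-bin by cluster distribution
#'
#' Entry \eqn{(b, k)} is the share of bin-`b` participants in cluster `k`;
#' rows sum to 1. Empty bins give a zero row and are flagged.
#'
#' @param labels cluster labels.
#' @param bin age-bin index per row (0-based bins from [bin_ages()]).
#' @return bins x clusters proportion matrix with a `flagged_bins`
#'   attribute.
#' @export
age_cluster_distribution <- function(labels, bin) {
  if (length(labels) != length(bin)) {
    stop("labels and bins must align", call. = FALSE)
  }
  tab <- table(factor(bin, levels = sort(unique(bin))),
               factor(labels, levels = sort(unique(labels))))
  tot <- rowSums(tab)
  P <- sweep(as.matrix(tab), 1L, pmax(tot, 1L), `/`)
  empty <- rownames(P)[tot == 0]
  attr(P, "flagged_bins") <- empty
  P
}

#' Drop small clusters from the interpretation output
#'
#' Clusters with fewer than `min_n` members are removed from the profile
#' tables (means, z-scores, bands) but stay in the retained `all_n` counts.
#' Applying the filter twice equals applying it once.
#'
#' @param profile a [cluster_feature_zscores()] result.
#' @param min_n inclusive retention threshold (`n >= min_n` is kept).
#' @return The filtered `cluster_profile`.
#' @export
filter_small_clusters <- function(profile, min_n = 10L) {
  stopifnot(inherits(profile, "cluster_profile"))
  keep <- profile$n >= min_n
  if (is.null(profile$all_n)) {
    profile$all_n <- stats::setNames(profile$n,
                                     as.character(profile$clusters))
  }
  profile$clusters <- profile$clusters[keep]
  profile$n <- profile$n[keep]
  profile$means <- profile$means[keep, , drop = FALSE]
  profile$z <- profile$z[keep, , drop = FALSE]
  profile$bands <- profile$bands[keep, , drop = FALSE]
  profile$min_n <- min_n
  profile
}

#' @export
print.cluster_profile <- function(x, top = 3L, ...) {
  cat(sprintf("cluster profile: %d cluster(s), %d participants\n",
              length(x$clusters), x$total_n))
  if (!is.null(x$min_n)) {
    cat(sprintf("  (clusters with n < %d filtered from interpretation)\n",
                x$min_n))
  }
  for (i in seq_along(x$clusters)) {
    zi <- x$z[i, ]
    ord <- order(abs(zi), decreasing = TRUE)[seq_len(min(top, length(zi)))]
    cat(sprintf("  cluster %s (n = %d): %s\n", x$clusters[i], x$n[i],
                paste(sprintf("%s z=%+.2f", names(zi)[ord], zi[ord]),
                      collapse = ", ")))
  }
  invisible(x)
}
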