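## Crisp and fuzzy cluster validity indices. Euclidean distances
## throughout; fuzzy indices take an n x K membership matrix with rows
## summing to 1.

.check_XU <- function(X, labels = NULL, U = NULL) {
  X <- as.matrix(X)
  if (!is.null(labels) && length(labels) != nrow(X)) {
    stop("labels must align with rows of X", call. = FALSE)
  }
  if (!is.null(U)) {
    U <- as.matrix(U)
    if (nrow(U) != nrow(X)) stop("U must align with rows of X", call. = FALSE)
    if (any(U < -1e-9) || any(abs(rowSums(U) - 1) > 1e-6)) {
      stop("membership rows must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  X
}

#' Silhouette score
#'
#' Mean over points of \eqn{(b - a)/\max(a, b)} where `a` is the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster. Points in singleton clusters contribute 0.
#'
#' @param X n x d coordinate matrix.
#' @param labels cluster labels (any atomic type).
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
silhouette_score <- function(X, labels) {
  X <- .check_XU(X, labels)
  labs <- as.integer(factor(labels))
  K <- max(labs)
  n <- nrow(X)
  if (K < 2L) stop("silhouette undefined for a single cluster", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  sizes <- tabulate(labs, K)
  ## mean distance from each point to each cluster
  M <- sapply(seq_len(K), function(k) rowSums(D[, labs == k, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labs[i]
    if (sizes[k] == 1L) { s[i] <- 0; next }
    a <- M[i, k] / (sizes[k] - 1L)
    b <- min(M[i, -k] / sizes[-k])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' \eqn{(B/(K-1)) / (W/(n-K))}: between- over within-cluster sum of squares
#' about centroids. Coincident within-cluster points (W = 0) return `Inf`.
#'
#' @inheritParams silhouette_score
#' @export
calinski_harabasz <- function(X, labels) {
  X <- .check_XU(X, labels)
  labs <- as.integer(factor(labels))
  K <- max(labs)
  n <- nrow(X)
  if (K < 2L || K >= n) stop("need 2 <= K < n", call. = FALSE)
  g <- colMeans(X)
  B <- 0; W <- 0
  for (k in seq_len(K)) {
    Xk <- X[labs == k, , drop = FALSE]
    ck <- colMeans(Xk)
    B <- B + nrow(Xk) * sum((ck - g)^2)
    W <- W + sum(sweep(Xk, 2L, ck)^2)
  }
  if (W <= 0) return(Inf)
  (B / (K - 1)) / (W / (n - K))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of \eqn{\max_{j \ne k} (S_k + S_j)/M_{kj}} with
#' \eqn{S_k} the mean distance to the centroid and \eqn{M_{kj}} the
#' centroid distance. Coincident centroids return `Inf`.
#'
#' @inheritParams silhouette_score
#' @export
davies_bouldin <- function(X, labels) {
  X <- .check_XU(X, labels)
  labs <- as.integer(factor(labels))
  K <- max(labs)
  if (K < 2L) stop("need at least 2 clusters", call. = FALSE)
  C <- t(sapply(seq_len(K), function(k) colMeans(X[labs == k, , drop = FALSE])))
  if (ncol(X) == 1L) C <- matrix(C, K, 1L)
  S <- vapply(seq_len(K), function(k) {
    Xk <- X[labs == k, , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xk, 2L, C[k, ])^2)))
  }, 0)
  M <- as.matrix(stats::dist(C))
  r <- numeric(K)
  for (k in seq_len(K)) {
    ratio <- (S[k] + S[-k]) / M[k, -k]
    r[k] <- max(ratio)
  }
  if (any(!is.finite(r))) return(Inf)
  mean(r)
}

#' Xie-Beni index
#'
#' Fuzzy compactness over separation:
#' \deqn{XB = \frac{\sum_i \sum_k u_{ik}^m \lVert x_i - v_k \rVert^2}
#'   {n \cdot \min_{j \ne k} \lVert v_j - v_k \rVert^2}}
#' with centroids \eqn{v_k} the \eqn{u^m}-weighted means (model-agnostic;
#' pass `centroids` to override, e.g. with a model's component means).
#'
#' @param X n x d coordinate matrix.
#' @param U n x K membership matrix, rows summing to 1.
#' @param m fuzzifier (> 1), conventionally 2.
#' @param centroids optional K x d matrix of externally supplied centroids.
#' @export
xie_beni <- function(X, U, m = 2, centroids = NULL) {
  X <- .check_XU(X, U = U)
  U <- as.matrix(U)
  stopifnot(m > 1)
  Um <- U^m
  K <- ncol(U)
  if (is.null(centroids)) {
    centroids <- crossprod(Um, X) / colSums(Um)
  }
  num <- 0
  for (k in seq_len(K)) {
    num <- num + sum(Um[, k] * rowSums(sweep(X, 2L, centroids[k, ])^2))
  }
  sep <- stats::dist(centroids)^2
  minsep <- min(sep)
  if (minsep <= 1e-300) return(Inf)
  num / (nrow(X) * minsep)
}

#' Fuzzy partition coefficient
#'
#' \eqn{FPC = \frac{1}{n}\sum_i \sum_k u_{ik}^2}; 1 for crisp memberships,
#' \eqn{1/K} for uniform ones.
#'
#' @inheritParams xie_beni
#' @export
fuzzy_partition_coefficient <- function(U) {
  U <- as.matrix(U)
  if (any(abs(rowSums(U) - 1) > 1e-6)) {
    stop("membership rows must sum to 1", call. = FALSE)
  }
  sum(U^2) / nrow(U)
}

#' Partition entropy
#'
#' \eqn{PE = -\frac{1}{n}\sum_i \sum_k u_{ik} \ln u_{ik}} (natural log,
#' \eqn{0 \ln 0 = 0}); 0 for crisp memberships, \eqn{\ln K} for uniform.
#'
#' @inheritParams xie_beni
#' @export
partition_entropy <- function(U) {
  U <- as.matrix(U)
  if (any(abs(rowSums(U) - 1) > 1e-6)) {
    stop("membership rows must sum to 1", call. = FALSE)
  }
  lu <- ifelse(U > 0, log(U), 0)
  -sum(U * lu) / nrow(U)
}

#' Full cluster-quality battery
#'
#' Crisp indices (silhouette, Calinski-Harabasz, Davies-Bouldin) on hard
#' labels (row-wise argmax when a membership matrix is given) and fuzzy
#' indices (Xie-Beni, fuzzy partition coefficient, partition entropy) when
#' memberships are available. Degenerate inputs yield `NA` entries with a
#' flag rather than errors.
#'
#' @param X n x d coordinates of the evaluation space.
#' @param labels hard cluster labels (crisp input).
#' @param U fuzzy membership matrix (rows sum to 1).
#' @param m fuzzifier for the Xie-Beni index.
#' @param space short description of the coordinate space, stored in the
#'   report.
#' @return Object of class `cluster_quality`.
#' @export
quality_report <- function(X, labels = NULL, U = NULL, m = 2,
                           space = "features") {
  if (is.null(labels) && is.null(U)) {
    stop("supply `labels`, `U`, or both", call. = FALSE)
  }
  if (is.null(labels)) labels <- max.col(U, ties.method = "first")
  X <- as.matrix(X)
  K <- length(unique(labels))
  grab <- function(expr) {
    tryCatch(expr, error = function(e) structure(NA_real_,
                                                 flag = conditionMessage(e)))
  }
  out <- list(
    silhouette = grab(silhouette_score(X, labels)),
    calinski_harabasz = grab(calinski_harabasz(X, labels)),
    davies_bouldin = grab(davies_bouldin(X, labels)),
    n = nrow(X), K = K, space = space
  )
  if (!is.null(U)) {
    out$xie_beni <- grab(xie_beni(X, U, m = m))
    out$fpc <- grab(fuzzy_partition_coefficient(U))
    out$partition_entropy <- grab(partition_entropy(U))
  }
  flags <- lapply(out, attr, "flag")
  out$flags <- Filter(Negate(is.null), flags)
  structure(out, class = "cluster_quality")
}

#' @export
print.cluster_quality <- function(x, ...) {
  cat(sprintf("cluster quality (%s space; n = %d, K = %d)\n",
              x$space, x$n, x$K))
  cat(sprintf("  silhouette          %8.4f\n", x$silhouette))
  cat(sprintf("  Calinski-Harabasz   %8.3f\n", x$calinski_harabasz))
  cat(sprintf("  Davies-Bouldin      %8.4f\n", x$davies_bouldin))
  if (!is.null(x$xie_beni)) {
    cat(sprintf("  Xie-Beni            %8.4f\n", x$xie_beni))
    cat(sprintf("  partition coeff.    %8.4f\n", x$fpc))
    cat(sprintf("  partition entropy   %8.4f\n", x$partition_entropy))
  }
  if (length(x$flags)) {
    cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  }
  invisible(x)
}
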