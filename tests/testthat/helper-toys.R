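## Shared toy builders for the test suite.

## 1-D two-cluster toy used for the hand-derived validity-index values.
toy_clusters_1d <- function() {
  list(X = matrix(c(0, 1, 10, 11), ncol = 1), labels = c(1, 1, 2, 2))
}

## small binary item matrix with two clearly separated response patterns
toy_two_pattern <- function(n_per = 3L, J = 4L) {
  X <- rbind(matrix(0, n_per, J), matrix(1, n_per, J))
  X
}

## random small instance for metric oracle comparisons
random_instance <- function(n = 25L, d = 3L, K = 3L) {
  X <- matrix(stats::rnorm(n * d), n, d) +
    matrix(stats::rnorm(K * d, sd = 3), K, d)[sample.int(K, n, TRUE), ]
  repeat {
    labels <- sample.int(K, n, replace = TRUE)
    if (length(unique(labels)) == K) break
  }
  list(X = X, labels = labels)
}

## random membership matrix with rows summing to 1
random_membership <- function(n, K) {
  U <- matrix(stats::rexp(n * K), n, K)
  U / rowSums(U)
}

## python + scikit-learn oracle for the crisp validity indices; returns
## NULL when the interpreter or library is unavailable
sklearn_metrics <- function(X, labels) {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  xf <- tempfile(fileext = ".csv"); lf <- tempfile(fileext = ".csv")
  of <- tempfile(fileext = ".json")
  utils::write.table(X, xf, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(labels, lf, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(
    "import json, numpy as np\nfrom sklearn import metrics\nX = np.loadtxt(%s, delimiter=','); y = np.loadtxt(%s, delimiter=',')\nX = X.reshape(len(y), -1)\nout = dict(sil=float(metrics.silhouette_score(X, y)), ch=float(metrics.calinski_harabasz_score(X, y)), db=float(metrics.davies_bouldin_score(X, y)))\njson.dump(out, open(%s, 'w'))\n",
    deparse(xf), deparse(lf), deparse(of))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- suppressWarnings(system2(py, sf, stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(of)) return(NULL)
  jsonlite::read_json(of, simplifyVector = TRUE)
}
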