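test_that("affinity_from_Z symmetrizes magnitudes and zeroes the diagonal", {
  Z <- matrix(0, 3, 3); Z[1, 2] <- 2; Z[2, 1] <- 0; Z[3, 3] <- 5
  S <- affinity_from_Z(Z)
  expect_equal(S[1, 2], 1); expect_equal(S[2, 1], 1)
  expect_equal(diag(unclass(S)), rep(0, 3))
  # fixed point on symmetric non-negative zero-diagonal input
  S0 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(unclass(affinity_from_Z(S0)), S0, ignore_attr = TRUE)
  # sign invariance
  expect_equal(unclass(affinity_from_Z(-Z)), unclass(affinity_from_Z(Z)))
  Zb <- Z; Zb[1, 1] <- NaN
  expect_error(affinity_from_Z(Zb), class = "mnst_validation_error")
})

test_that("leiden_domains recovers planted partitions and is reproducible", {
  set.seed(1)
  # two disconnected cliques
  S <- matrix(0, 20, 20)
  S[1:10, 1:10] <- 1; S[11:20, 11:20] <- 1; diag(S) <- 0
  d <- leiden_domains(S, target_K = 2, seed = 0)
  expect_equal(ari(rep(1:2, each = 10), d$labels), 1)

  # three planted blocks with weak cross-talk
  lab <- rep(1:3, each = 12)
  S3 <- matrix(0.01, 36, 36)
  for (k in 1:3) S3[lab == k, lab == k] <- 1
  diag(S3) <- 0
  d3 <- leiden_domains(S3, target_K = 3, seed = 2)
  expect_equal(ari(lab, d3$labels), 1)
  expect_equal(d3$K, 3)

  # determinism: identical inputs and seed -> identical output
  d3b <- leiden_domains(S3, target_K = 3, seed = 2)
  expect_identical(d3$labels, d3b$labels)
  expect_identical(d3$resolution, d3b$resolution)

  # fixed-resolution mode
  dr <- leiden_domains(S3, resolution = d3$resolution, seed = 2)
  expect_equal(dr$labels, d3$labels)

  expect_error(leiden_domains(S3), class = "mnst_param_error")
  expect_error(leiden_domains(S3, target_K = 2, resolution = 1),
               class = "mnst_param_error")
  expect_error(leiden_domains(matrix(0, 4, 4), target_K = 2),
               class = "mnst_validation_error")
  expect_error(leiden_domains(S3, target_K = 99), class = "mnst_param_error")
})

test_that("ari matches hand-derived cases", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)      # label permutation
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(ari(1:3, 1:4), class = "mnst_validation_error")
})

test_that("ari equals brute-force pair counting on random partitions", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    t <- sample(1:4, n, replace = TRUE)
    p <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(t, p), ari_oracle(t, p), tolerance = 1e-12)
  }
})

test_that("silhouette behaves as the definition dictates", {
  # tight, far-apart clusters
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
             matrix(rnorm(40, 10, 0.05), 20, 2))
  lab <- rep(1:2, each = 20)
  expect_gte(silhouette_score(X, lab), 0.9)
  expect_equal(silhouette_score(X, lab), silhouette_oracle(X, lab),
               tolerance = 1e-12)
  # a point equidistant between two clusters scores ~ 0
  Xe <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1), c(5, 0.5))
  le <- c(1, 1, 2, 2, 1)
  sil_per <- silhouette_oracle(Xe, le)
  expect_equal(silhouette_score(Xe, le), sil_per, tolerance = 1e-12)
  a <- mean(sqrt(colSums((t(Xe[1:2, ]) - Xe[5, ])^2)))
  b <- mean(sqrt(colSums((t(Xe[3:4, ]) - Xe[5, ])^2)))
  expect_lt(abs((b - a) / max(a, b)), 0.02)
  expect_error(silhouette_score(X, rep(1, 40)), class = "mnst_param_error")
})

test_that("davies_bouldin matches the direct formula and its limits", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  lab <- sample(1:3, 30, replace = TRUE)
  expect_equal(davies_bouldin(X, lab), db_oracle(X, lab), tolerance = 1e-10)
  # point clusters -> 0
  Xp <- rbind(matrix(0, 5, 2), matrix(5, 5, 2))
  expect_equal(davies_bouldin(Xp, rep(1:2, each = 5)), 0)
  # moving centroids closer at fixed scatter increases DB
  mk <- function(sep) rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                            matrix(rnorm(40, sep, 0.3), 20, 2))
  set.seed(5); X1 <- mk(10); set.seed(5); X2 <- mk(2)
  l2 <- rep(1:2, each = 20)
  expect_gt(davies_bouldin(X2, l2), davies_bouldin(X1, l2))
  expect_error(davies_bouldin(X, rep(1, 30)), class = "mnst_param_error")
})

test_that("topology_stats computes degree, centrality, closeness", {
  # 3-node path with unit weights
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 1; P[2, 3] <- P[3, 2] <- 1
  ts <- topology_stats(P)
  expect_equal(ts$nodes$degree, c(1, 2, 1))
  # regular graph: constant eigenvector centrality
  R <- matrix(1, 4, 4); diag(R) <- 0
  tr <- topology_stats(R)
  expect_equal(tr$nodes$eigen_centrality, rep(1, 4), tolerance = 1e-8)
  # star: hub has maximal closeness
  St <- matrix(0, 5, 5); St[1, 2:5] <- 1; St <- St + t(St)
  th <- topology_stats(St)
  expect_equal(which.max(th$nodes$closeness), 1L)
  # edge tags
  te <- topology_stats(P, labels = c(1, 1, 2))
  expect_equal(te$edges$within_domain, c(TRUE, FALSE))
})

test_that("differential_expression applies all three filters", {
  set.seed(10)
  n_half <- 40; genes <- 60
  mu <- matrix(5, 2 * n_half, genes)
  mu[1:n_half, 1] <- 80                       # planted 16-fold marker
  counts <- matrix(rpois(length(mu), mu), nrow(mu))
  counts[1:20, 2] <- 0                        # gene 2 under-expressed in a
  sl <- slice_data(counts, cbind(runif(2 * n_half), runif(2 * n_half)))
  lab <- rep(c("a", "b"), each = n_half)
  deg <- differential_expression(sl, lab, "a", "b")
  expect_true(sl$gene_ids[1] %in% deg$gene)
  expect_false(sl$gene_ids[2] %in% deg$gene)  # fails the 80% rule
  expect_true(all(abs(deg$log2_fc) >= 2))
  expect_true(all(deg$p_adj <= 0.05))
  expect_true(all(deg$frac_a >= 0.8 & deg$frac_b >= 0.8))
  # tiny domains are rejected
  expect_error(differential_expression(sl, c(rep("a", 2), rep("b", 78)),
                                       "a", "b"),
               class = "mnst_validation_error")
})

test_that("null genes essentially never pass the combined filters", {
  set.seed(11)
  retained <- 0; total <- 0
  for (rep in 1:10) {
    counts <- matrix(rpois(80 * 50, 5), 80, 50)
    sl <- slice_data(counts, cbind(runif(80), runif(80)))
    deg <- differential_expression(sl, rep(1:2, each = 40), 1, 2)
    retained <- retained + nrow(deg); total <- total + 50
  }
  expect_lte(retained / total, 0.05)
})
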