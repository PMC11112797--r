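test_that("build_spatial_knn gives inverse-distance weights, max-symmetrized", {
  g <- build_spatial_knn(cbind(c(0, 1, 3), 0), k = 1)
  W <- as.matrix(g$W_s)
  # 0-1 mutual nearest at distance 1; 2's nearest is 1 at distance 2;
  # symmetrization by elementwise max keeps the 1/2 weight on both sides
  expect_equal(W, rbind(c(0, 1, 0), c(1, 0, 0.5), c(0, 0.5, 0)))

  # deep-interior spots of a unit lattice: 4 unit-weight neighbours at k = 4
  # (spots nearer the boundary can receive extra diagonal edges from the
  # symmetrization of boundary spots, whose 4th neighbour is diagonal)
  co <- as.matrix(expand.grid(x = 1:7, y = 1:7))
  W4 <- as.matrix(build_spatial_knn(co, k = 4)$W_s)
  interior <- which(co[, 1] %in% 3:5 & co[, 2] %in% 3:5)
  for (i in interior) {
    expect_equal(sum(W4[i, ] > 0), 4)
    expect_equal(unname(W4[i, W4[i, ] > 0]), rep(1, 4))
  }

  # homogeneity: scaling coordinates by c scales weights by 1/c
  set.seed(5)
  co2 <- matrix(runif(40), 20, 2)
  W1 <- as.matrix(build_spatial_knn(co2, k = 3)$W_s)
  W2 <- as.matrix(build_spatial_knn(co2 * 7, k = 3)$W_s)
  expect_equal(W2, W1 / 7, tolerance = 1e-12)

  expect_error(build_spatial_knn(co2, k = 20), class = "mnst_param_error")
  expect_error(build_spatial_knn(matrix(1, 5, 2), k = 2),
               class = "mnst_validation_error")
})

test_that("coincident spots get finite 1/eps weight, ranked closest", {
  co <- rbind(c(0, 0), c(0, 0), c(1, 0), c(5, 0))
  W <- as.matrix(build_spatial_knn(co, k = 1)$W_s)
  expect_true(all(is.finite(W)))
  expect_equal(W[1, 2], 1)        # eps = smallest positive neighbour distance
  expect_gte(W[1, 2], max(W[W < W[1, 2]]))
})

test_that("pmi_matrix matches hand-derived values", {
  # single unit edge: d = (1,1), total 2 -> log 2
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  expect_equal(pmi_matrix(W)$M_s[1, 2], log(2))
  # path A-B-C with unit weights: d = (1,2,1), total 4
  W3 <- matrix(0, 3, 3); W3[1, 2] <- W3[2, 1] <- 1; W3[2, 3] <- W3[3, 2] <- 1
  M <- pmi_matrix(W3)$M_s
  expect_equal(M[1, 2], log(2))
  expect_equal(M[1, 3], 0)                      # non-edges stay zero
  # kappa shifts every nonzero entry by -log(kappa) before clipping
  M2 <- pmi_matrix(W3, kappa = 2, clip = FALSE)$M_s
  expect_equal(M2[1, 2], log(2) - log(2))
  expect_equal(M2[2, 3], M[2, 3] - log(2))
  # clipping truncates negatives to zero
  expect_true(all(pmi_matrix(W3, kappa = 100)$M_s == 0))
  expect_error(pmi_matrix(matrix(0, 3, 3)), class = "mnst_validation_error")
})

test_that("pmi_matrix agrees with brute-force evaluation on random graphs", {
  set.seed(42)
  worst <- 0
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    W <- random_graph(n, density = runif(1, 0.1, 0.5))
    kap <- sample(1:3, 1)
    clip <- rep %% 2 == 0
    M <- pmi_matrix(W, kappa = kap, clip = clip)$M_s
    worst <- max(worst, max(abs(M - pmi_oracle(W, kap, clip))))
  }
  expect_lte(worst, 1e-10)
})

test_that("expression-graph solver satisfies constraints and decreases", {
  set.seed(3)
  X <- matrix(rnorm(20 * 6), 20, 6)
  fit <- learn_expression_graph(X, alpha = 0.3, beta = 0, max_iter = 300)
  expect_true(all(fit$W_e >= 0))
  expect_equal(diag(fit$W_e), rep(0, 20))
  expect_lte(max(diff(fit$trace$objective)), 1e-8)
})

test_that("solver reaches the optimum found by a projected-gradient oracle", {
  set.seed(9)
  for (rep in 1:4) {
    n <- sample(10:30, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    alpha <- runif(1, 0.05, 0.5)
    L <- NULL; beta <- 0
    if (rep %% 2 == 0) {
      L <- graph_laplacian(build_spatial_knn(matrix(runif(2 * n), n, 2), 3))
      beta <- runif(1, 0.1, 1)
    }
    fit <- learn_expression_graph(X, alpha = alpha, beta = beta,
                                  laplacian = L, max_iter = 600, tol = 1e-12)
    orc <- srl_pg_oracle(X, alpha, beta, L, iters = 20000)
    expect_lte(fit$objective, orc$objective * 1.01)
  }
})

test_that("duplicated cells admit exact self-representation as alpha -> 0", {
  set.seed(4)
  base <- matrix(rnorm(5 * 6), 5, 6)
  X <- base[rep(1:5, each = 2), ]              # every cell duplicated
  fit <- learn_expression_graph(X, alpha = 1e-8, beta = 0,
                                max_iter = 3000, tol = 1e-14)
  expect_lte(sum((t(X) - t(X) %*% fit$W_e)^2), 1e-8)
})

test_that("very large alpha shrinks the graph to zero", {
  set.seed(6)
  X <- matrix(rnorm(12 * 4), 12, 4)
  fit <- learn_expression_graph(X, alpha = 1e6 * sum(X^2), beta = 0,
                                max_iter = 50)
  expect_equal(max(fit$W_e), 0)
  expect_equal(fit$objective, sum(X^2))
})

test_that("orthogonal-subspace data yields block-diagonal representation", {
  d <- two_subspace_data(n = 60, seed = 0)
  fit <- learn_expression_graph(d$X, alpha = 0.01, beta = 0, max_iter = 400)
  W <- fit$W_e
  same <- outer(d$groups, d$groups, "==")
  expect_gte(sum(W[same]) / sum(W), 0.95)
})

test_that("a non-PSD laplacian is rejected", {
  X <- matrix(rnorm(30), 10, 3)
  L <- diag(10); L[1, 1] <- -2
  expect_error(learn_expression_graph(X, beta = 1, laplacian = L),
               class = "mnst_param_error")
})
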