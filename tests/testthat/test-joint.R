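test_that("planted exact factorization is recovered", {
  set.seed(2)
  n <- 60; d <- 6
  B0 <- matrix(runif(n * d), n, d)
  A <- B0 %*% matrix(runif(d * n), d, n)
  fit <- joint_fit(A, A, joint_params(d = d))
  expect_lte(sum((A - fit$B %*% fit$F_e)^2), 1e-3 * sum(A^2))
  expect_lte(sum((A - fit$B %*% fit$F_s)^2), 1e-3 * sum(A^2))
  # non-negativity holds exactly
  expect_true(all(fit$B >= 0) && all(fit$F_e >= 0) && all(fit$F_s >= 0))
  # linear constraint feasible at convergence
  res <- norm(t(fit$B) - t(fit$B) %*% fit$Z - fit$E, "F") /
    max(1, norm(t(fit$B), "F"))
  expect_lte(res, 1e-4)
})

test_that("two-block layers give a block-dominant symmetrized Z", {
  bl <- generate_block_multilayer(n = 80, K = 2, within_weight = 1,
                                  between_weight = 0.02, noise_sd = 0.05,
                                  seed = 1)
  fit <- joint_fit(bl$W_e, bl$M_s, joint_params(d = 10))
  S <- unclass(affinity_from_Z(fit$Z))
  same <- outer(bl$labels, bl$labels, "==") & upper.tri(S)
  diff_ <- !outer(bl$labels, bl$labels, "==") & upper.tri(S)
  expect_gte(sum(S[same]) / (sum(S[same]) + sum(S[diff_])), 0.9)
})

test_that("huge lambda forces E to zero and the constraint onto Z", {
  bl <- generate_block_multilayer(n = 50, K = 2, seed = 3)
  fit <- joint_fit(bl$W_e, bl$M_s, joint_params(d = 8, lambda = 1e6))
  expect_lte(max(abs(fit$E)), 1e-6)
  expect_lte(max(abs(t(fit$B) - t(fit$B) %*% fit$Z)), 1e-4)
})

test_that("objective_value matches the dense-SVD oracle", {
  set.seed(8)
  n <- 25; d <- 5
  model <- list(B = matrix(runif(n * d), n, d),
                F_e = matrix(runif(d * n), d, n),
                F_s = matrix(runif(d * n), d, n),
                Z = matrix(rnorm(n * n), n, n),
                E = matrix(rnorm(d * n), d, n))
  We <- matrix(runif(n * n), n, n); Ms <- matrix(runif(n * n), n, n)
  p <- joint_params(d = d, gamma = 1.7, lambda = 0.3)
  expect_equal(objective_value(model, We, Ms, p),
               joint_objective_oracle(model, We, Ms, 1.7, 0.3),
               tolerance = 1e-10)
  # worked cases
  zeros <- list(B = matrix(0, n, d), F_e = matrix(0, d, n),
                F_s = matrix(0, d, n), Z = matrix(0, n, n),
                E = matrix(0, d, n))
  expect_equal(objective_value(zeros, matrix(0, n, n), matrix(0, n, n), p), 0)
  eye <- zeros; eye$Z <- diag(n)
  expect_equal(objective_value(eye, matrix(0, n, n), matrix(0, n, n),
                               joint_params(d = d, gamma = 1, lambda = 1)),
               n)
  bad <- model; bad$Z[1, 1] <- Inf
  expect_error(objective_value(bad, We, Ms, p),
               class = "mnst_validation_error")
})

test_that("objective trace is non-increasing and constraint-feasible", {
  for (seed in 0:1) {
    bl <- generate_block_multilayer(n = 90, K = 3, noise_sd = 0.1,
                                    seed = seed)
    fit <- joint_fit(bl$W_e, bl$M_s, joint_params(d = 15))
    tr <- fit$report$trace
    expect_lte(max(diff(tr$objective)), 1e-8)
    expect_lte(tr$constraint_residual[nrow(tr)], 1e-4)
  }
})

test_that("sequential_fit freezes B between its two stages", {
  bl <- generate_block_multilayer(n = 40, K = 2, seed = 5)
  p <- joint_params(d = 6, max_iter = 80)
  fit <- sequential_fit(bl$W_e, bl$M_s, p)
  # rerunning stage 1 alone reproduces the same B bit for bit
  fit2 <- sequential_fit(bl$W_e, bl$M_s, p)
  expect_identical(fit$B, fit2$B)
  # and the LRR stage leaves B untouched: reconstruction equals stage-1's
  expect_true(all(fit$B >= 0))
})

test_that("sequential and joint reach comparable recon on noiseless data", {
  set.seed(12)
  n <- 50; d <- 5
  A <- matrix(runif(n * d), n, d) %*% matrix(runif(d * n), d, n)
  pj <- joint_params(d = d)
  rj <- sum((A - with(joint_fit(A, A, pj), B %*% F_e))^2)
  rs <- sum((A - with(sequential_fit(A, A, pj), B %*% F_e))^2)
  # both solve the same well-posed planted problem near-exactly; compare
  # with an absolute slack because the residuals themselves are ~0
  expect_lte(rj, 1e-3 * sum(A^2))
  expect_lte(rs, 1e-3 * sum(A^2))
  expect_lte(abs(rj - rs), 0.1 * max(rj, rs) + 1e-4 * sum(A^2))
})

test_that("scaling both layers leaves the cluster structure of Z unchanged", {
  bl <- generate_block_multilayer(n = 60, K = 3, noise_sd = 0.08, seed = 7)
  p <- joint_params(d = 12)
  f1 <- joint_fit(bl$W_e, bl$M_s, p)
  f2 <- joint_fit(5 * bl$W_e, 5 * bl$M_s, p)
  d1 <- leiden_domains(affinity_from_Z(f1$Z), target_K = 3, seed = 0)
  d2 <- leiden_domains(affinity_from_Z(f2$Z), target_K = 3, seed = 0)
  expect_equal(ari(d1$labels, d2$labels), 1)
})

test_that("shape mismatches and bad params are rejected", {
  bl <- generate_block_multilayer(n = 30, K = 2, seed = 0)
  expect_error(joint_fit(bl$W_e, bl$M_s[1:20, 1:20], joint_params(d = 5)),
               class = "mnst_validation_error")
  expect_error(joint_fit(bl$W_e, bl$M_s, joint_params(d = 30)),
               class = "mnst_param_error")
  expect_error(joint_params(gamma = 0), class = "mnst_param_error")
  expect_error(joint_params(d = 1), class = "mnst_param_error")
})
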