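#' Parameters for the joint multi-layer factorization
#'
#' @param d shared feature dimension (stable range roughly 100-200).
#' @param gamma nuclear-norm weight on the representation `Z`, `> 0`.
#' @param lambda l2,1 weight on the error matrix `E`, `> 0`.
#' @param rho0,rho_scale,rho_max ADMM penalty schedule.
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter maximum ADMM iterations.
#' @param seed seed for the randomized fallback initialization.
#' @return A list of class `joint_params`.
#' @export
joint_params <- function(d = 100L, gamma = 1, lambda = 0.1, rho0 = 20,
                         rho_scale = 1.1, rho_max = 1e6, tol = 1e-6,
                         max_iter = 200L, seed = 0L) {
  if (d < 2) stop_param("d must be >= 2")
  if (gamma <= 0 || lambda <= 0) stop_param("gamma and lambda must be > 0")
  structure(list(d = as.integer(d), gamma = gamma, lambda = lambda,
                 rho0 = rho0, rho_scale = rho_scale, rho_max = rho_max,
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "joint_params")
}

# non-negative double-SVD seeding (deterministic); falls back to seeded
# uniform(0,1) columns where a component carries no usable sign structure
nndsvd_init <- function(A, d, seed) {
  n <- nrow(A)
  s <- svd(A, nu = min(d, n), nv = min(d, n))
  B <- matrix(0, n, d); H <- matrix(0, d, ncol(A))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (j in seq_len(d)) {
    if (j > length(s$d) || s$d[j] <= 1e-12) {
      B[, j] <- stats::runif(n) * sqrt(mean(abs(A)) + 1e-12)
      H[j, ] <- stats::runif(ncol(A)) * sqrt(mean(abs(A)) + 1e-12)
      next
    }
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      sc <- sqrt(s$d[j] * nup * nvp)
      B[, j] <- sc * up / nup; H[j, ] <- sc * vp / nvp
    } else if (nun * nvn > 0) {
      sc <- sqrt(s$d[j] * nun * nvn)
      B[, j] <- sc * un / nun; H[j, ] <- sc * vn / nvn
    } else {
      B[, j] <- stats::runif(n) * sqrt(mean(abs(A)) + 1e-12)
      H[j, ] <- stats::runif(ncol(A)) * sqrt(mean(abs(A)) + 1e-12)
    }
  }
  list(B = B, H = H)
}

# singular value thresholding; values exactly at the threshold are zeroed
svt <- function(A, tau) {
  s <- svd(A)
  keep <- pmax(s$d - tau, 0)
  nz <- keep > 0
  if (!any(nz)) return(list(M = matrix(0, nrow(A), ncol(A)), nuclear = 0))
  M <- s$u[, nz, drop = FALSE] %*% (keep[nz] * t(s$v[, nz, drop = FALSE]))
  list(M = M, nuclear = sum(keep))
}

# one HALS sweep for min ||A - B F||^2, F >= 0 (rows of F updated in turn;
# exact coordinate minimization, hence monotone in the reconstruction)
hals_F <- function(B, A, F) {
  BtB <- crossprod(B)
  BtA <- crossprod(B, A)
  dg <- pmax(diag(BtB), .Machine$double.eps)
  for (j in seq_len(nrow(F)))
    F[j, ] <- pmax(F[j, ] + (BtA[j, ] - BtB[j, ] %*% F) / dg[j], 0)
  F
}

# one HALS sweep for the B factor given FF = Fe Fe' + Fs Fs' and
# WF = We Fe' + Ms Fs'
hals_B <- function(B, FF, WF) {
  dg <- pmax(diag(FF), .Machine$double.eps)
  for (j in seq_len(ncol(B)))
    B[, j] <- pmax(B[, j] + (WF[, j] - B %*% FF[, j]) / dg[j], 0)
  B
}

# columnwise l2,1 shrinkage: each column scaled by max(0, 1 - tau/||col||)
l21_shrink <- function(V, tau) {
  nrm <- sqrt(colSums(V^2))
  sc <- pmax(1 - tau / pmax(nrm, .Machine$double.eps), 0)
  sweep(V, 2, sc, "*")
}

#' Jointly factorize the two network layers and learn the cell affinity
#' representation
#'
#' Optimizes
#' \deqn{\|W_e - B F_e\|_F^2 + \|M_s - B F_s\|_F^2 + \gamma \|Z\|_*
#'       + \lambda \|E\|_{2,1}}
#' subject to \eqn{B, F_e, F_s \ge 0} and \eqn{B^\top = B^\top Z + E}.
#' The shared non-negative factor `B` couples the expression layer `W_e` and
#' the high-order spatial layer `M_s`, and the low-rank representation `Z`
#' (learned on the rows of `B`) yields the affinity graph that is clustered
#' into spatial domains.
#'
#' Optimization warm-starts from the uncoupled two-layer NMF (HALS run to
#' tolerance), then applies inexact-ALM ADMM with an auxiliary copy `J = Z`:
#' per iteration, `F_e`/`F_s` take exact HALS non-negative least-squares
#' sweeps, `B` takes a HALS sweep plus projected-gradient steps on its
#' quadratic subproblem, `J` is updated by singular-value thresholding at
#' `gamma/rho`, `Z` by a Woodbury linear solve, `E` by columnwise l2,1
#' shrinkage at `lambda/rho`, followed by dual ascent and penalty growth.
#' The recorded objective trace evaluates the objective at the feasible
#' surrogate point `(B, F_e, F_s, J, B' - B'J)`, i.e. with the linear
#' constraint eliminated, so it is a true objective value at every iteration.
#'
#' @param W_e expression layer: an [learn_expression_graph()] result or an
#'   n x n non-negative matrix.
#' @param M_s spatial layer: a [pmi_matrix()] result or an n x n
#'   non-negative matrix.
#' @param params a [joint_params()].
#' @return A list of class `joint_factor_model` with elements `B`, `F_e`,
#'   `F_s`, `Z`, `E`, `params`, and `report` (class `convergence_report`:
#'   trace data frame with objective and constraint residual, plus the stop
#'   reason).
#' @export
joint_fit <- function(W_e, M_s, params = joint_params()) {
  We <- layer_matrix(W_e); Ms <- layer_matrix(M_s)
  # warm start the non-convex ADMM from the uncoupled NMF solution; the
  # coupled phase then refines B, F_e, F_s jointly with Z and E
  init <- .nmf_stage(We, Ms, params)
  .joint_admm(We, Ms, params, update_factors = TRUE, init = init)
}

# plain two-layer NMF (reconstruction terms only) by HALS, used as the
# warm start of joint_fit and as stage 1 of sequential_fit
.nmf_stage <- function(We, Ms, params) {
  n <- nrow(We)
  if (!all(dim(Ms) == dim(We))) stop_valid("layer dimension mismatch")
  if (params$d >= n) stop_param("d must be smaller than n")
  ini <- nndsvd_init(We, params$d, params$seed)
  B <- ini$B; Fe <- ini$H; Fs <- ini$H
  prev <- Inf
  for (it in seq_len(params$max_iter)) {
    Fe <- hals_F(B, We, Fe)
    Fs <- hals_F(B, Ms, Fs)
    B <- hals_B(B, tcrossprod(Fe) + tcrossprod(Fs),
                We %*% t(Fe) + Ms %*% t(Fs))
    rec <- fnorm(We - B %*% Fe)^2 + fnorm(Ms - B %*% Fs)^2
    if (is.finite(prev) && abs(prev - rec) <= params$tol * max(1, prev)) break
    prev <- rec
  }
  list(B = B, Fe = Fe, Fs = Fs, iterations = it)
}

#' Non-joint (sequential) ablation of the factorization
#'
#' First solves the plain joint NMF (the reconstruction terms only) to
#' convergence, then freezes `B` and solves the low-rank representation
#' subproblem on it.  `B` after stage 2 is bit-identical to `B` after
#' stage 1.  Exists for the joint-vs-sequential ablation comparison.
#'
#' @inheritParams joint_fit
#' @return Same structure as [joint_fit()].
#' @export
sequential_fit <- function(W_e, M_s, params = joint_params()) {
  We <- layer_matrix(W_e); Ms <- layer_matrix(M_s)
  init <- .nmf_stage(We, Ms, params)
  fit <- .joint_admm(We, Ms, params, update_factors = FALSE, init = init)
  fit$report$stage1_iterations <- init$iterations
  fit
}

.joint_admm <- function(We, Ms, params, update_factors = TRUE, init = NULL) {
  n <- nrow(We)
  if (!all(dim(We) == c(n, n)) || !all(dim(Ms) == c(n, n)))
    stop_valid("layers must be square matrices of matching size")
  check_finite(We, "W_e"); check_finite(Ms, "M_s")
  if (params$d >= n) stop_param("d must be smaller than n")
  d <- params$d
  gamma <- params$gamma; lambda <- params$lambda
  eps <- .Machine$double.eps

  if (is.null(init)) {
    ini <- nndsvd_init(We, d, params$seed)
    B <- ini$B; Fe <- ini$H; Fs <- ini$H
  } else {
    B <- init$B; Fe <- init$Fe; Fs <- init$Fs
  }
  Z <- matrix(0, n, n); J <- matrix(0, n, n)
  E <- matrix(0, d, n)
  Y1 <- matrix(0, d, n); Y2 <- matrix(0, n, n)
  rho <- params$rho0

  obj_surrogate <- function(nuclear_J) {
    rec <- fnorm(We - B %*% Fe)^2 + fnorm(Ms - B %*% Fs)^2
    Efeas <- t(B) - crossprod(B, J)    # B' - B'J, feasible error
    rec + gamma * nuclear_J + lambda * sum(sqrt(colSums(Efeas^2)))
  }

  trace_df <- data.frame(iter = integer(), objective = numeric(),
                         constraint_residual = numeric())
  obj_prev <- obj_surrogate(0)
  bad <- 0L
  stop_reason <- "max_iter"
  for (it in seq_len(params$max_iter)) {
    if (update_factors) {
      # F blocks: exact HALS (hierarchical non-negative least squares)
      Fe <- hals_F(B, We, Fe)
      Fs <- hals_F(B, Ms, Fs)
      # B block: HALS sweep on the reconstruction terms, then projected
      # gradient steps that fold in the constraint-coupling penalty
      #   rho/2 ||B'(I-Z) - (E - Y1/rho)||^2
      FF <- tcrossprod(Fe) + tcrossprod(Fs)
      WF <- We %*% t(Fe) + Ms %*% t(Fs)
      B <- hals_B(B, FF, WF)
      IZ <- diag(n) - Z
      Gt <- E - Y1 / rho
      lip <- 2 * spec_norm_psd(FF) + rho * spec_norm_psd(IZ %*% t(IZ)) + eps
      step <- 1 / lip
      for (s in 1:2) {
        gradB <- 2 * (B %*% FF - WF) +
          rho * IZ %*% (crossprod(IZ, B) - t(Gt))
        B <- pmax(B - step * gradB, 0)
      }
    }
    # J block: SVT of Z + Y2/rho at gamma/rho
    sv <- svt(Z + Y2 / rho, gamma / rho)
    J <- sv$M
    # Z block: (B B' + I) Z = B (B' - E + Y1/rho) + J - Y2/rho  (Woodbury)
    Tm <- t(B) - E + Y1 / rho
    RHS <- B %*% Tm + J - Y2 / rho
    K <- chol2inv(chol(diag(d) + crossprod(B)))
    Z <- RHS - B %*% (K %*% (crossprod(B, RHS)))
    # E block: columnwise l2,1 shrinkage
    V <- t(B) - crossprod(B, Z) + Y1 / rho
    E <- l21_shrink(V, lambda / rho)
    # dual ascent
    R1 <- t(B) - crossprod(B, Z) - E
    Y1 <- Y1 + rho * R1
    Y2 <- Y2 + rho * (Z - J)
    cres <- fnorm(R1) / max(1, fnorm(t(B)))
    split <- fnorm(Z - J) / max(1, fnorm(Z))
    # grow the penalty only while the primal residuals still dominate;
    # freezing rho once they are resolved damps late dual oscillation
    if (cres > 1e-8 || split > 1e-8)
      rho <- min(rho * params$rho_scale, params$rho_max)

    obj <- obj_surrogate(sv$nuclear)
    trace_df <- rbind(trace_df, data.frame(iter = it, objective = obj,
                                           constraint_residual = cres))
    if (obj > obj_prev * (1 + 1e-3) + 1e-8) bad <- bad + 1L else bad <- 0L
    if (bad >= 10L)
      stop_opt("joint ADMM diverged: objective increased 5 consecutive steps",
               trace = trace_df)
    if (it > 10 && abs(obj - obj_prev) <= params$tol * max(1, abs(obj_prev)) &&
        cres <= 1e-4 && split <= 1e-4) {
      obj_prev <- obj
      stop_reason <- "converged"
      break
    }
    obj_prev <- obj
  }
  report <- structure(list(trace = trace_df, stop_reason = stop_reason,
                           iterations = nrow(trace_df)),
                      class = "convergence_report")
  structure(list(B = B, F_e = Fe, F_s = Fs, Z = Z, E = E,
                 params = params, report = report),
            class = "joint_factor_model")
}

#' Evaluate the joint objective at a model
#'
#' Returns the scalar value of the combined objective — the two squared
#' Frobenius reconstruction residuals plus `gamma` times the nuclear norm of
#' `Z` and `lambda` times the l2,1 norm of `E` — at the model's stored
#' variables.
#'
#' @param model a `joint_factor_model` (or a list with `B`, `F_e`, `F_s`,
#'   `Z`, `E`).
#' @param W_e,M_s the two layers.
#' @param params a [joint_params()] supplying `gamma` and `lambda`.
#' @return A single numeric value.
#' @export
objective_value <- function(model, W_e, M_s, params = model$params) {
  We <- layer_matrix(W_e); Ms <- layer_matrix(M_s)
  for (nm in c("B", "F_e", "F_s", "Z", "E"))
    check_finite(model[[nm]], nm)
  rec <- fnorm(We - model$B %*% model$F_e)^2 +
    fnorm(Ms - model$B %*% model$F_s)^2
  rec + params$gamma * sum(svd(model$Z, nu = 0, nv = 0)$d) +
    params$lambda * sum(sqrt(colSums(model$E^2)))
}

#' @export
print.joint_factor_model <- function(x, ...) {
  cat("joint_factor_model: n =", nrow(x$B), ", d =", ncol(x$B),
      "|", x$report$stop_reason, "after", x$report$iterations, "iterations\n")
  invisible(x)
}
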