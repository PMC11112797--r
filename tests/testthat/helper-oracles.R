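# Independent oracles: deliberately naive implementations used to verify the
# package's optimized code paths.

# elementwise PMI by direct loop over the adjacency matrix
pmi_oracle <- function(W, kappa = 1, clip = TRUE) {
  n <- nrow(W)
  d <- rowSums(W)
  total <- sum(d)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (W[i, j] > 0) {
      v <- log(W[i, j] * total / (d[i] * d[j])) - log(kappa)
      M[i, j] <- if (clip) max(v, 0) else v
    }
  }
  M
}

# plain (unaccelerated) projected proximal gradient for the
# self-representation program, run long with a conservative step
srl_pg_oracle <- function(X, alpha, beta = 0, L = NULL, iters = 30000) {
  n <- nrow(X)
  G <- tcrossprod(X)
  lip <- 2 * norm(G, "2") + if (!is.null(L)) 2 * beta * norm(L, "2") else 0
  W <- matrix(0, n, n)
  st <- 1 / lip
  for (i in seq_len(iters)) {
    gr <- 2 * G %*% (W - diag(n))
    if (!is.null(L)) gr <- gr + 2 * beta * W %*% L
    W <- pmax(W - st * gr - st * alpha, 0)
    diag(W) <- 0
  }
  obj <- sum((t(X) - t(X) %*% W)^2) + alpha * sum(W) +
    if (!is.null(L)) beta * sum(W * (W %*% L)) else 0
  list(W = W, objective = obj)
}

# pair-counting ARI: loop over all pairs of observations
ari_oracle <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  maxidx <- ((a + b) + (a + c_)) / 2
  if (maxidx == expected) return(1)
  (a - expected) / (maxidx - expected)
}

# Davies-Bouldin by the direct formula
db_oracle <- function(X, labels) {
  ks <- unique(labels)
  cen <- t(sapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE])))
  sc <- sapply(seq_along(ks), function(i) {
    P <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((P - matrix(cen[i, ], nrow(P), ncol(P), byrow = TRUE))^2)))
  })
  K <- length(ks)
  mean(sapply(seq_len(K), function(i) {
    max(sapply(setdiff(seq_len(K), i), function(j) {
      (sc[i] + sc[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
    }))
  }))
}

# silhouette by the direct per-point definition
silhouette_oracle <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- length(labels)
  mean(sapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(k)
      mean(D[i, labels == k])))
    (b - a) / max(a, b)
  }))
}

# objective of the joint program via a dense SVD
joint_objective_oracle <- function(model, We, Ms, gamma, lambda) {
  sum((We - model$B %*% model$F_e)^2) + sum((Ms - model$B %*% model$F_s)^2) +
    gamma * sum(svd(model$Z)$d) + lambda * sum(sqrt(colSums(model$E^2)))
}

# random sparse symmetric non-negative graph for property tests
random_graph <- function(n, density = 0.2) {
  W <- matrix(0, n, n)
  m <- max(1, round(density * n * (n - 1) / 2))
  idx <- which(upper.tri(W))
  sel <- sample(idx, min(m, length(idx)))
  W[sel] <- runif(length(sel), 0.1, 2)
  W + t(W)
}
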