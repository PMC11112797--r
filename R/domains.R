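#' Symmetrize the learned representation into a cell affinity graph
#'
#' `S = (|Z| + |Z'|)/2` with the diagonal zeroed — the standard
#' subspace-clustering symmetrization.  The result is exactly symmetric,
#' non-negative, with zero diagonal.
#'
#' @param Z n x n numeric matrix (e.g. the `Z` of a [joint_fit()] model).
#' @return A dense symmetric affinity matrix of class `affinity_graph`.
#' @export
affinity_from_Z <- function(Z) {
  Z <- as_dense(Z)
  check_finite(Z, "Z")
  S <- (abs(Z) + t(abs(Z))) / 2
  diag(S) <- 0
  structure(S, class = c("affinity_graph", class(matrix())))
}

affinity_matrix <- function(S) {
  if (inherits(S, "affinity_graph")) unclass(S) else as_dense(S)
}

#' Partition the affinity graph into spatial domains with Leiden
#'
#' Runs Leiden community detection (modularity objective with a resolution
#' parameter) on the weighted affinity graph.  Give either a fixed
#' `resolution`, or a `target_K`: in the latter case resolutions 0.01, 0.02,
#' ... (cap 3.00) are scanned with a fixed seed and the smallest resolution
#' yielding exactly `target_K` communities is returned; if no resolution
#' achieves it, the resolution whose community count is closest to the
#' target (ties broken toward the lower resolution) is returned with a
#' warning.
#'
#' @param S an `affinity_graph` (or symmetric non-negative matrix) with at
#'   least one edge.
#' @param target_K desired number of domains (exclusive with `resolution`).
#' @param resolution fixed Leiden resolution (exclusive with `target_K`).
#' @param seed RNG seed; identical inputs and seed give identical labels.
#' @return A list of class `domain_assignment`: `labels` (integer domain per
#'   spot), `resolution`, `K`.
#' @export
leiden_domains <- function(S, target_K = NULL, resolution = NULL, seed = 0L) {
  S <- affinity_matrix(S)
  if (is.null(target_K) == is.null(resolution))
    stop_param("give exactly one of target_K or resolution")
  if (all(S == 0)) stop_valid("affinity graph has no edges")
  n <- nrow(S)
  if (!is.null(target_K) && target_K > n) stop_param("target_K exceeds n")
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  run <- function(res, n_iter) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res, n_iterations = n_iter)
    igraph::membership(cl)
  }
  # the scan uses cheap refinement; the selected resolution is re-run with
  # deep refinement (better modularity optima), kept only if the community
  # count is unchanged so the grid-search contract stays intact
  finish <- function(memb, res, want_K = NULL) {
    deep <- run(res, 25L)
    if (is.null(want_K) || length(unique(deep)) == want_K) memb <- deep
    structure(list(labels = as.integer(memb), resolution = res,
                   K = length(unique(memb))),
              class = "domain_assignment")
  }
  if (!is.null(resolution)) {
    return(finish(run(resolution, 3L), resolution))
  }
  grid <- seq(0.01, 3.00, by = 0.01)
  best <- NULL
  for (res in grid) {
    memb <- run(res, 3L)
    K <- length(unique(memb))
    if (K == target_K) return(finish(memb, res, target_K))
    if (is.null(best) || abs(K - target_K) < abs(best$K - target_K)) {
      best <- list(labels = as.integer(memb), resolution = res, K = K)
    }
  }
  warning("no resolution in [0.01, 3.00] yields exactly ", target_K,
          " domains; returning closest (K = ", best$K, " at resolution ",
          best$resolution, ")")
  structure(best, class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("domain_assignment:", length(x$labels), "spots in", x$K,
      "domains (resolution", x$resolution, ")\n")
  invisible(x)
}

label_vector <- function(labels) {
  if (inherits(labels, "domain_assignment")) labels$labels
  else as.integer(factor(labels))
}

#' Adjusted Rand index between two partitions
#'
#' The Hubert-Arabie chance-corrected pair-counting agreement,
#' `(index - expected) / (max - expected)`, computed from the contingency
#' counts of the two labelings.  1 for identical partitions (up to label
#' permutation), about 0 for independent ones.
#'
#' @param truth,pred label vectors of equal length (length >= 2).
#' @return A single numeric value in `[-1, 1]`.
#' @export
ari <- function(truth, pred) {
  truth <- label_vector(truth); pred <- label_vector(pred)
  if (length(truth) != length(pred)) stop_valid("label length mismatch")
  n <- length(truth)
  if (n < 2) stop_param("need at least 2 observations")
  tab <- table(truth, pred)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)       # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

#' Mean silhouette coefficient of a clustering
#'
#' Per-spot score `(b - a) / max(a, b)` with `a` the mean intra-cluster
#' distance and `b` the mean distance to the nearest other cluster; spots in
#' singleton clusters score 0.  Accepts either a feature matrix (Euclidean
#' distances on rows) or an `affinity_graph`, which is converted to the
#' dissimilarity `1 / (1 + S)`.
#'
#' @param x spots x p feature matrix, `dist` object, or `affinity_graph`.
#' @param labels cluster labels (>= 2 clusters required).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  labels <- label_vector(labels)
  if (length(unique(labels)) < 2) stop_param("silhouette undefined for a single cluster")
  D <- if (inherits(x, "affinity_graph")) {
    S <- affinity_matrix(x); M <- 1 / (1 + S); diag(M) <- 0; M
  } else if (inherits(x, "dist")) {
    as.matrix(x)
  } else {
    as.matrix(stats::dist(as_dense(x)))
  }
  n <- length(labels)
  if (nrow(D) != n) stop_valid("labels length does not match x")
  ulab <- unique(labels)
  sizes <- table(factor(labels, levels = ulab))
  # mean distance of each point to each cluster
  agg <- sapply(ulab, function(k) rowSums(D[, labels == k, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], ulab)
    nk <- sizes[[k]]
    if (nk == 1) { s[i] <- 0; next }
    a <- agg[i, k] / (nk - 1)
    b <- min(agg[i, -k] / as.numeric(sizes[-k]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin score of a clustering
#'
#' Average over clusters of the maximal ratio
#' `(s_i + s_j) / d(c_i, c_j)`, where `s_i` is the mean distance of cluster
#' `i`'s members to its centroid and `d(c_i, c_j)` the centroid distance.
#' Lower is better; compact, well-separated clusterings approach 0.
#'
#' @param features spots x p feature matrix.
#' @param labels cluster labels (>= 2 clusters).
#' @return Non-negative numeric value.
#' @export
davies_bouldin <- function(features, labels) {
  features <- as_dense(features)
  labels <- label_vector(labels)
  ulab <- unique(labels)
  K <- length(ulab)
  if (K < 2) stop_param("Davies-Bouldin undefined for a single cluster")
  centroids <- t(sapply(ulab, function(k)
    colMeans(features[labels == k, , drop = FALSE])))
  scatter <- sapply(seq_len(K), function(k) {
    pts <- features[labels == ulab[k], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centroids[k, ])^2)))
  })
  M <- as.matrix(stats::dist(centroids))
  db_k <- sapply(seq_len(K), function(i) {
    max(sapply(setdiff(seq_len(K), i), function(j)
      (scatter[i] + scatter[j]) / M[i, j]))
  })
  mean(db_k)
}

#' Compute ARI, silhouette, and Davies-Bouldin for a domain assignment
#'
#' @param pred predicted labels (or `domain_assignment`).
#' @param truth optional ground-truth labels; ARI is `NA` without them.
#' @param features optional feature matrix for SC/DB (e.g. the `B` rows of
#'   the model); when absent and `S` is given, silhouette falls back to the
#'   graph dissimilarity and DB is `NA`.
#' @param S optional `affinity_graph` for the graph-based silhouette.
#' @return A list with `ari`, `sc`, `db`.
#' @export
clustering_scores <- function(pred, truth = NULL, features = NULL, S = NULL) {
  pred <- label_vector(pred)
  list(
    ari = if (!is.null(truth)) ari(truth, pred) else NA_real_,
    sc = if (!is.null(features)) silhouette_score(features, pred)
         else if (!is.null(S)) silhouette_score(S, pred) else NA_real_,
    db = if (!is.null(features)) davies_bouldin(features, pred) else NA_real_)
}
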