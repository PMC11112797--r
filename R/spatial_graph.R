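#' Build the inverse-distance k-nearest-neighbour spatial graph
#'
#' Connects each spot to its `k` nearest spatial neighbours (Euclidean
#' distance `r`) with edge weight `1/r`, then symmetrizes by elementwise
#' maximum, so the weight keeps its inverse-distance meaning and the matrix
#' is symmetric with at most `2kn` nonzeros.  Pairs at exactly coincident
#' coordinates get weight `1/eps`, where `eps` is the smallest positive
#' distance observed among selected neighbour pairs — finite, but still
#' ranked closest.
#'
#' Typical `k` by platform: 6 for 10x Visium, 8 for Slide-seq and
#' Stereo-seq, 15 for imaging-based platforms.
#'
#' @param coords spots x 2 numeric coordinate matrix.
#' @param k number of neighbours per spot, `1 <= k < n`.
#' @return A `spatial_graph`: list with sparse symmetric `W_s` and the
#'   coordinates.
#' @export
build_spatial_knn <- function(coords, k = 6L) {
  coords <- as.matrix(coords)
  check_finite(coords, "coords")
  n <- nrow(coords)
  if (k < 1) stop_param("k must be >= 1")
  if (k >= n) stop_param("k must be smaller than the number of spots")
  d2 <- outer(coords[, 1], coords[, 1], "-")^2 +
        outer(coords[, 2], coords[, 2], "-")^2
  diag(d2) <- Inf
  if (all(d2[upper.tri(d2)] == 0)) stop_valid("all spots coincident: degenerate geometry")
  ii <- integer(n * k); jj <- integer(n * k); rr <- numeric(n * k)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    idx <- ((i - 1) * k + 1):(i * k)
    ii[idx] <- i; jj[idx] <- nb; rr[idx] <- sqrt(d2[i, nb])
  }
  pos <- rr[rr > 0]
  if (length(pos) == 0) stop_valid("all selected neighbour pairs coincident")
  eps <- min(pos)
  w <- ifelse(rr == 0, 1 / eps, 1 / rr)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- pmax_sparse(W, Matrix::t(W))          # symmetrize by elementwise max
  structure(list(W_s = W, coords = coords), class = "spatial_graph")
}

# elementwise max of two sparse matrices with identical pattern support
pmax_sparse <- function(A, B) {
  S <- (A + B + abs(A - B)) / 2
  Matrix::drop0(S)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph:", nrow(x$W_s), "spots,",
      Matrix::nnzero(x$W_s) / 2, "undirected edges\n")
  invisible(x)
}

spatial_weights <- function(spatial) {
  if (inherits(spatial, "spatial_graph")) spatial$W_s
  else if (is.matrix(spatial) || inherits(spatial, "Matrix")) spatial
  else stop_param("expected a spatial_graph or adjacency matrix")
}

#' Graph Laplacian of a spatial graph
#'
#' `L = D - W` with `D` the diagonal of weighted degrees; symmetric positive
#' semidefinite.  Used as the fixed local-preservation operator in
#' [learn_expression_graph()].
#'
#' @param spatial a [spatial_graph()] or symmetric adjacency matrix.
#' @return A dense symmetric PSD matrix.
#' @export
graph_laplacian <- function(spatial) {
  W <- as_dense(spatial_weights(spatial))
  diag(Matrix::rowSums(W)) - W
}

#' High-order pointwise-mutual-information matrix of the spatial graph
#'
#' Lifts the first-order spatial graph to its PMI transform: for every edge
#' with weight `w_ij`,
#' `m_ij = log(w_ij * sum(d) / (d_i * d_j)) - log(kappa)`,
#' where `d` are the weighted degrees and `kappa` is the negative-sampling
#' count (default 1).  Non-edges stay 0, and negative PMI values are clipped
#' to 0 when `clip = TRUE` (the positive-PMI convention); set `clip = FALSE`
#' to keep the signed values.
#'
#' @param spatial a [spatial_graph()] or symmetric non-negative adjacency
#'   matrix with at least one edge.
#' @param kappa positive integer shift, subtracted as `log(kappa)`.
#' @param clip clip negative PMI values to zero (default `TRUE`).
#' @return A `high_order_matrix`: list with dense `M_s` and degree vector `d`.
#' @export
pmi_matrix <- function(spatial, kappa = 1L, clip = TRUE) {
  W <- as_dense(spatial_weights(spatial))
  if (any(W < 0)) stop_valid("spatial weights must be non-negative")
  if (all(W == 0)) stop_valid("empty spatial graph")
  if (kappa < 1) stop_param("kappa must be >= 1")
  d <- rowSums(W)
  total <- sum(d)
  M <- matrix(0, nrow(W), ncol(W))
  nz <- which(W > 0)
  dd <- outer(d, d)
  M[nz] <- log(W[nz] * total / dd[nz]) - log(kappa)
  if (clip) M[nz] <- pmax(M[nz], 0)
  structure(list(M_s = M, d = d, kappa = kappa, clipped = clip),
            class = "high_order_matrix")
}

layer_matrix <- function(x) {
  if (inherits(x, "high_order_matrix")) x$M_s
  else if (inherits(x, "expression_graph")) x$W_e
  else if (inherits(x, "spatial_graph")) as_dense(x$W_s)
  else if (is.matrix(x) || inherits(x, "Matrix")) as_dense(x)
  else stop_param("expected a network layer (matrix or graph object)")
}
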