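#' Remove genes expressed in too few spots
#'
#' Drops genes with a nonzero count in fewer than `min_spots` spots (strictly
#' fewer: a gene seen in exactly `min_spots` spots is kept).  The spot set is
#' unchanged.
#'
#' @param data a [slice_data()].
#' @param min_spots minimum number of expressing spots (default 10).
#' @return A filtered [slice_data()].
#' @export
filter_genes <- function(data, min_spots = 10L) {
  stopifnot(inherits(data, "slice_data"))
  if (min_spots < 0) stop_param("min_spots must be >= 0")
  n_expr <- Matrix::colSums(data$counts > 0)
  keep <- n_expr >= min_spots
  if (!any(keep)) stop_valid("all genes removed by filter_genes")
  slice_data(data$counts[, keep, drop = FALSE], data$coords,
             spot_ids = data$spot_ids, gene_ids = data$gene_ids[keep],
             labels = data$labels, slice_of = data$slice_of)
}

#' Library-size normalize and log-transform counts
#'
#' Each spot is scaled so its total count equals `target_sum`, then
#' `log1p` is applied.  The default `target_sum` is the median library size
#' of the slice.
#'
#' @param data a [slice_data()].
#' @param target_sum positive scalar; total count per spot after scaling.
#' @return A dense spots x genes matrix of log-normalized expression.
#' @export
normalize_log <- function(data, target_sum = NULL) {
  stopifnot(inherits(data, "slice_data"))
  lib <- Matrix::rowSums(data$counts)
  if (any(lib == 0)) {
    bad <- data$spot_ids[which(lib == 0)[1]]
    stop_valid("spot with zero library size: ", bad)
  }
  if (is.null(target_sum)) target_sum <- stats::median(lib)
  if (target_sum <= 0) stop_param("target_sum must be positive")
  scaled <- as_dense(data$counts) * (target_sum / lib)
  out <- log1p(scaled)
  dimnames(out) <- dimnames(data$counts)
  out
}

#' Keep the highest-variance genes
#'
#' Retains the `n_hvg` genes of largest variance across spots, preserving the
#' input column order.  Ties at the variance cut are broken in favour of the
#' lower column index, so the selection is deterministic.
#'
#' @param expr spots x genes numeric matrix (normalized expression).
#' @param n_hvg number of genes to keep.
#' @return `expr` restricted to the selected genes.
#' @export
select_hvg <- function(expr, n_hvg) {
  expr <- as_dense(expr)
  if (n_hvg <= 0) stop_param("n_hvg must be positive")
  if (n_hvg > ncol(expr)) stop_param("n_hvg exceeds number of genes")
  v <- apply(expr, 2, stats::var)
  ord <- order(-v, seq_along(v))           # variance desc, column index asc
  keep <- sort(ord[seq_len(n_hvg)])
  expr[, keep, drop = FALSE]
}

#' Smooth expression profiles with spatial neighbours
#'
#' Replaces each spot's profile with the convex combination
#' `(1 - mu) * own + mu * weighted mean of neighbours`, where neighbour
#' weights are the spatial-graph edge weights normalized per spot.  The
#' mixing operator is row-stochastic: its row sums are exactly 1.  Spots with
#' no neighbours keep their own profile for any `mu`.
#'
#' @param expr spots x genes numeric matrix.
#' @param spatial a [spatial_graph()] over the same spots.
#' @param mu mixing weight in `[0, 1)`; `mu = 0` is the identity.
#' @return Smoothed matrix of the same shape.
#' @export
augment_expression <- function(expr, spatial, mu = 0.2) {
  expr <- as_dense(expr)
  W <- spatial_weights(spatial)
  if (nrow(W) != nrow(expr))
    stop_valid("spatial graph has ", nrow(W), " spots but expr has ", nrow(expr))
  if (mu < 0 || mu >= 1) stop_param("mu must be in [0, 1)")
  if (mu == 0) return(expr)
  deg <- Matrix::rowSums(W)
  has_nb <- deg > 0
  P <- W
  P[has_nb, ] <- P[has_nb, , drop = FALSE] / deg[has_nb]
  out <- (1 - mu) * expr + mu * as_dense(P %*% expr)
  out[!has_nb, ] <- expr[!has_nb, , drop = FALSE]
  dimnames(out) <- dimnames(expr)
  out
}

#' Reduce expression to leading principal components
#'
#' Column-centers `expr` and returns the scores on the leading `n_pcs`
#' principal components.  The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the result
#' deterministic across linear-algebra backends.
#'
#' @param expr spots x genes numeric matrix.
#' @param n_pcs number of components (the feature dimension, default 50).
#' @param seed kept for interface symmetry; the computation is deterministic.
#' @return A `feature_matrix`: list with `X` (spots x n_pcs scores) and
#'   `spot_ids`.
#' @export
pca_reduce <- function(expr, n_pcs = 50L, seed = 0L) {
  expr <- as_dense(expr)
  check_finite(expr, "expr")
  n <- nrow(expr); g <- ncol(expr)
  if (n_pcs > min(n, g)) stop_param("n_pcs exceeds min(spots, genes)")
  Xc <- sweep(expr, 2, colMeans(expr))
  if (n <= g) {
    K <- tcrossprod(Xc)                       # n x n Gram, cheaper side
    e <- eigen(K, symmetric = TRUE)
    sv <- sqrt(pmax(e$values[seq_len(n_pcs)], 0))
    U <- e$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- U * rep(sv, each = n)
    loadings <- crossprod(Xc, U)
    loadings <- sweep(loadings, 2, pmax(sv, .Machine$double.eps), "/")
  } else {
    s <- svd(Xc, nu = n_pcs, nv = n_pcs)
    scores <- s$u * rep(s$d[seq_len(n_pcs)], each = n)
    loadings <- s$v
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(X = scores, spot_ids = rownames(expr)),
            class = "feature_matrix")
}

#' Stack multiple slices into one for integrative analysis
#'
#' Concatenates the spots of several slices and restricts genes to the
#' intersection of their gene sets.  In `shared` mode coordinates are kept as
#' given (slices are assumed pre-aligned, so cross-slice spatial neighbours
#' can form and adjacent spots across slices reinforce each other); in
#' `offset` mode each slice is translated along x so slices are spatially
#' disjoint.  The originating slice of each spot is recorded in `slice_of`.
#'
#' @param slices list of two or more [slice_data()] objects.
#' @param coordinate_mode `"shared"` or `"offset"`.
#' @return A stacked [slice_data()] with unique spot ids
#'   (`<slice>.<spot_id>`) and the `slice_of` tag filled.
#' @export
stack_slices <- function(slices, coordinate_mode = c("shared", "offset")) {
  coordinate_mode <- match.arg(coordinate_mode)
  if (length(slices) < 2) stop_param("need at least 2 slices")
  genes <- Reduce(intersect, lapply(slices, function(s) s$gene_ids))
  if (length(genes) == 0) stop_join("empty gene intersection across slices")
  names(slices) <- names(slices) %||% paste0("s", seq_along(slices))
  offset <- 0
  parts <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    coords <- s$coords
    if (coordinate_mode == "offset") {
      span <- max(coords[, 1]) - min(coords[, 1])
      shift <- offset - min(coords[, 1])
      coords[, 1] <- coords[, 1] + shift
      # gap larger than any intra-slice extent keeps slices disjoint
      offset <- offset + span + 2 * max(span, max(coords[, 2]) - min(coords[, 2]), 1)
    }
    parts[[i]] <- list(
      counts = s$counts[, genes, drop = FALSE],
      coords = coords,
      spot_ids = paste0(names(slices)[i], ".", s$spot_ids),
      labels = if (is.null(s$labels)) rep(NA, nrow(s$counts)) else s$labels,
      slice_of = rep(names(slices)[i], nrow(s$counts)))
  }
  labels <- unlist(lapply(parts, `[[`, "labels"))
  if (all(is.na(labels))) labels <- NULL
  slice_data(do.call(rbind, lapply(parts, `[[`, "counts")),
             do.call(rbind, lapply(parts, `[[`, "coords")),
             spot_ids = unlist(lapply(parts, `[[`, "spot_ids")),
             gene_ids = genes, labels = labels,
             slice_of = unlist(lapply(parts, `[[`, "slice_of")))
}

#' Full preprocessing: filter, normalize, HVG, smooth, PCA
#'
#' Convenience wrapper running [filter_genes()], [normalize_log()],
#' [select_hvg()], [augment_expression()] and [pca_reduce()] in order.
#' Deterministic for fixed inputs.
#'
#' @param data a [slice_data()].
#' @param spatial a [spatial_graph()] on the same spots (used for smoothing);
#'   `NULL` skips the smoothing step.
#' @param min_spots_per_gene,n_hvg,n_pcs,target_sum,mu,seed see the
#'   individual steps.  `n_hvg` is capped at the number of genes surviving
#'   the filter.
#' @return A `feature_matrix`.
#' @export
preprocess_slice <- function(data, spatial = NULL, min_spots_per_gene = 10L,
                             n_hvg = 3000L, n_pcs = 50L, target_sum = NULL,
                             mu = 0.2, seed = 0L) {
  data <- filter_genes(data, min_spots_per_gene)
  expr <- normalize_log(data, target_sum)
  expr <- select_hvg(expr, min(n_hvg, ncol(expr)))
  if (!is.null(spatial)) expr <- augment_expression(expr, spatial, mu)
  pca_reduce(expr, min(n_pcs, ncol(expr), nrow(expr)), seed)
}
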