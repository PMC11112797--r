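#' Topology statistics of the cell affinity graph
#'
#' Per-spot weighted degree (sum of adjacent edge weights), eigenvector
#' centrality (principal eigenvector of the affinity matrix, scaled to unit
#' maximum), and weighted closeness centrality (edge lengths `1/weight`;
#' computed within each connected component).  Also returns a per-edge table
#' tagging each edge as within- or between-domain, for edge-weight
#' comparisons across domains.
#'
#' @param S an `affinity_graph` or symmetric non-negative matrix.
#' @param labels optional domain labels (or a `domain_assignment`); when
#'   given they are attached to the node table and drive the edge tags.
#' @return A list with data frames `nodes` (`spot`, `domain`, `degree`,
#'   `eigen_centrality`, `closeness`) and `edges` (`i`, `j`, `weight`,
#'   `within_domain`).
#' @export
topology_stats <- function(S, labels = NULL) {
  S <- affinity_matrix(S)
  n <- nrow(S)
  if (n == 0) stop_valid("empty graph")
  if (!is.null(labels)) {
    labels <- label_vector(labels)
    if (length(labels) != n) stop_valid("labels length mismatch")
  }
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  deg <- rowSums(S)
  ec <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  # closeness on distances 1/weight, per connected component
  clo <- suppressWarnings(
    igraph::closeness(g, weights = 1 / igraph::E(g)$weight, mode = "all"))
  clo[!is.finite(clo)] <- 0
  nodes <- data.frame(spot = seq_len(n),
                      domain = if (is.null(labels)) NA_integer_ else labels,
                      degree = deg, eigen_centrality = as.numeric(ec),
                      closeness = as.numeric(clo))
  ut <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      weight = S[ut],
                      within_domain = if (is.null(labels)) NA else
                        labels[ut[, 1]] == labels[ut[, 2]])
  list(nodes = nodes, edges = edges)
}
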