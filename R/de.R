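#' Differentially expressed genes between two spatial domains
#'
#' For every gene, a two-sided Wilcoxon rank-sum test compares the
#' log-normalized expression between the spots of two domains; p-values are
#' Benjamini-Hochberg adjusted across all tested genes.  The log2 fold
#' change is computed on the library-normalized (linear-scale) domain means.
#' A gene is reported only if it passes all three filters: expressed
#' (nonzero count) in at least `min_frac` of the spots of each domain,
#' `|log2FC| >= lfc_min`, and adjusted p `<= fdr_max`.
#'
#' @param data a [slice_data()] with raw counts.
#' @param labels domain labels per spot (or a `domain_assignment`).
#' @param domain_a,domain_b the two domain identifiers to compare (fold
#'   change is a over b).
#' @param min_frac expressed-fraction threshold per domain (default 0.8).
#' @param lfc_min minimum absolute log2 fold change (default 2).
#' @param fdr_max maximum BH-adjusted p-value (default 0.05).
#' @param target_sum library-normalization target passed to
#'   [normalize_log()].
#' @return A data frame (class `deg_table`) with one row per retained gene:
#'   `gene`, `domain_pair`, `log2_fc`, `p_value`, `p_adj`, `frac_a`,
#'   `frac_b`, sorted by adjusted p.  The full per-gene statistics are
#'   attached as attribute `"all_genes"`.
#' @export
differential_expression <- function(data, labels, domain_a, domain_b,
                                    min_frac = 0.8, lfc_min = 2,
                                    fdr_max = 0.05, target_sum = NULL) {
  stopifnot(inherits(data, "slice_data"))
  labels <- if (inherits(labels, "domain_assignment")) labels$labels else labels
  if (length(labels) != nrow(data$counts)) stop_valid("labels length mismatch")
  ia <- which(labels == domain_a)
  ib <- which(labels == domain_b)
  if (length(ia) == 0 || length(ib) == 0) stop_valid("empty domain")
  if (length(ia) < 3 || length(ib) < 3)
    stop_valid("underpowered test: a domain has fewer than 3 spots")

  counts <- data$counts
  lib <- Matrix::rowSums(counts)
  if (any(lib[c(ia, ib)] == 0)) stop_valid("zero-library spot in a tested domain")
  if (is.null(target_sum)) target_sum <- stats::median(lib)
  lin <- as_dense(counts) * (target_sum / lib)   # linear normalized
  logx <- log1p(lin)

  frac_a <- Matrix::colMeans(counts[ia, , drop = FALSE] > 0)
  frac_b <- Matrix::colMeans(counts[ib, , drop = FALSE] > 0)
  mean_a <- colMeans(lin[ia, , drop = FALSE])
  mean_b <- colMeans(lin[ib, , drop = FALSE])
  pseudo <- 1e-9
  lfc <- log2((mean_a + pseudo) / (mean_b + pseudo))
  pv <- vapply(seq_len(ncol(counts)), function(g) {
    xa <- logx[ia, g]; xb <- logx[ib, g]
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) return(1)
    stats::wilcox.test(xa, xb, exact = FALSE)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")

  all_genes <- data.frame(gene = data$gene_ids,
                          domain_pair = paste0(domain_a, "_vs_", domain_b),
                          log2_fc = lfc, p_value = pv, p_adj = padj,
                          frac_a = frac_a, frac_b = frac_b,
                          row.names = NULL)
  keep <- frac_a >= min_frac & frac_b >= min_frac &
    abs(lfc) >= lfc_min & padj <= fdr_max & !is.na(padj)
  out <- all_genes[keep, , drop = FALSE]
  out <- out[order(out$p_adj), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_genes") <- all_genes
  class(out) <- c("deg_table", class(out))
  out
}
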