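#' Construct a spatial-transcriptomics slice container
#'
#' `slice_data` bundles a spot-by-gene UMI count matrix with per-spot spatial
#' coordinates, identifiers, and optional ground-truth domain labels.  It is
#' the input container for the preprocessing and pipeline functions.
#'
#' @param counts spots x genes non-negative integer matrix (dense or
#'   `Matrix` sparse).
#' @param coords spots x 2 numeric matrix of spatial coordinates (same row
#'   order as `counts`).
#' @param spot_ids character vector of unique spot identifiers.  Defaults to
#'   the rownames of `counts`.
#' @param gene_ids character vector of unique gene identifiers.  Defaults to
#'   the colnames of `counts`.
#' @param labels optional per-spot domain annotation (factor/character/integer).
#' @param slice_of optional per-spot slice tag, filled by [stack_slices()].
#'
#' @return An object of class `slice_data`: a list with elements `counts`
#'   (sparse `dgCMatrix`), `coords`, `spot_ids`, `gene_ids`, `labels`,
#'   `slice_of`.
#' @export
slice_data <- function(counts, coords, spot_ids = rownames(counts),
                       gene_ids = colnames(counts), labels = NULL,
                       slice_of = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  coords <- as.matrix(coords)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(coords) != nrow(counts))
    stop_valid("coords has ", nrow(coords), " rows but counts has ", nrow(counts))
  if (ncol(coords) != 2) stop_valid("coords must have exactly 2 columns")
  if (length(spot_ids) != nrow(counts)) stop_valid("spot_ids length mismatch")
  if (length(gene_ids) != ncol(counts)) stop_valid("gene_ids length mismatch")
  if (anyDuplicated(spot_ids)) stop_valid("duplicate spot_ids")
  if (anyDuplicated(gene_ids)) stop_valid("duplicate gene_ids")
  if (any(counts@x < 0)) stop_valid("counts contains negative entries")
  if (!all(is.finite(coords))) stop_valid("coords contains non-finite values")
  if (!is.null(labels) && length(labels) != nrow(counts))
    stop_valid("labels length mismatch")
  if (!is.null(slice_of) && length(slice_of) != nrow(counts))
    stop_valid("slice_of length mismatch")
  dimnames(counts) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  structure(list(counts = counts, coords = coords, spot_ids = spot_ids,
                 gene_ids = gene_ids, labels = labels, slice_of = slice_of),
            class = "slice_data")
}

#' @export
print.slice_data <- function(x, ...) {
  cat("slice_data:", nrow(x$counts), "spots x", ncol(x$counts), "genes\n")
  if (!is.null(x$labels))
    cat("  labels:", length(unique(x$labels)), "domains\n")
  if (!is.null(x$slice_of))
    cat("  slices:", paste(unique(x$slice_of), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.slice_data <- function(x) dim(x$counts)
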