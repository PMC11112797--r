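#' Read a spatial slice from count and coordinate files
#'
#' Counts may be Matrix Market (`.mtx`, with `<prefix>_features.tsv` /
#' `<prefix>_barcodes.tsv` sidecar files holding gene and spot identifiers;
#' either genes-by-spots or spots-by-genes orientation is accepted and
#' disambiguated against the sidecar lengths) or a delimited CSV/TSV table
#' with spot identifiers in the first column and gene identifiers in the
#' header.  Coordinates are a delimited table whose first three columns are
#' spot id, x, y.  Spots are joined on spot id; spots missing coordinates are
#' dropped with a message.
#'
#' @param counts_path path to the count matrix.
#' @param coords_path path to the coordinate table.
#' @param labels_path optional path to a `spot_id,label` table.
#' @return A [slice_data()].
#' @export
read_slice <- function(counts_path, coords_path, labels_path = NULL) {
  for (p in c(counts_path, coords_path, labels_path))
    if (!file.exists(p)) stop_input("file not found: ", p)

  if (grepl("\\.mtx$", counts_path)) {
    m <- tryCatch(Matrix::readMM(counts_path),
                  error = function(e) stop_input("unreadable MTX file: ", counts_path))
    prefix <- sub("\\.mtx$", "", counts_path)
    feat_path <- paste0(prefix, "_features.tsv")
    bc_path <- paste0(prefix, "_barcodes.tsv")
    if (!file.exists(feat_path) || !file.exists(bc_path))
      stop_input("missing sidecar files for ", counts_path)
    genes <- readLines(feat_path)
    spots <- readLines(bc_path)
    if (nrow(m) == length(genes) && ncol(m) == length(spots)) {
      counts <- Matrix::t(m); rownames(counts) <- spots; colnames(counts) <- genes
    } else if (nrow(m) == length(spots) && ncol(m) == length(genes)) {
      counts <- m; rownames(counts) <- spots; colnames(counts) <- genes
    } else {
      stop_input("MTX dimensions do not match sidecar lengths")
    }
  } else {
    tab <- tryCatch(
      utils::read.table(counts_path, header = TRUE,
                        sep = if (grepl("\\.tsv$", counts_path)) "\t" else ",",
                        row.names = 1, check.names = FALSE),
      error = function(e) stop_input("unreadable count table: ", counts_path))
    counts <- as.matrix(tab)
  }
  if (any(counts < 0)) stop_valid("counts contains negative entries")

  co <- tryCatch(
    utils::read.table(coords_path, header = TRUE,
                      sep = if (grepl("\\.tsv$", coords_path)) "\t" else ",",
                      check.names = FALSE),
    error = function(e) stop_input("unreadable coords table: ", coords_path))
  if (ncol(co) < 3) stop_input("coords table needs columns spot_id, x, y")
  coord_ids <- as.character(co[[1]])
  keep <- intersect(rownames(counts), coord_ids)
  if (length(keep) == 0) stop_join("no overlapping spot ids between counts and coords")
  n_drop <- nrow(counts) - length(keep)
  if (n_drop > 0)
    message(n_drop, " spot(s) without coordinates dropped")
  extra <- length(coord_ids) - length(keep)
  if (extra > 0)
    warning(extra, " coordinate row(s) without counts ignored")
  counts <- counts[keep, , drop = FALSE]
  coords <- as.matrix(co[match(keep, coord_ids), 2:3])
  storage.mode(coords) <- "double"

  labels <- NULL
  if (!is.null(labels_path)) {
    lt <- utils::read.table(labels_path, header = TRUE, sep = ",",
                            check.names = FALSE)
    labels <- lt[[2]][match(keep, as.character(lt[[1]]))]
  }
  slice_data(counts, coords, spot_ids = keep, gene_ids = colnames(counts),
             labels = labels)
}

#' Write a slice in the layout `read_slice` reads
#'
#' Writes `<prefix>.mtx`, `<prefix>_features.tsv`, `<prefix>_barcodes.tsv`,
#' `<prefix>_coords.csv` and, if labels are present, `<prefix>_labels.csv` —
#' making the synthetic generator a drop-in data source for the CLI.
#'
#' @param slice a [slice_data()].
#' @param prefix output path prefix.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_slice <- function(slice, prefix) {
  stopifnot(inherits(slice, "slice_data"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = paste0(prefix, ".mtx"),
                features = paste0(prefix, "_features.tsv"),
                barcodes = paste0(prefix, "_barcodes.tsv"),
                coords = paste0(prefix, "_coords.csv"))
  Matrix::writeMM(Matrix::t(slice$counts), paths$counts)  # genes x spots
  writeLines(slice$gene_ids, paths$features)
  writeLines(slice$spot_ids, paths$barcodes)
  utils::write.csv(data.frame(spot_id = slice$spot_ids,
                              x = slice$coords[, 1], y = slice$coords[, 2]),
                   paths$coords, row.names = FALSE, quote = FALSE)
  if (!is.null(slice$labels)) {
    paths$labels <- paste0(prefix, "_labels.csv")
    utils::write.csv(data.frame(spot_id = slice$spot_ids, label = slice$labels),
                     paths$labels, row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Export a graph as an edge-list TSV
#'
#' @param W square (possibly sparse) adjacency matrix.
#' @param path output path; columns `i`, `j`, `weight`, upper triangle only.
#' @export
export_edge_list <- function(W, path) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  keep <- W@i < W@j
  df <- data.frame(i = W@i[keep] + 1L, j = W@j[keep] + 1L, weight = W@x[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
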