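#' Cluster partitions
#'
#' A cluster partition is one label per cell, aligned with an
#' [expression_matrix()]'s `cell_ids`. Internally labels are plain character
#' vectors; `cluster_partition()` validates alignment and
#' `partition_clusters()` returns the distinct labels in sorted order.
#'
#' @param labels vector of cluster labels, one per cell. Names, if present,
#'   must equal `expr$cell_ids` (in any order; labels are re-aligned).
#' @param expr the [expression_matrix()] the labels annotate.
#' @return named character vector of labels aligned to `expr$cell_ids`.
#' @export
cluster_partition <- function(labels, expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  labels <- stats::setNames(as.character(labels), names(labels))
  if (length(labels) != n_cells(expr))
    stop("need exactly one label per cell (", n_cells(expr), " cells, ",
         length(labels), " labels)", call. = FALSE)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), expr$cell_ids))
      stop("label names do not match cell_ids", call. = FALSE)
    labels <- labels[expr$cell_ids]
  } else {
    names(labels) <- expr$cell_ids
  }
  if (anyNA(labels)) stop("NA cluster labels", call. = FALSE)
  labels
}

#' @rdname cluster_partition
#' @export
partition_clusters <- function(labels) sort(unique(as.character(labels)))

#' Read / write per-cell labels as a two-column TSV (cell, cluster)
#' @param path TSV path.
#' @param labels named character vector (names are cell ids).
#' @return `read_labels_tsv()`: named character vector;
#'   `write_labels_tsv()`: `path`, invisibly.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(cell = names(labels), cluster = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
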