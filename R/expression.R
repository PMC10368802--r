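#' Construct a cells x genes expression matrix
#'
#' The central container used throughout the package: a numeric matrix with
#' cells as rows and genes as columns (dense `matrix` or any
#' \pkg{Matrix} sparse class), carrying unique cell and gene identifiers and
#' a layer tag recording whether values are raw counts or log-normalized.
#'
#' @param values numeric matrix, cells x genes; non-negative. May be a base
#'   matrix or a \pkg{Matrix} sparse matrix.
#' @param cell_ids,gene_ids character vectors of unique identifiers; taken
#'   from `dimnames(values)` when omitted.
#' @param layer `"raw_counts"` or `"log_normalized"`.
#' @return An object of class `ExpressionMatrix`.
#' @examples
#' m <- matrix(rpois(6, 2), 3, 2,
#'             dimnames = list(paste0("c", 1:3), c("gA", "gB")))
#' expression_matrix(m, layer = "raw_counts")
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw_counts", "log_normalized")) {
  layer <- match.arg(layer)
  if (is.null(cell_ids)) cell_ids <- paste0("cell-", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene-", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("need at least one cell and one gene", call. = FALSE)
  mn <- if (inherits(values, "sparseMatrix")) min(values@x, 0) else min(values)
  if (is.na(mn) || mn < 0)
    stop("expression values must be non-negative and finite", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              n_cells(x), n_genes(x), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Numbers of cells and genes
#' @param expr an [expression_matrix()].
#' @return integer count.
#' @export
n_cells <- function(expr) nrow(expr$values)

#' @rdname n_cells
#' @export
n_genes <- function(expr) ncol(expr$values)

#' Subset an ExpressionMatrix by cells and/or genes
#' @param x an [expression_matrix()].
#' @param i,j cell / gene indices (numeric, logical or character).
#' @param ... ignored.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  expression_matrix(v[i, j, drop = FALSE], layer = x$layer)
}

# shared "expressed" threshold: a gene is expressed in a cell iff value > 0,
# on whichever layer is stored
.EXPRESSED_MIN <- 0

#' Read an expression matrix from disk
#'
#' Supports the three interchange formats common in single-cell pipelines:
#' a MatrixMarket directory (`matrix.mtx(.gz)` plus features/genes and
#' barcodes TSVs, as written by Cell Ranger and friends), a dense CSV/TSV
#' with a header row of gene ids and cell ids in the first column, and
#' AnnData `.h5ad` (dense or CSR/CSC `X`; requires \pkg{rhdf5}).
#'
#' MatrixMarket exports are conventionally genes x cells, so `mtx_dir`
#' defaults to transposing into the internal cells x genes orientation;
#' pass `transpose = FALSE` for matrices already stored cells x genes.
#' Duplicate gene identifiers are disambiguated deterministically with
#' `-1`, `-2`, ... suffixes in file order.
#'
#' @param path file (csv/h5ad) or directory (mtx_dir) path.
#' @param format one of `"mtx_dir"`, `"csv"`, `"h5ad"`.
#' @param transpose flip the stored orientation; default `TRUE` for
#'   `mtx_dir`, `FALSE` otherwise.
#' @param layer layer tag to record, `"raw_counts"` by default.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv", "h5ad"),
                            transpose = NULL,
                            layer = c("raw_counts", "log_normalized")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (is.null(transpose)) transpose <- (format == "mtx_dir")
  if (!file.exists(path))
    stop("input path does not exist: ", path, call. = FALSE)
  out <- switch(format,
    mtx_dir = .read_mtx_dir(path),
    csv = .read_dense_table(path),
    h5ad = .read_h5ad(path))
  v <- out$values
  if (transpose) v <- Matrix::t(v)
  expression_matrix(v,
                    cell_ids = if (transpose) out$col_ids else out$row_ids,
                    gene_ids = .dedup_ids(if (transpose) out$row_ids else out$col_ids),
                    layer = layer)
}

.dedup_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  make.unique(ids, sep = "-")
}

.first_existing <- function(dir, candidates, what) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing ", what, " in ", dir, " (looked for ",
       paste(candidates, collapse = ", "), ")", call. = FALSE)
}

.read_mtx_dir <- function(dir) {
  mtx <- .first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"), "matrix.mtx")
  feat <- .first_existing(dir,
    c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"),
    "features/genes TSV")
  bc <- .first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"),
                        "barcodes TSV")
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m))
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d features / %d barcodes",
      nrow(m), ncol(m), nrow(features), nrow(barcodes)), call. = FALSE)
  list(values = m, row_ids = features[[1L]], col_ids = barcodes[[1L]])
}

.read_dense_table <- function(path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  list(values = m, row_ids = rownames(df), col_ids = colnames(df))
}

#' Write an expression matrix
#'
#' `write_mtx_dir()` writes the MatrixMarket trio (genes x cells orientation,
#' matching the convention `read_expression(format = "mtx_dir")` expects);
#' `write_expression_csv()` writes a dense table with cells as rows.
#'
#' @param expr an [expression_matrix()].
#' @param dir,path output directory / file.
#' @return The output path, invisibly.
#' @export
write_mtx_dir <- function(expr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::t(expr$values), "CsparseMatrix"),
                   "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(expr$gene_ids, expr$gene_ids),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(expr$cell_ids),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_mtx_dir
#' @export
write_expression_csv <- function(expr, path) {
  m <- as.matrix(expr$values)
  utils::write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}

#' Log-normalize raw counts
#'
#' Scales each cell so its total count equals the median per-cell total,
#' then applies `log(1 + x)` elementwise — log1p counts normalized to the
#' median library size, the standard normalization this scoring method
#' expects as input.
#'
#' @param expr an [expression_matrix()] with `layer == "raw_counts"`.
#' @return An [expression_matrix()] with `layer == "log_normalized"`.
#'   Zeros are preserved exactly and per-cell `expm1` totals equal the
#'   median raw total.
#' @export
log_normalize <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$layer != "raw_counts")
    stop("log_normalize expects raw counts", call. = FALSE)
  totals <- Matrix::rowSums(expr$values)
  if (any(totals <= 0))
    stop("cells with zero total count: ",
         paste(expr$cell_ids[totals <= 0], collapse = ", "), call. = FALSE)
  target <- stats::median(totals)
  scaled <- if (inherits(expr$values, "sparseMatrix"))
    Matrix::Diagonal(x = target / totals) %*% expr$values
  else expr$values * (target / totals)  # length-nrow vector recycles by row
  v <- if (inherits(scaled, "sparseMatrix")) {
    s <- methods::as(scaled, "CsparseMatrix")
    s@x <- log1p(s@x)
    s
  } else log1p(scaled)
  expression_matrix(v, expr$cell_ids, expr$gene_ids, layer = "log_normalized")
}
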