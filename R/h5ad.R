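# Minimal AnnData (.h5ad) interchange, via rhdf5.
#
# Covers the subset of the format the rest of the package needs: the main
# matrix X (dense, CSR or CSC), the obs/var index identifiers, and obs label
# columns (plain or categorical). HDF5 is row-major while R is column-major;
# rhdf5 reverses dimensions, so a dense X written by h5py arrives here as
# genes x cells and is transposed back.

.need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5ad support requires the rhdf5 package", call. = FALSE)
}

.h5_index <- function(path, group) {
  at <- rhdf5::h5readAttributes(path, group)
  idx <- if (!is.null(at[["_index"]])) at[["_index"]] else "_index"
  as.character(rhdf5::h5read(path, paste0(group, "/", idx)))
}

.read_h5ad <- function(path) {
  .need_rhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  cells <- .h5_index(path, "obs")
  genes <- .h5_index(path, "var")
  contents <- rhdf5::h5ls(path, recursive = FALSE)
  x_is_group <- contents$otype[contents$name == "X"] == "H5I_GROUP"
  if (length(x_is_group) == 0L)
    stop("h5ad file has no X matrix: ", path, call. = FALSE)
  if (x_is_group) {
    at <- rhdf5::h5readAttributes(path, "X")
    enc <- at[["encoding-type"]]
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    if (identical(enc, "csr_matrix")) {
      # CSR over cells x genes == CSC over genes x cells
      m <- Matrix::t(methods::new("dgCMatrix", i = indices, p = indptr,
                                  x = data,
                                  Dim = c(length(genes), length(cells))))
    } else if (identical(enc, "csc_matrix")) {
      m <- methods::new("dgCMatrix", i = indices, p = indptr, x = data,
                        Dim = c(length(cells), length(genes)))
    } else stop("unsupported X encoding: ", enc, call. = FALSE)
  } else {
    m <- rhdf5::h5read(path, "X")
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) m <- t(m)
  }
  list(values = m, row_ids = cells, col_ids = genes)
}

# set attribute(s) on an object; obj = NULL targets the file root.
# Values wrapped in I() are written as (possibly empty) arrays, everything
# else of length 1 as a scalar.
.h5_attrs <- function(path, obj, ...) {
  at <- list(...)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE, after = FALSE)
  h5o <- if (is.null(obj)) fid else rhdf5::H5Oopen(fid, obj)
  if (!is.null(obj))
    on.exit(rhdf5::H5Oclose(h5o), add = TRUE, after = FALSE)
  for (nm in names(at)) {
    v <- at[[nm]]
    rhdf5::h5writeAttribute(unclass(v), h5o, nm,
                            asScalar = length(v) == 1L && !inherits(v, "AsIs"),
                            variableLengthString = is.character(unclass(v)))
  }
}

.h5_write_str_array <- function(path, name, values) {
  rhdf5::h5write(as.character(values), path, name)
  .h5_attrs(path, name, `encoding-type` = "string-array",
            `encoding-version` = "0.2.0")
}

.h5_write_frame <- function(path, group, index, columns = list()) {
  rhdf5::h5createGroup(path, group)
  .h5_write_str_array(path, paste0(group, "/_index"), index)
  for (nm in names(columns))
    .h5_write_str_array(path, paste0(group, "/", nm),
                        as.character(columns[[nm]]))
  # column-order is always an array; empty defaults to a numeric empty
  # array (zero-length string attributes round-trip poorly)
  .h5_attrs(path, group, `encoding-type` = "dataframe",
            `encoding-version` = "0.2.0", `_index` = "_index",
            `column-order` = if (length(columns)) I(names(columns))
                             else I(numeric(0)))
}

#' Write an expression matrix (and optional cell labels) as .h5ad
#'
#' Produces a minimal AnnData-compatible HDF5 file: dense `X`
#' (cells x genes), `obs` with the cell identifiers plus any label columns,
#' and `var` with the gene identifiers. Readable by the Python `anndata`
#' package and by [read_expression()] with `format = "h5ad"`.
#'
#' @param expr an [expression_matrix()].
#' @param path output `.h5ad` path (overwritten if present).
#' @param obs named list of per-cell label vectors to store as obs columns.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(expr, path, obs = list()) {
  .need_rhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  .h5_attrs(path, NULL, `encoding-type` = "anndata",
            `encoding-version` = "0.1.0")
  # write genes x cells so row-major readers see cells x genes
  rhdf5::h5write(t(as.matrix(expr$values)), path, "X")
  .h5_attrs(path, "X", `encoding-type` = "array",
            `encoding-version` = "0.2.0")
  .h5_write_frame(path, "obs", expr$cell_ids, obs)
  .h5_write_frame(path, "var", expr$gene_ids)
  invisible(path)
}

#' Read a per-cell label column from an .h5ad file
#'
#' Handles both plain string/integer obs columns and AnnData categorical
#' columns (`categories` + `codes` groups).
#'
#' @param path `.h5ad` path.
#' @param field obs column name.
#' @return character vector of labels, one per cell, named by cell id.
#' @export
read_labels_h5ad <- function(path, field) {
  .need_rhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  cells <- .h5_index(path, "obs")
  obs <- rhdf5::h5ls(path)
  avail <- obs$name[obs$group == "/obs"]
  if (!field %in% avail)
    stop("obs field '", field, "' not found; available: ",
         paste(setdiff(avail, "_index"), collapse = ", "), call. = FALSE)
  node <- paste0("obs/", field)
  val <- rhdf5::h5read(path, node)
  if (is.list(val) && all(c("categories", "codes") %in% names(val))) {
    labels <- as.character(val$categories)[as.integer(val$codes) + 1L]
  } else {
    labels <- as.character(val)
  }
  stats::setNames(labels, cells)
}
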