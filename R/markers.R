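# One-versus-rest differential expression and marker-gene selection.
#
# Marker sets drive everything downstream: the positive "code" a cell must
# co-express to score for a cluster, and (by pairwise set algebra) the
# negative sets that disambiguate overlapping clusters.

# Welch's unequal-variance t-test, vectorized over genes.
# Returns t, df, p. Zero standard error (both group variances zero) gives
# t = 0, p = 1 by convention: no usable evidence either way.
.welch_vec <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
  list(t = t, df = df, p = p)
}

.group_moments <- function(values, idx) {
  n <- length(idx)
  s <- Matrix::colSums(values[idx, , drop = FALSE])
  ss <- Matrix::colSums(values[idx, , drop = FALSE]^2)
  m <- s / n
  v <- pmax(ss - n * m^2, 0) / (n - 1)
  list(n = n, sum = s, sumsq = ss, mean = m, var = v)
}

#' One-versus-rest Welch t-tests for one cluster
#'
#' Tests every gene for differential expression between one cluster's cells
#' and all remaining cells, using Welch's unequal-variance t-statistic on
#' the log-normalized layer. `log_fc` is the difference of group means on
#' the log scale.
#'
#' @param expr a log-normalized [expression_matrix()].
#' @param labels cluster labels aligned to cells (see [cluster_partition()]).
#' @param cluster the cluster to test.
#' @return data.frame with columns `gene`, `t`, `p`, `log_fc`, ordered as
#'   `expr$gene_ids`. Genes with zero variance in both groups get `t = 0`,
#'   `p = 1`.
#' @export
welch_one_vs_rest <- function(expr, labels, cluster) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  labels <- cluster_partition(labels, expr)
  if (!cluster %in% labels)
    stop("unknown cluster: ", cluster, call. = FALSE)
  in_cl <- which(labels == cluster)
  out_cl <- which(labels != cluster)
  if (length(in_cl) < 2L || length(out_cl) < 2L)
    stop("cluster '", cluster, "' needs >= 2 cells on both sides of the ",
         "comparison (", length(in_cl), " vs ", length(out_cl), ")",
         call. = FALSE)
  a <- .group_moments(expr$values, in_cl)
  b <- .group_moments(expr$values, out_cl)
  w <- .welch_vec(a$mean, a$var, a$n, b$mean, b$var, b$n)
  data.frame(gene = expr$gene_ids, t = w$t, p = w$p,
             log_fc = a$mean - b$mean, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()] after
#' validating the input range).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Marker selection configuration
#'
#' @param max_genes maximum markers per cluster (default 5).
#' @param min_genes minimum markers per cluster (default 1); when fewer
#'   genes pass the significance filter, the top `min_genes` upregulated
#'   genes are kept regardless, with a warning recorded on the result.
#' @param padj_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @param rank_by rank candidate genes by `"t_stat"` (default) or
#'   `"log_fc"`.
#' @param t_threshold optional additional filter: keep only genes with
#'   Welch t above this value (e.g. 14 in a stringent tumour-atlas
#'   configuration).
#' @return a `marker_config` list.
#' @export
marker_config <- function(max_genes = 5L, min_genes = 1L,
                          padj_cutoff = 0.05,
                          rank_by = c("t_stat", "log_fc"),
                          t_threshold = NULL) {
  rank_by <- match.arg(rank_by)
  stopifnot(min_genes >= 1L, min_genes <= max_genes,
            padj_cutoff > 0, padj_cutoff <= 1)
  structure(list(max_genes = as.integer(max_genes),
                 min_genes = as.integer(min_genes),
                 padj_cutoff = padj_cutoff, rank_by = rank_by,
                 t_threshold = t_threshold),
            class = "marker_config")
}

#' Select marker gene sets for every cluster
#'
#' For each cluster: one-versus-rest Welch tests over all genes, BH
#' adjustment across genes, then keep upregulated genes (`log_fc > 0`)
#' passing `padj_cutoff` (and `t_threshold`, if set), ranked best-first by
#' `rank_by` with deterministic tie-breaking (statistic desc, log_fc desc,
#' gene id asc), truncated to `max_genes`. Clusters where fewer than
#' `min_genes` genes pass fall back to the top-ranked upregulated genes and
#' are recorded in `attr(result, "fallback_clusters")`.
#'
#' @inheritParams welch_one_vs_rest
#' @param config a [marker_config()].
#' @param clusters optionally restrict selection to these clusters (all
#'   cells still form the "rest" background); default: every cluster.
#' @return object of class `marker_sets`: a named list (one element per
#'   cluster) of character vectors of marker genes, ranked best-first, with
#'   the full per-cluster DE tables in `attr(, "tables")`.
#' @export
select_markers <- function(expr, labels, config = marker_config(),
                           clusters = NULL) {
  labels <- cluster_partition(labels, expr)
  if (length(partition_clusters(labels)) < 2L)
    stop("marker selection needs >= 2 clusters", call. = FALSE)
  if (is.null(clusters)) clusters <- partition_clusters(labels)
  sets <- list()
  tables <- list()
  fallback <- character()
  for (cl in clusters) {
    de <- welch_one_vs_rest(expr, labels, cl)
    de$padj <- bh_adjust(de$p)
    up <- de[de$log_fc > 0, , drop = FALSE]
    if (nrow(up) == 0L)
      stop("cluster '", cl, "' has no upregulated gene; it cannot be scored",
           call. = FALSE)
    key <- if (config$rank_by == "t_stat") up$t else up$log_fc
    ord <- order(-key, -up$log_fc, up$gene)
    up <- up[ord, , drop = FALSE]
    pass <- up$padj < config$padj_cutoff
    if (!is.null(config$t_threshold)) pass <- pass & up$t > config$t_threshold
    chosen <- up$gene[pass]
    if (length(chosen) < config$min_genes) {
      fallback <- c(fallback, cl)
      chosen <- up$gene[seq_len(min(config$min_genes, nrow(up)))]
    }
    sets[[cl]] <- utils::head(chosen, config$max_genes)
    tables[[cl]] <- de
  }
  if (length(fallback) > 0L)
    warning("clusters with no gene passing the significance filter ",
            "(top-ranked genes kept): ", paste(fallback, collapse = ", "),
            call. = FALSE)
  structure(sets, tables = tables, fallback_clusters = fallback,
            class = "marker_sets")
}

#' @export
print.marker_sets <- function(x, ...) {
  cat(sprintf("marker_sets: %d clusters, %d-%d genes each\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read / write marker sets
#'
#' TSV form: two columns (cluster, gene), genes ranked best-first within
#' cluster. JSON form: object mapping cluster to gene array.
#'
#' @param markers a `marker_sets` object or plain named list of character
#'   vectors.
#' @param path output/input path.
#' @return read: a `marker_sets` object; write: `path` invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  df <- data.frame(cluster = rep(names(markers), lengths(markers)),
                   gene = unlist(markers, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  structure(split(df$gene, factor(df$cluster, unique(df$cluster))),
            class = "marker_sets")
}

#' @rdname write_markers_tsv
#' @export
write_markers_json <- function(markers, path) {
  jsonlite::write_json(lapply(markers, as.character), path)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_json <- function(path) {
  structure(lapply(jsonlite::read_json(path), unlist),
            class = "marker_sets")
}
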