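# Per-cell enrichment scoring of cluster marker-gene co-expression.
#
# The code-score for cell k and cluster i is log2(H / P): H the number of
# cluster-i marker genes the cell expresses, P the empirical joint
# probability of co-expressing those genes at or above the cell's observed
# levels. The score is gated to 0 unless the cell expresses at least the
# winsorized minimum number of markers, and (for code-scoring) expresses
# none of cluster i's negative gene sets — the genes distinguishing other
# clusters whose marker sets heavily overlap G_i.

#' Winsorized minimum intersection size
#'
#' The minimum overlap / co-expression count for a gene set of a given
#' size: the full size for sets of 1 or 2 genes, all-but-one for larger
#' sets. Used both to decide when one cluster's markers overlap another's
#' enough to warrant a negative set, and as the gate on how many markers a
#' cell must express to receive a nonzero score.
#'
#' @param set_size non-negative integer (vectorized).
#' @return integer of the same length.
#' @export
min_intersection <- function(set_size) {
  if (any(set_size < 0)) stop("set size must be >= 0", call. = FALSE)
  ifelse(set_size <= 2L, set_size, set_size - 1L)
}

#' Negative gene sets per cluster
#'
#' For each ordered cluster pair (i, j), i != j: when
#' `|G_j intersect G_i| >= min_intersection(|G_i|)` and the difference
#' `G_j - G_i` is non-empty, that difference becomes a negative set for
#' cluster i — a cell expressing it is evidence of belonging to j, not i.
#' Full overlap contributes nothing (empty difference), and identical
#' negative sets arising from different j are stored once.
#'
#' @param markers a `marker_sets` object ([select_markers()]) or named list
#'   of non-empty character vectors.
#' @return named list (one element per cluster) of lists of character
#'   vectors, class `negative_sets`.
#' @export
negative_gene_sets <- function(markers) {
  if (any(lengths(markers) == 0L))
    stop("all marker sets must be non-empty", call. = FALSE)
  clusters <- names(markers)
  out <- stats::setNames(vector("list", length(clusters)), clusters)
  for (i in clusters) {
    gi <- markers[[i]]
    thr <- min_intersection(length(gi))
    negs <- list()
    for (j in clusters) {
      if (j == i) next
      gj <- markers[[j]]
      if (length(intersect(gj, gi)) >= thr) {
        diff <- setdiff(gj, gi)
        if (length(diff) > 0L) negs[[length(negs) + 1L]] <- sort(diff)
      }
    }
    out[[i]] <- unique(negs)
  }
  structure(out, class = "negative_sets")
}

#' Number of genes in a set expressed by one cell
#'
#' @param expr an [expression_matrix()].
#' @param cell cell index or id.
#' @param genes character vector of gene ids (may be empty).
#' @return integer count of genes with expression strictly > 0.
#' @export
expressed_count <- function(expr, cell, genes) {
  if (length(genes) == 0L) return(0L)
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing) > 0L)
    stop("unknown gene id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(expr$values[cell, genes] > .EXPRESSED_MIN)
}

#' Number of negative gene sets a cell co-expresses
#'
#' A negative set counts as co-expressed when the cell expresses strictly
#' more than the winsorized minimum (`rule = "strict_gt"`, the default:
#' `H > f(|N|)`, i.e. every gene for sets of three or more and never for
#' sets of one or two), or at least the winsorized minimum
#' (`rule = "winsorized_ge"`: `H >= f(|N|)`, the more aggressive gate).
#' The strict default keeps the filter conservative: a cell is only
#' excluded from a cluster when it unambiguously expresses the full gene
#' program distinguishing an overlapping cluster, which in practice is
#' what keeps marker-selection noise on near-identical clusters from
#' zeroing their own cells' scores.
#'
#' @inheritParams expressed_count
#' @param negsets list of character vectors.
#' @param rule `"strict_gt"` or `"winsorized_ge"`.
#' @return integer count of co-expressed negative sets.
#' @export
negative_hits <- function(expr, cell, negsets,
                          rule = c("strict_gt", "winsorized_ge")) {
  rule <- match.arg(rule)
  if (length(negsets) == 0L) return(0L)
  hits <- vapply(negsets, function(ns) {
    h <- expressed_count(expr, cell, ns)
    f <- min_intersection(length(ns))
    if (rule == "winsorized_ge") h >= f else h > f
  }, logical(1L))
  sum(hits)
}

#' Empirical joint co-expression probability
#'
#' For one cell and a gene set: the product over genes of the fraction of
#' cells (the cell itself included) expressing the gene at or above the
#' cell's level. Each factor lies in \[1/T, 1\], so the product is always
#' positive and `log2` of its inverse is finite.
#'
#' @inheritParams expressed_count
#' @return probability in `((1/T)^length(genes), 1]`.
#' @export
joint_coexpr_prob <- function(expr, cell, genes) {
  if (length(genes) == 0L) stop("gene set must be non-empty", call. = FALSE)
  v <- expr$values[, genes, drop = FALSE]
  x <- as.numeric(v[cell, ])
  tt <- n_cells(expr)
  prod(vapply(seq_along(genes),
              function(g) sum(v[, g] >= x[g]) / tt, numeric(1L)))
}

# per-gene matrix of Eq-6 factors: entry (k, g) = fraction of cells with
# expression >= cell k's value for gene g; computed via min-ranks per gene
.ge_fraction_matrix <- function(values, genes) {
  tt <- nrow(values)
  sub <- as.matrix(values[, genes, drop = FALSE])
  out <- matrix(0, tt, length(genes), dimnames = list(NULL, genes))
  for (g in seq_along(genes)) {
    r <- rank(sub[, g], ties.method = "min")
    out[, g] <- (tt - r + 1) / tt
  }
  out
}

#' Scoring configuration
#'
#' @param method `"code"` (marker co-expression with negative-set
#'   filtering; default), `"coexpr"` (no negative sets), `"additive"`
#'   (simple control: mean marker expression minus the overall mean of the
#'   marker genes), or `"additive_neg"` (additive with negative-set
#'   filtering).
#' @param negative_rule gate for negative-set co-expression, see
#'   [negative_hits()]; default `"strict_gt"`.
#' @return a `score_config` list.
#' @export
score_config <- function(method = c("code", "coexpr", "additive",
                                    "additive_neg"),
                         negative_rule = c("strict_gt", "winsorized_ge")) {
  structure(list(method = match.arg(method),
                 negative_rule = match.arg(negative_rule)),
            class = "score_config")
}

#' Score every cell for every cluster
#'
#' Computes the cells x clusters enrichment score matrix. For
#' `method = "code"`, cell k scores
#' `log2(H(k, G_i) / P(k, G_i))` for cluster i when it expresses at least
#' `min_intersection(|G_i|)` of the markers and co-expresses none of the
#' negative sets, and 0 otherwise; `"coexpr"` drops the negative-set
#' condition; `"additive"`/`"additive_neg"` are the simple mean-shift
#' control scorers.
#'
#' @param expr a log-normalized [expression_matrix()].
#' @param markers a `marker_sets` object or named list of character
#'   vectors (one per cluster to score).
#' @param config a [score_config()].
#' @return a `score_matrix`: numeric cells x clusters matrix (cell ids as
#'   rownames, cluster ids as colnames) with the scoring method in
#'   `attr(, "method")`.
#' @export
code_score <- function(expr, markers, config = score_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stop("markers must be a named list of gene sets", call. = FALSE)
  missing <- setdiff(unique(unlist(markers)), expr$gene_ids)
  if (length(missing) > 0L)
    stop("marker gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  clusters <- names(markers)
  tt <- n_cells(expr)
  scores <- matrix(0, tt, length(clusters),
                   dimnames = list(expr$cell_ids, clusters))
  negsets <- if (config$method %in% c("code", "additive_neg"))
    negative_gene_sets(markers) else NULL

  # cache per-cluster negative-hit counts (cells x 1) as needed
  neg_count <- function(cl) {
    ns <- negsets[[cl]]
    if (length(ns) == 0L) return(integer(tt))
    hits <- integer(tt)
    for (s in ns) {
      h <- Matrix::rowSums(expr$values[, s, drop = FALSE] > .EXPRESSED_MIN)
      f <- min_intersection(length(s))
      hit <- if (config$negative_rule == "winsorized_ge") h >= f else h > f
      hits <- hits + hit
    }
    hits
  }

  for (cl in clusters) {
    gi <- markers[[cl]]
    if (length(gi) == 0L)
      stop("empty marker set for cluster '", cl, "'", call. = FALSE)
    h <- as.integer(
      Matrix::rowSums(expr$values[, gi, drop = FALSE] > .EXPRESSED_MIN))
    if (config$method %in% c("code", "coexpr")) {
      keep <- h >= min_intersection(length(gi))
      if (config$method == "code") keep <- keep & neg_count(cl) == 0L
      if (any(keep)) {
        fr <- .ge_fraction_matrix(expr$values, gi)
        log2p <- rowSums(log2(fr))
        scores[keep, cl] <- log2(h[keep]) - log2p[keep]
      }
    } else {
      v <- expr$values[, gi, drop = FALSE]
      s <- Matrix::rowMeans(v) - sum(v) / prod(dim(v))
      if (config$method == "additive_neg") s[neg_count(cl) > 0L] <- 0
      scores[, cl] <- as.numeric(s)
    }
  }
  structure(scores, method = config$method, class = c("score_matrix",
                                                      class(scores)))
}

#' Diagonal ordering for score heatmaps
#'
#' Orders cells by cluster and clusters identically on both axes, so that
#' own-cluster scores form diagonal blocks in a cells x clusters heatmap
#' and cross-scoring shows up off the diagonal.
#'
#' @param scores a `score_matrix` from [code_score()].
#' @param labels cluster labels aligned to the score rows.
#' @return list with `cell_order` (row permutation) and `cluster_order`
#'   (column permutation of the score columns).
#' @export
diagnostic_order <- function(scores, labels) {
  if (length(labels) != nrow(scores))
    stop("labels must align with score rows", call. = FALSE)
  cluster_order <- intersect(partition_clusters(labels), colnames(scores))
  cluster_order <- match(c(cluster_order,
                           setdiff(colnames(scores), cluster_order)),
                         colnames(scores))
  cell_order <- order(match(as.character(labels),
                            colnames(scores)[cluster_order]))
  list(cell_order = cell_order, cluster_order = cluster_order)
}

#' Write a score matrix as TSV (cells x clusters, header row)
#' @param scores a `score_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- data.frame(cell = rownames(scores), as.data.frame(unclass(scores)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write negative gene sets as JSON for audit
#' @param negsets a `negative_sets` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_negsets_json <- function(negsets, path) {
  jsonlite::write_json(lapply(negsets, function(l) lapply(l, as.character)),
                       path)
  invisible(path)
}
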