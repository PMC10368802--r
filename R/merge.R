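# Cluster-merge: bi-directional Welch tests on summarized enrichment
# scores, merging mutually non-significant cluster pairs.
#
# Treating every cell as an independent observation inflates significance
# with cluster size (the pseudoreplication problem familiar from
# single-cell DE). Score vectors are therefore summarized to k values per
# cluster side before testing; k evenly spaced quantiles is the default.

#' Cluster-merge configuration
#'
#' @param p_cut significance threshold on the (BH-adjusted, unless
#'   `adjust = FALSE`) p-values; a pair differs significantly when either
#'   direction's p-value falls strictly below it. Default 0.01.
#' @param summarization how to reduce each cluster-side score vector before
#'   testing: `"k_quantiles"` (default; k evenly spaced quantiles),
#'   `"k_bins"` (means within k equal-probability bins, empty bins
#'   dropped), `"k_means"` (1-D k-means centroids, deterministically seeded
#'   from the quantile summary), or `"none"` (per-cell testing, for
#'   comparison only — inflates significance with cluster size).
#' @param k number of summary values per side (default 15).
#' @param pair_selection `"all_pairs"` (default) or `"mnn"` (restrict to
#'   mutual nearest-neighbour cluster pairs in mean-score-profile space).
#' @param mnn_neighbours neighbourhood size for `"mnn"` (default 4).
#' @param max_iterations merge rounds to run (default 1; in practice
#'   merging converges in one round). When `run_to_convergence = TRUE` and
#'   `max_iterations` is left at 1, the cap is raised to 20.
#' @param run_to_convergence iterate until the partition stops changing.
#' @param adjust apply BH adjustment across all pair p-values of a round
#'   (default TRUE).
#' @return a `merge_config` list.
#' @export
merge_config <- function(p_cut = 0.01,
                         summarization = c("k_quantiles", "k_bins",
                                           "k_means", "none"),
                         k = 15L,
                         pair_selection = c("all_pairs", "mnn"),
                         mnn_neighbours = 4L,
                         max_iterations = 1L,
                         run_to_convergence = FALSE,
                         adjust = TRUE) {
  summarization <- match.arg(summarization)
  pair_selection <- match.arg(pair_selection)
  stopifnot(p_cut > 0, p_cut < 1, k >= 2L, mnn_neighbours >= 1L,
            max_iterations >= 1L)
  if (isTRUE(run_to_convergence) && max_iterations == 1L)
    max_iterations <- 20L
  structure(list(p_cut = p_cut, summarization = summarization,
                 k = as.integer(k), pair_selection = pair_selection,
                 mnn_neighbours = as.integer(mnn_neighbours),
                 max_iterations = as.integer(max_iterations),
                 run_to_convergence = isTRUE(run_to_convergence),
                 adjust = isTRUE(adjust)),
            class = "merge_config")
}

#' Summarize a score vector to at most k values
#'
#' @param values non-empty numeric vector.
#' @param method summarization method, see [merge_config()].
#' @param k target number of summary values.
#' @return numeric vector of length <= k (exactly k for `"k_quantiles"`;
#'   `"none"` returns the input unchanged).
#' @export
summarize_scores <- function(values,
                             method = c("k_quantiles", "k_bins", "k_means",
                                        "none"),
                             k = 15L) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty score vector", call. = FALSE)
  if (method == "none") return(as.numeric(values))
  probs <- seq(0, 1, length.out = k)
  switch(method,
    k_quantiles = unname(stats::quantile(values, probs = probs, type = 7)),
    k_bins = {
      edges <- unname(stats::quantile(values, seq(0, 1, length.out = k + 1)))
      bin <- findInterval(values, unique(edges), rightmost.closed = TRUE,
                          all.inside = TRUE)
      # map back onto the k nominal bins when edges are tied
      as.numeric(tapply(values, bin, mean))
    },
    k_means = {
      distinct <- sort(unique(as.numeric(values)))
      if (length(distinct) < k) return(distinct)
      centers <- unique(stats::quantile(values, probs = probs, type = 7))
      fit <- stats::kmeans(as.numeric(values), centers = matrix(centers),
                           iter.max = 50L)
      sort(as.numeric(fit$centers))
    })
}

#' Mean cross-cluster score profiles
#'
#' Entry (i, j) is the mean cluster-j enrichment score among the cells of
#' cluster i; the rows are the profiles used for mutual-nearest-neighbour
#' pair selection.
#'
#' @param scores a `score_matrix` ([code_score()]).
#' @param labels cluster labels aligned to score rows; every score column
#'   must appear among the labels.
#' @return square numeric matrix indexed by cluster on both axes.
#' @export
cluster_profiles <- function(scores, labels) {
  clusters <- colnames(scores)
  if (!all(partition_clusters(labels) %in% clusters) ||
      !all(clusters %in% labels))
    stop("score columns and partition clusters must coincide", call. = FALSE)
  out <- matrix(0, length(clusters), length(clusters),
                dimnames = list(clusters, clusters))
  for (cl in clusters)
    out[cl, ] <- colMeans(scores[labels == cl, , drop = FALSE])
  out
}

#' Mutual nearest-neighbour cluster pairs
#'
#' @param profiles square profile matrix from [cluster_profiles()].
#' @param neighbours how many nearest rows (Euclidean distance, self
#'   excluded) count as each cluster's neighbourhood; values >= the number
#'   of clusters are clamped with a warning.
#' @return two-column character matrix of unordered pairs (i < j), possibly
#'   with zero rows.
#' @export
mnn_pairs <- function(profiles, neighbours = 4L) {
  clusters <- rownames(profiles)
  nc <- length(clusters)
  if (nc < 2L) stop("need >= 2 clusters", call. = FALSE)
  if (neighbours >= nc) {
    warning("neighbours >= number of clusters; clamped to ", nc - 1L,
            call. = FALSE)
    neighbours <- nc - 1L
  }
  d <- as.matrix(stats::dist(profiles))
  nn <- lapply(seq_len(nc), function(i) {
    ord <- order(d[i, -i])  # ties broken by cluster order: deterministic
    clusters[-i][ord][seq_len(neighbours)]
  })
  names(nn) <- clusters
  pairs <- list()
  for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
    a <- clusters[i]; b <- clusters[j]
    if (b %in% nn[[a]] && a %in% nn[[b]])
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs) == 0L)
    return(matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("cluster_i", "cluster_j"))))
  out <- do.call(rbind, pairs)
  dimnames(out) <- list(NULL, c("cluster_i", "cluster_j"))
  out
}

# Welch test of two summary vectors; the degenerate both-sides-constant
# case is resolved by the means (equal -> 1, different -> 0)
.welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

#' Bi-directional significance test for one cluster pair
#'
#' Summarizes the four score vectors (cells of i and of j, scored for
#' cluster i and for cluster j) and runs two two-sided Welch tests: `p_i`
#' compares the cluster-i scores between the two cell groups, `p_j` the
#' cluster-j scores. Significance is filled in later by
#' [call_significance()] so that adjustment can pool all tested pairs.
#'
#' @param scores a `score_matrix` covering both clusters' columns.
#' @param labels cluster labels aligned to score rows.
#' @param i,j the two cluster labels.
#' @param config a [merge_config()].
#' @return one-row data.frame: `cluster_i`, `cluster_j`, `p_i`, `p_j`,
#'   `n_i`, `n_j`.
#' @export
test_pair <- function(scores, labels, i, j, config = merge_config()) {
  if (identical(i, j)) stop("i and j must differ", call. = FALSE)
  ci <- which(labels == i); cj <- which(labels == j)
  if (length(ci) == 0L || length(cj) == 0L)
    stop("empty cluster in pair (", i, ", ", j, ")", call. = FALSE)
  summ <- function(cells, column, who) {
    s <- summarize_scores(scores[cells, column], config$summarization,
                          config$k)
    if (length(s) < 2L)
      stop("summarized score vector for cluster '", who,
           "' has fewer than 2 values", call. = FALSE)
    s
  }
  p_i <- .welch_p(summ(ci, i, i), summ(cj, i, j))
  p_j <- .welch_p(summ(ci, j, i), summ(cj, j, j))
  data.frame(cluster_i = i, cluster_j = j, p_i = p_i, p_j = p_j,
             n_i = length(ci), n_j = length(cj),
             stringsAsFactors = FALSE)
}

#' Fill adjusted p-values and significance calls for tested pairs
#'
#' Pools all raw p-values of the round (both directions of every pair)
#' into one BH family, then calls a pair significantly different when
#' either adjusted p-value is strictly below `p_cut` (raw p-values when
#' `adjust = FALSE`).
#'
#' @param results data.frame of [test_pair()] rows.
#' @param config a [merge_config()].
#' @return `results` with `padj_i`, `padj_j`, `significant` columns.
#' @export
call_significance <- function(results, config = merge_config()) {
  if (nrow(results) == 0L) stop("no tested pairs", call. = FALSE)
  padj <- bh_adjust(c(results$p_i, results$p_j))
  results$padj_i <- padj[seq_len(nrow(results))]
  results$padj_j <- padj[nrow(results) + seq_len(nrow(results))]
  use_i <- if (config$adjust) results$padj_i else results$p_i
  use_j <- if (config$adjust) results$padj_j else results$p_j
  results$significant <- (use_i < config$p_cut) | (use_j < config$p_cut)
  results
}

# minimal union-find over cluster labels
.components <- function(clusters, edges) {
  parent <- stats::setNames(clusters, clusters)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0L) for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  vapply(clusters, find, character(1L))
}

#' Merge mutually non-significant cluster pairs
#'
#' Builds a graph over clusters with an edge for every tested pair that is
#' not significantly different; connected components become the merged
#' clusters (so merging is transitive: non-significant edges A-B and B-C
#' pull A, B and C into one cluster even if A-C tested significant).
#' When merges occur, new labels `"0"`, `"1"`, ... are assigned by
#' decreasing component cell count (ties by the lexicographically smallest
#' member label); when nothing merges, the input labels are kept as-is.
#'
#' @param labels cluster labels (named by cell id).
#' @param results output of [call_significance()].
#' @return list with `labels` (new partition) and `merge_map` (named
#'   character vector, input label -> output label).
#' @export
merge_step <- function(labels, results) {
  clusters <- partition_clusters(labels)
  ns <- results[!results$significant, c("cluster_i", "cluster_j"),
                drop = FALSE]
  comp <- .components(clusters, as.matrix(ns))
  if (all(table(comp) == 1L)) {
    return(list(labels = labels,
                merge_map = stats::setNames(clusters, clusters)))
  }
  sizes <- table(factor(as.character(labels), clusters))
  comp_size <- tapply(as.numeric(sizes), comp[clusters], sum)
  comp_min <- tapply(clusters, comp[clusters], min)
  roots <- names(comp_size)[order(-as.numeric(comp_size),
                                  comp_min[names(comp_size)])]
  new_of_root <- stats::setNames(as.character(seq_along(roots) - 1L), roots)
  merge_map <- stats::setNames(new_of_root[comp[clusters]], clusters)
  list(labels = stats::setNames(merge_map[as.character(labels)],
                                names(labels)),
       merge_map = merge_map)
}

#' One round of cluster-pair significance testing
#'
#' Convenience wrapper running marker selection, scoring, pair selection
#' and bi-directional testing on a fixed partition, without merging —
#' the table ROC benchmarking consumes.
#'
#' @inheritParams cluster_merge
#' @return data.frame of [call_significance()] output (one row per tested
#'   pair).
#' @export
test_cluster_pairs <- function(expr, labels, markers = NULL,
                               marker_config = clustercode::marker_config(),
                               score_config = clustercode::score_config(),
                               merge_config = clustercode::merge_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$layer == "raw_counts") expr <- log_normalize(expr)
  labels <- cluster_partition(labels, expr)
  clusters <- partition_clusters(labels)
  if (length(clusters) < 2L) stop("need >= 2 clusters", call. = FALSE)
  mk <- if (!is.null(markers)) markers
        else select_markers(expr, labels, marker_config)
  sc <- code_score(expr, mk, score_config)
  pairs <- if (merge_config$pair_selection == "mnn")
    mnn_pairs(cluster_profiles(sc, labels), merge_config$mnn_neighbours)
  else t(utils::combn(clusters, 2L))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
    test_pair(sc, labels, pairs[r, 1L], pairs[r, 2L], merge_config)))
  call_significance(res, merge_config)
}

#' Merge non-significantly different single-cell clusters
#'
#' The main entry point. Starting from a tentative (deliberately
#' over-clustered) partition, each round: selects marker genes per cluster
#' (one-versus-rest Welch + BH), scores every cell for every cluster
#' ([code_score()]), selects the cluster pairs to compare (all pairs, or
#' mutual nearest neighbours in profile space), tests each pair
#' bi-directionally on summarized scores, and merges mutually
#' non-significant pairs. By default a single round is run; merging can be
#' iterated to convergence. Markers and scores are recomputed on the final
#' partition for diagnostics.
#'
#' Singleton clusters cannot be tested; they are pre-merged into their
#' nearest cluster by score-profile distance, with a warning.
#'
#' @param expr an [expression_matrix()]; raw counts are log-normalized
#'   automatically.
#' @param labels tentative cluster labels (see [cluster_partition()]).
#' @param markers optional user-supplied marker sets (named list of gene
#'   vectors, one per cluster); when supplied, marker selection is skipped
#'   in the first round (and re-run in later rounds on merged partitions).
#' @param marker_config a [marker_config()].
#' @param score_config a [score_config()].
#' @param merge_config a [merge_config()].
#' @return object of class `cluster_merge` with elements `labels` (final
#'   partition, named by cell), `initial_labels`, `merge_map`,
#'   `iterations`, `pair_tables` (one data.frame per round), `scores` and
#'   `markers` (recomputed on the final partition), and `config`.
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   n_genes = 300, n_cells = 400, n_groups = 3, de_pool_size = 8,
#'   genes_per_group_min = 2, genes_per_group_max = 4, seed = 1))
#' split <- split_artificial_subclusters(sim$truth, n_sub = 2, seed = 1)
#' fit <- cluster_merge(sim$counts, split$labels)
#' fit
#' @export
cluster_merge <- function(expr, labels, markers = NULL,
                          marker_config = clustercode::marker_config(),
                          score_config = clustercode::score_config(),
                          merge_config = clustercode::merge_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$layer == "raw_counts") expr <- log_normalize(expr)
  labels <- cluster_partition(labels, expr)
  initial <- labels
  if (length(partition_clusters(labels)) < 2L)
    stop("cluster-merge needs >= 2 clusters", call. = FALSE)

  total_map <- stats::setNames(partition_clusters(labels),
                               partition_clusters(labels))
  pair_tables <- list()
  iterations <- 0L
  user_markers <- markers

  repeat {
    clusters <- partition_clusters(labels)
    if (length(clusters) < 2L) {
      warning("partition collapsed to a single cluster; stopping",
              call. = FALSE)
      break
    }
    # singleton clusters cannot be tested (Welch needs two cells a side):
    # absorb each one into its nearest cluster by score-profile distance,
    # using markers selected for the non-singleton clusters only
    sizes <- table(factor(as.character(labels), clusters))
    if (any(sizes < 2L)) {
      ok <- names(sizes)[sizes >= 2L]
      if (length(ok) == 0L)
        stop("all clusters are singletons; nothing can be tested",
             call. = FALSE)
      mk_ok <- select_markers(expr, labels, marker_config, clusters = ok)
      sc_ok <- code_score(expr, mk_ok, score_config)
      prof <- rowsum(unclass(sc_ok), as.character(labels)) /
        as.numeric(table(as.character(labels))[clusters])
      d <- as.matrix(stats::dist(prof))
      for (cl in names(sizes)[sizes < 2L]) {
        tgt <- ok[which.min(d[cl, ok])]
        warning("singleton cluster '", cl, "' pre-merged into '", tgt, "'",
                call. = FALSE)
        labels[labels == cl] <- tgt
        total_map[total_map == cl] <- tgt
      }
      next  # recompute on the amended partition
    }

    mk <- if (!is.null(user_markers) && iterations == 0L) user_markers
          else select_markers(expr, labels, marker_config)
    sc <- code_score(expr, mk, score_config)

    pairs <- if (merge_config$pair_selection == "mnn")
      mnn_pairs(cluster_profiles(sc, labels), merge_config$mnn_neighbours)
    else t(utils::combn(clusters, 2L))
    if (nrow(pairs) == 0L) {
      iterations <- iterations + 1L
      break
    }
    res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
      test_pair(sc, labels, pairs[r, 1L], pairs[r, 2L], merge_config)))
    res <- call_significance(res, merge_config)
    pair_tables[[length(pair_tables) + 1L]] <- res

    step <- merge_step(labels, res)
    changed <- !identical(unname(step$labels), unname(labels))
    total_map <- stats::setNames(step$merge_map[unname(total_map)],
                                 names(total_map))
    labels <- step$labels
    iterations <- iterations + 1L
    if (iterations >= merge_config$max_iterations) break
    if (merge_config$run_to_convergence && !changed) break
    if (!merge_config$run_to_convergence && !changed) break
  }

  final_markers <- if (length(partition_clusters(labels)) >= 2L)
    select_markers(expr, labels, marker_config) else NULL
  final_scores <- if (!is.null(final_markers))
    code_score(expr, final_markers, score_config) else NULL

  structure(list(labels = labels, initial_labels = initial,
                 merge_map = total_map, iterations = iterations,
                 pair_tables = pair_tables, scores = final_scores,
                 markers = final_markers,
                 config = list(marker = marker_config, score = score_config,
                               merge = merge_config)),
            class = "cluster_merge")
}

#' @export
print.cluster_merge <- function(x, ...) {
  cat(sprintf("cluster_merge: %d -> %d clusters in %d iteration(s)\n",
              length(unique(x$initial_labels)),
              length(unique(x$labels)), x$iterations))
  invisible(x)
}

#' @export
summary.cluster_merge <- function(object, ...) {
  cat(sprintf("cluster_merge of %d cells\n", length(object$labels)))
  cat(sprintf("  input clusters:  %d\n",
              length(unique(object$initial_labels))))
  cat(sprintf("  output clusters: %d (after %d iteration(s))\n",
              length(unique(object$labels)), object$iterations))
  if (length(object$pair_tables) > 0L) {
    last <- object$pair_tables[[length(object$pair_tables)]]
    cat(sprintf("  last round: %d pairs tested, %d significant (p_cut = %g)\n",
                nrow(last), sum(last$significant),
                object$config$merge$p_cut))
  }
  cat("  cluster sizes:\n")
  print(sort(table(object$labels), decreasing = TRUE))
  invisible(object)
}

#' Final cluster labels of a merge fit
#' @param object a `cluster_merge` object.
#' @param ... ignored.
#' @return named character vector of merged labels.
#' @export
labels.cluster_merge <- function(object, ...) object$labels

#' Score heatmap of a merge fit
#'
#' Draws the cells x clusters score matrix with cells grouped by final
#' cluster and clusters ordered identically on both axes, so own-cluster
#' scores lie on the diagonal and off-diagonal signal indicates residual
#' cross-scoring.
#'
#' @param x a `cluster_merge` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.cluster_merge <- function(x, ...) {
  if (is.null(x$scores)) stop("fit holds no score matrix", call. = FALSE)
  ord <- diagnostic_order(x$scores, x$labels)
  m <- unclass(x$scores)[ord$cell_order, ord$cluster_order, drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  xlab = "cluster", ylab = "cells (grouped by cluster)",
                  xaxt = "n", yaxt = "n", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  invisible(x)
}

#' Write the pair-test table / merge map of a fit as TSV
#' @param fit a `cluster_merge` object.
#' @param path output path.
#' @param iteration which round's table (default: last).
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(fit, path,
                            iteration = length(fit$pair_tables)) {
  tab <- fit$pair_tables[[iteration]]
  tab <- tab[, c("cluster_i", "cluster_j", "p_i", "p_j", "padj_i", "padj_j",
                 "significant", "n_i", "n_j")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
write_merge_map_tsv <- function(fit, path) {
  utils::write.table(
    data.frame(input_label = names(fit$merge_map),
               output_label = unname(fit$merge_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
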