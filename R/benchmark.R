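# Evaluation utilities: per-cluster binary classification from positive
# scores, ROC/AUROC of pair significance against ground truth over a
# dyadic p-value cutoff grid, and the cell-abundance bias diagnostic.

#' Per-cluster binary classification metrics from positive scores
#'
#' Cells with a strictly positive score in a cluster's column are
#' predicted to belong to the cluster; predictions are compared with the
#' true membership. Precision is 0 when nothing is predicted positive and
#' F1 is 0 when precision + recall is 0.
#'
#' @param scores a `score_matrix` ([code_score()]).
#' @param truth true cluster labels aligned to score rows; every score
#'   column must be a truth cluster.
#' @return data.frame (one row per cluster plus a `"mean"` row) with
#'   columns `cluster`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
membership_metrics <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(truth) != nrow(scores))
    stop("truth labels must align with score rows", call. = FALSE)
  missing <- setdiff(colnames(scores), unique(truth))
  if (length(missing) > 0L)
    stop("score column(s) absent from truth: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(colnames(scores), function(cl) {
    pred <- scores[, cl] > 0
    act <- truth == cl
    tp <- sum(pred & act); fp <- sum(pred & !act)
    fn <- sum(!pred & act); tn <- sum(!pred & !act)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(cluster = cl, accuracy = (tp + tn) / length(act),
               precision = precision, recall = recall, f1 = f1)
  })
  out <- do.call(rbind, rows)
  means <- data.frame(cluster = "mean", accuracy = mean(out$accuracy),
                      precision = mean(out$precision),
                      recall = mean(out$recall), f1 = mean(out$f1))
  rbind(out, means)
}

#' Dyadic p-value cutoff grid
#'
#' `{0} U {2^-c : c = 0..100}`, sorted ascending — dense near 0 where
#' p-values of truly different cluster pairs live, and reaching 1.
#'
#' @return numeric vector of length 102.
#' @export
cutoff_grid <- function() {
  sort(unique(c(0, 2^-(0:100))))
}

#' ROC / AUROC of pair significance against ground truth
#'
#' Each tested pair is reduced to the statistic `min(p_i, p_j)` (the
#' continuous analogue of the either-direction significance rule) and
#' called significant at a cutoff when the statistic falls strictly below
#' it. Sweeping the cutoffs yields TPR/FPR against the ground-truth pair
#' labels (positive = truly significantly different); AUROC is the
#' trapezoidal area with (0,0) and (1,1) anchors.
#'
#' @param results data.frame with `cluster_i`, `cluster_j`, `p_i`, `p_j`
#'   ([test_pair()] rows).
#' @param truth_pairs data.frame with `cluster_i`, `cluster_j`,
#'   `significant` (e.g. from [split_artificial_subclusters()]); pair
#'   orientation is ignored.
#' @param cutoffs cutoff sweep, default [cutoff_grid()].
#' @return list of class `roc_result`: `cutoffs`, `fpr`, `tpr`, `auroc`,
#'   `n_pairs`.
#' @export
pair_roc <- function(results, truth_pairs, cutoffs = cutoff_grid()) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  truth <- stats::setNames(truth_pairs$significant,
                           key(truth_pairs$cluster_i,
                               truth_pairs$cluster_j))
  k <- key(results$cluster_i, results$cluster_j)
  if (any(!k %in% names(truth)))
    stop("tested pair(s) without a ground-truth label", call. = FALSE)
  lab <- as.logical(truth[k])
  if (all(lab) || !any(lab))
    stop("ground truth has a single class; AUROC undefined", call. = FALSE)
  stat <- pmin(results$p_i, results$p_j)
  pos <- sum(lab); neg <- sum(!lab)
  tpr <- vapply(cutoffs, function(ct) sum(stat < ct & lab) / pos,
                numeric(1L))
  fpr <- vapply(cutoffs, function(ct) sum(stat < ct & !lab) / neg,
                numeric(1L))
  ord <- order(fpr, tpr)
  fx <- c(0, fpr[ord], 1)
  fy <- c(0, tpr[ord], 1)
  auroc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  structure(list(cutoffs = cutoffs, fpr = fpr, tpr = tpr, auroc = auroc,
                 n_pairs = length(lab)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUROC = %.4f over %d pairs\n", x$auroc,
              x$n_pairs))
  invisible(x)
}

#' Cell-abundance bias of pair significance
#'
#' Spearman correlation between `-log10(min(p_i, p_j))` (p floored at
#' 1e-300) and `log2(n_i + n_j)` across tested pairs. A well-calibrated
#' summarized test should show little correlation; per-cell testing shows
#' a strong one.
#'
#' @param results data.frame of [test_pair()] rows (needs `p_i`, `p_j`,
#'   `n_i`, `n_j`).
#' @return Spearman rho (0 with attribute `degenerate = TRUE` when either
#'   vector is constant).
#' @export
abundance_bias <- function(results) {
  if (nrow(results) < 3L) stop("need >= 3 pairs", call. = FALSE)
  x <- -log10(pmax(pmin(results$p_i, results$p_j), 1e-300))
  y <- log2(results$n_i + results$n_j)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(x, y, method = "spearman")
}

#' Write a ROC result as TSV plus a one-line JSON summary
#' @param roc a `roc_result`.
#' @param path TSV path (columns cutoff, fpr, tpr); the JSON summary
#'   `{auroc, n_pairs}` is written alongside with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(
    data.frame(cutoff = roc$cutoffs, fpr = roc$fpr, tpr = roc$tpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(auroc = roc$auroc, n_pairs = roc$n_pairs),
                       sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
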