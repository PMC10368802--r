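# small deterministic fixtures built in code

toy_expr <- function(m, layer = "log_normalized") {
  if (is.null(rownames(m))) rownames(m) <- paste0("c", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  expression_matrix(m, layer = layer)
}

random_expr <- function(n_cells, n_genes, seed = 1,
                        layer = "log_normalized") {
  set.seed(seed)
  m <- matrix(round(stats::rexp(n_cells * n_genes), 3), n_cells, n_genes)
  m[stats::runif(length(m)) < 0.4] <- 0
  toy_expr(m, layer = layer)
}

# two well-separated populations, each defined by its own gene block
separated_expr <- function(n_per = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(4 * n_per * 10, 1), 2 * n_per, 20)
  m[seq_len(n_per), 1:5] <- m[seq_len(n_per), 1:5] + 20
  m[n_per + seq_len(n_per), 11:15] <- m[n_per + seq_len(n_per), 11:15] + 20
  e <- toy_expr(m + 1, layer = "raw_counts")   # +1 avoids zero totals
  list(expr = log_normalize(e),
       labels = stats::setNames(rep(c("A", "B"), each = n_per), e$cell_ids))
}

# small simulated dataset shared by merge/simulate tests
small_sim <- function(seed = 7) {
  simulate_dataset(simulation_config(
    n_genes = 500, n_cells = 600, n_groups = 4, de_pool_size = 10,
    genes_per_group_min = 2, genes_per_group_max = 5, seed = seed))
}

# medium dataset for structure-recovery checks: a larger pool relative to
# the number of groups and >= 200 cells per sub-cluster, so the planted
# codes differ in at least two selected markers (groups whose codes share
# all but one marker are legitimately indistinguishable and would merge)
recovery_sim <- function(seed = 8) {
  simulate_dataset(simulation_config(
    n_genes = 500, n_cells = 1600, n_groups = 4, de_pool_size = 14,
    genes_per_group_min = 3, genes_per_group_max = 5, seed = seed))
}
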