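test_that("score summarization honours each method's contract", {
  # constant input: every summary is the constant
  for (m in c("k_quantiles", "k_bins", "k_means"))
    expect_true(all(summarize_scores(rep(3.5, 40), m, 15) == 3.5))
  # endpoint-inclusive quantile convention
  expect_equal(summarize_scores(0:14, "k_quantiles", 15), as.numeric(0:14))
  set.seed(8)
  x <- rexp(200)
  q <- summarize_scores(x, "k_quantiles", 15)
  expect_length(q, 15)
  expect_equal(range(q), range(x))   # endpoints always included
  b <- summarize_scores(x, "k_bins", 15)
  expect_lte(length(b), 15)
  expect_true(all(b >= min(x) & b <= max(x)))
  km <- summarize_scores(x, "k_means", 15)
  expect_length(km, 15)
  expect_identical(km, summarize_scores(x, "k_means", 15))  # deterministic
  # fewer distinct values than k: the distinct values come back
  expect_equal(summarize_scores(c(1, 2, 2, 5), "k_means", 15), c(1, 2, 5))
  expect_identical(summarize_scores(x, "none"), x)
  expect_error(summarize_scores(numeric(), "k_quantiles"), "empty")
})

test_that("cluster profiles are the per-pair means", {
  set.seed(9)
  sc <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("c", 1:20),
                                                 c("A", "B", "C")))
  lab <- sample(c("A", "B", "C"), 20, replace = TRUE)
  lab[1:3] <- c("A", "B", "C")
  prof <- cluster_profiles(sc, lab)
  for (i in c("A", "B", "C")) for (j in c("A", "B", "C"))
    expect_equal(prof[i, j], mean(sc[lab == i, j]))
  # single cluster and constant-zero edge cases
  expect_equal(unname(cluster_profiles(
    matrix(0, 4, 1, dimnames = list(paste0("c", 1:4), "Z")),
    rep("Z", 4))), matrix(0, 1, 1))
})

test_that("mutual nearest-neighbour pairs match exhaustive distances", {
  # 2 clusters: the only pair is mutual by necessity
  p2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  expect_equal(nrow(mnn_pairs(p2, 1)), 1)

  set.seed(10)
  prof <- matrix(rnorm(25), 5, 5,
                 dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  got <- mnn_pairs(prof, 2)
  d <- as.matrix(dist(prof))
  nn <- lapply(1:5, function(i) LETTERS[1:5][-i][order(d[i, -i])][1:2])
  names(nn) <- LETTERS[1:5]
  want <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    a <- LETTERS[i]; b <- LETTERS[j]
    if (b %in% nn[[a]] && a %in% nn[[b]])
      want[[length(want) + 1]] <- c(a, b)
  }
  expect_equal(unname(got), do.call(rbind, want), ignore_attr = TRUE)

  # identical rows are always mutual; oversized neighbourhood clamps
  prof2 <- prof; prof2["B", ] <- prof2["A", ]
  expect_true(any(apply(mnn_pairs(prof2, 1), 1, function(r)
    all(r == c("A", "B")))))
  expect_warning(mnn_pairs(prof, 10), "clamped")
})

test_that("pair tests behave on identical, separated and swapped inputs", {
  set.seed(12)
  sc <- matrix(0, 60, 2, dimnames = list(paste0("c", 1:60), c("A", "B")))
  lab <- stats::setNames(rep(c("A", "B"), each = 30), rownames(sc))
  base <- rnorm(30, 5)
  # identical distributions on both columns -> p = 1 under duplication
  sc[, "A"] <- rep(base, 2); sc[, "B"] <- rep(base, 2)
  r <- test_pair(sc, lab, "A", "B")
  expect_equal(r$p_i, 1); expect_equal(r$p_j, 1)
  expect_equal(c(r$n_i, r$n_j), c(30L, 30L))

  # well-separated own scores -> tiny p
  sc2 <- sc
  sc2[lab == "A", "A"] <- rnorm(30, 10, 0.3)
  sc2[lab == "B", "A"] <- rnorm(30, 0, 0.3)
  r2 <- test_pair(sc2, lab, "A", "B")
  expect_lt(r2$p_i, 0.01)

  # orientation swap exchanges the two p-values
  r3 <- test_pair(sc2, lab, "B", "A")
  expect_equal(r3$p_i, r2$p_j)
  expect_equal(r3$p_j, r2$p_i)

  expect_error(test_pair(sc2, lab, "A", "A"), "differ")
  lab1 <- lab
  lab1[lab1 == "A"][-1] <- "B"   # leave a single cell in A
  lab1 <- stats::setNames(ifelse(seq_along(lab) == 1, "A", "B"),
                          names(lab))
  expect_error(test_pair(sc2, lab1, "A", "B",
                         merge_config(summarization = "none")),
               "fewer than 2")
})

test_that("significance calls pool both directions into one BH family", {
  res <- data.frame(cluster_i = c("A", "A"), cluster_j = c("B", "C"),
                    p_i = c(1, 0.001), p_j = c(1, 0.5),
                    n_i = 10, n_j = 10)
  out <- call_significance(res, merge_config())
  expect_false(out$significant[1])
  expect_true(out$significant[2])    # 0.001 * 4 / 1 < 0.01
  expect_equal(c(out$padj_i, out$padj_j),
               bh_adjust(c(res$p_i, res$p_j)))
  # raw-p mode
  out2 <- call_significance(res, merge_config(p_cut = 0.01, adjust = FALSE))
  expect_true(out2$significant[2])
})

test_that("merging is transitive over non-significant edges", {
  lab <- stats::setNames(c(rep("A", 5), rep("B", 4), rep("C", 3),
                           rep("D", 8)), paste0("c", 1:20))
  res <- data.frame(
    cluster_i = c("A", "B", "A", "A", "B", "C"),
    cluster_j = c("B", "C", "C", "D", "D", "D"),
    significant = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  st <- merge_step(lab, res)
  # A,B,C collapse despite (A,C) significant; D stays
  expect_length(unique(st$labels), 2)
  expect_equal(unname(st$merge_map[c("A", "B", "C")]), rep("0", 3))
  expect_equal(unname(st$merge_map[["D"]]), "1")  # smaller component

  # all pairs significant: labels untouched
  res2 <- res; res2$significant <- TRUE
  expect_identical(merge_step(lab, res2)$labels, lab)

  # one non-significant pair among 4 clusters -> 3 clusters out
  res3 <- res; res3$significant <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_length(unique(merge_step(lab, res3)$labels), 3)
})

test_that("well-separated clusters are a fixed point of cluster_merge", {
  sep <- separated_expr(30, seed = 14)
  fit <- cluster_merge(sep$expr, sep$labels)
  expect_identical(fit$labels, sep$labels)
  expect_equal(fit$iterations, 1L)
  expect_output(print(fit), "2 -> 2 clusters")
})

test_that("cluster_merge recovers planted structure and is well-behaved", {
  sim <- recovery_sim(seed = 8)
  sp <- split_artificial_subclusters(sim$truth, n_sub = 2, seed = 8)
  ln <- log_normalize(sim$counts)
  fit <- cluster_merge(ln, sp$labels)

  # recovers the 4 planted groups exactly (up to relabeling)
  expect_length(unique(fit$labels), 4)
  expect_equal(unname(apply(table(sim$truth, fit$labels) > 0, 1, sum)),
               rep(1L, 4))

  # coarsening: no input cluster is ever split
  expect_true(all(apply(table(fit$initial_labels, fit$labels) > 0, 1,
                        sum) == 1))
  # merge_map is total and consistent with the label mapping
  expect_setequal(names(fit$merge_map), unique(sp$labels))
  expect_identical(unname(fit$merge_map[fit$initial_labels]),
                   unname(fit$labels))

  # determinism
  fit2 <- cluster_merge(ln, sp$labels)
  expect_identical(fit$labels, fit2$labels)

  # idempotence at convergence: re-running performs zero merges
  fit3 <- cluster_merge(ln, fit$labels)
  expect_length(unique(fit3$labels), length(unique(fit$labels)))
  expect_true(all(table(fit$labels, fit3$labels) %in%
                    c(0L, table(fit$labels))))

  # mnn pair selection with |C|-1 neighbours agrees with all_pairs
  fit4 <- cluster_merge(ln, sp$labels,
                        merge_config = merge_config(
                          pair_selection = "mnn",
                          mnn_neighbours = length(unique(sp$labels)) - 1L))
  expect_identical(fit4$labels, fit$labels)
})

test_that("singleton clusters are absorbed before testing", {
  sep <- separated_expr(20, seed = 15)
  lab <- sep$labels
  lab[1] <- "orphan"
  expect_warning(fit <- cluster_merge(sep$expr, lab), "singleton")
  expect_false("orphan" %in% fit$labels)
  expect_length(unique(fit$labels), 2)
})

test_that("fit artifacts serialize and summarize", {
  sep <- separated_expr(15, seed = 16)
  fit <- cluster_merge(sep$expr, sep$labels)
  d <- withr::local_tempdir()
  write_pairs_tsv(fit, file.path(d, "pairs.tsv"))
  tab <- utils::read.delim(file.path(d, "pairs.tsv"))
  expect_named(tab, c("cluster_i", "cluster_j", "p_i", "p_j", "padj_i",
                      "padj_j", "significant", "n_i", "n_j"))
  write_merge_map_tsv(fit, file.path(d, "map.tsv"))
  expect_equal(nrow(utils::read.delim(file.path(d, "map.tsv"))), 2)
  expect_output(summary(fit), "pairs tested")
  expect_silent(grDevices::png(file.path(d, "p.png")))
  plot(fit)
  grDevices::dev.off()
})
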