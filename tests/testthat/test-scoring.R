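test_that("winsorized minimum intersection follows the size rule", {
  expect_equal(min_intersection(c(0, 1, 2, 3, 5, 10)),
               c(0, 1, 2, 2, 4, 9))
  expect_error(min_intersection(-1), ">= 0")
})

test_that("negative gene sets arise exactly at the overlap threshold", {
  # overlap 2 >= f(3) = 2: difference {d} becomes a negative set
  mk <- list(i = c("a", "b", "c"), j = c("a", "b", "d"))
  ns <- negative_gene_sets(mk)
  expect_equal(ns[["i"]], list("d"))
  expect_equal(ns[["j"]], list("c"))

  # full overlap: no set difference, nothing added
  mk2 <- list(i = c("a", "b", "c"), j = c("a", "b", "c"))
  expect_length(negative_gene_sets(mk2)[["i"]], 0)

  # overlap 1 < f(5) = 4: nothing added
  mk3 <- list(i = c("a", "b", "c", "d", "e"), j = c("a", "x"))
  expect_length(negative_gene_sets(mk3)[["i"]], 0)

  # identical differences from different clusters are stored once
  mk4 <- list(i = c("a", "b"), j = c("a", "b", "z"), k = c("a", "b", "z"))
  expect_equal(negative_gene_sets(mk4)[["i"]], list("z"))

  expect_error(negative_gene_sets(list(i = character(), j = "a")),
               "non-empty")
})

test_that("expressed_count counts strictly positive entries", {
  e <- toy_expr(matrix(c(1.2, 0, 3.0), 1, 3,
                       dimnames = list("c1", c("ga", "gb", "gc"))))
  expect_equal(expressed_count(e, "c1", c("ga", "gb", "gc")), 2L)
  expect_equal(expressed_count(e, "c1", character()), 0L)
  expect_equal(expressed_count(e, "c1", "gb"), 0L)
  expect_error(expressed_count(e, "c1", "nope"), "unknown gene")
})

test_that("negative-hit rules differ exactly as designed", {
  e <- toy_expr(matrix(c(2, 1, 1, 1, 0), 1, 5,
                       dimnames = list("c1", paste0("g", 1:5))))
  # singleton set, gene expressed: counts under >=, never under >
  expect_equal(negative_hits(e, "c1", list("g1"), "winsorized_ge"), 1L)
  expect_equal(negative_hits(e, "c1", list("g1"), "strict_gt"), 0L)
  # 4-gene set with 3 expressed: H = 3 = f -> >= counts, > does not
  s4 <- list(paste0("g", 2:5))
  expect_equal(negative_hits(e, "c1", s4, "winsorized_ge"), 1L)
  expect_equal(negative_hits(e, "c1", s4, "strict_gt"), 0L)
  # all 4 expressed: both count
  s4b <- list(paste0("g", 1:4))
  expect_equal(negative_hits(e, "c1", s4b, "winsorized_ge"), 1L)
  expect_equal(negative_hits(e, "c1", s4b, "strict_gt"), 1L)
  expect_equal(negative_hits(e, "c1", list()), 0L)
})

test_that("joint co-expression probability matches the brute-force oracle", {
  brute <- function(values, cell, genes) {
    p <- 1
    for (g in genes) {
      cnt <- 0
      for (v in seq_len(nrow(values)))
        if (values[v, g] >= values[cell, g]) cnt <- cnt + 1
      p <- p * cnt / nrow(values)
    }
    p
  }
  for (seed in 1:5) {
    e <- random_expr(30, 10, seed = seed)
    genes <- sample(e$gene_ids, 4)
    for (cell in sample(e$cell_ids, 6)) {
      expect_equal(joint_coexpr_prob(e, cell, genes),
                   brute(as.matrix(e$values), cell, genes),
                   tolerance = 1e-12)
    }
  }
  # strict unique maximum -> factor 1/T; zero value -> factor 1
  m <- matrix(c(5, 1, 0, 2,  0, 0, 0, 0), 4, 2,
              dimnames = list(paste0("c", 1:4), c("hi", "zero")))
  e2 <- toy_expr(m)
  expect_equal(joint_coexpr_prob(e2, "c1", "hi"), 1 / 4)
  expect_equal(joint_coexpr_prob(e2, "c1", "zero"), 1)
  expect_equal(joint_coexpr_prob(e2, "c1", c("hi", "zero")), 1 / 4)
})

test_that("the maximal-expression cell in a 4-cell toy scores exactly 5", {
  m <- matrix(c(9, 1, 1, 1,  8, 2, 0, 1), 4, 2,
              dimnames = list(paste0("c", 1:4), c("m1", "m2")))
  e <- toy_expr(m)
  sc <- code_score(e, list(X = c("m1", "m2")))
  # H = 2, P = (1/4)*(1/4) -> log2(2 * 16) = 5
  expect_equal(unname(sc["c1", "X"]), 5)
})

test_that("cells co-expressing a negative set score zero for the cluster", {
  # cluster A marked by m1..m3; cluster B by m1,m2,m4: overlap 2 >= f(3)=2
  # -> negative set {m4} for A. Cell x expresses all of A's markers AND m4.
  m <- rbind(x  = c(5, 5, 5, 5),
             a1 = c(4, 4, 4, 0),
             a2 = c(4, 5, 3, 0),
             b1 = c(5, 5, 0, 6),
             b2 = c(4, 4, 0, 5))
  colnames(m) <- c("m1", "m2", "m3", "m4")
  e <- toy_expr(m)
  mk <- list(A = c("m1", "m2", "m3"), B = c("m1", "m2", "m4"))
  sc_ge <- code_score(e, mk, score_config("code", "winsorized_ge"))
  psi <- code_score(e, mk, score_config("coexpr"))
  expect_equal(unname(sc_ge["x", "A"]), 0)  # killed by negative set {m4}
  expect_gt(psi["x", "A"], 0)               # coexpr ignores negative sets
  expect_gt(sc_ge["a1", "A"], 0)            # clean cells keep their score
  # under the strict rule a singleton negative set can never trigger
  sc_gt <- code_score(e, mk, score_config("code", "strict_gt"))
  expect_gt(sc_gt["x", "A"], 0)
})

test_that("code equals coexpr wherever code is nonzero", {
  for (seed in c(2, 9)) {
    e <- random_expr(40, 15, seed = seed)
    mk <- list(A = c("g1", "g2", "g3"), B = c("g1", "g2", "g5"),
               C = c("g8", "g9"))
    omega <- code_score(e, mk, score_config("code", "winsorized_ge"))
    psi <- code_score(e, mk, score_config("coexpr"))
    expect_true(all(omega >= 0))
    expect_true(all(psi >= 0))
    nz <- omega != 0
    expect_equal(omega[nz], psi[nz])
    # negative masking only ever zeroes
    expect_true(all(psi[!nz & psi != 0] >= 0))
  }
})

test_that("scores are invariant to gene and cell permutations", {
  e <- random_expr(25, 12, seed = 13)
  mk <- list(A = c("g2", "g4", "g7"), B = c("g2", "g4", "g9"))
  sc <- code_score(e, mk)
  set.seed(1)
  pg <- sample(n_genes(e)); pc <- sample(n_cells(e))
  ep <- expression_matrix(e$values[pc, pg], layer = e$layer)
  scp <- code_score(ep, mk)
  expect_equal(scp[e$cell_ids, ], sc[, ])
})

test_that("additive control scorer is the mean-shift formula", {
  e <- random_expr(20, 8, seed = 21)
  mk <- list(A = c("g1", "g3"))
  sc <- code_score(e, mk, score_config("additive"))
  v <- as.matrix(e$values[, c("g1", "g3")])
  expect_equal(unname(sc[, "A"]), unname(rowMeans(v) - mean(v)))
  # additive_neg zeroes negative-hit cells, and needs a second cluster
  mk2 <- list(A = c("g1", "g3", "g5"), B = c("g1", "g3", "g7"))
  sn <- code_score(e, mk2, score_config("additive_neg", "winsorized_ge"))
  hit <- as.matrix(e$values[, "g7"]) > 0
  expect_true(all(sn[hit, "A"] == 0))
})

test_that("sparse and dense storage give identical scores", {
  e <- random_expr(30, 10, seed = 31)
  es <- expression_matrix(methods::as(e$values, "CsparseMatrix"),
                          layer = e$layer)
  mk <- list(A = c("g1", "g2", "g3"), B = c("g1", "g2", "g6"))
  for (method in c("code", "coexpr", "additive", "additive_neg")) {
    cfg <- score_config(method, "winsorized_ge")
    expect_equal(unclass(code_score(e, mk, cfg)),
                 unclass(code_score(es, mk, cfg)), tolerance = 1e-12)
  }
})

test_that("diagnostic ordering groups cells by cluster on the diagonal", {
  sc <- matrix(runif(12), 6, 2, dimnames = list(paste0("c", 1:6),
                                                c("A", "B")))
  class(sc) <- c("score_matrix", class(sc))
  lab <- c("B", "A", "B", "A", "B", "A")
  ord <- diagnostic_order(sc, lab)
  expect_equal(lab[ord$cell_order], c("A", "A", "A", "B", "B", "B"))
  expect_equal(colnames(sc)[ord$cluster_order], c("A", "B"))
  # permutation round-trip restores input order
  inv <- order(ord$cell_order)
  expect_equal(seq_len(6), ord$cell_order[inv])
  # singleton clusters stay as 1-row blocks
  lab2 <- c("A", "A", "A", "A", "A", "Z")
  ord2 <- diagnostic_order(sc2 <- sc, lab2)
  expect_equal(sum(lab2[ord2$cell_order] == "Z"), 1)
})

test_that("score matrices and negative sets serialize", {
  e <- random_expr(10, 6, seed = 30)
  mk <- list(A = c("g1", "g2"), B = c("g1", "g3"))
  sc <- code_score(e, mk)
  d <- withr::local_tempdir()
  write_scores_tsv(sc, file.path(d, "s.tsv"))
  back <- utils::read.delim(file.path(d, "s.tsv"), check.names = FALSE)
  expect_equal(as.matrix(back[, c("A", "B")]), unclass(sc),
               ignore_attr = TRUE, tolerance = 1e-9)
  write_negsets_json(negative_gene_sets(mk), file.path(d, "n.json"))
  expect_true(file.exists(file.path(d, "n.json")))
})
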