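test_that("the exact one-sided rank-sum p matches enumeration on the textbook case", {
  f <- make_two_group(c(4, 5, 6), c(1, 2, 3))
  res <- wilcoxon_overexpression(f$m, f$lab, "tgt")
  expect_equal(res$p_value, 0.05)   # 1 of choose(6,3)=20 orderings

  g <- make_two_group(rep(2, 4), rep(2, 4))
  expect_equal(wilcoxon_overexpression(g$m, g$lab, "tgt")$p_value, 1)
})

test_that("exact p-values agree with stats::wilcox.test enumeration on untied data", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    f <- make_two_group(x, y)
    mine <- wilcoxon_overexpression(f$m, f$lab, "tgt")$p_value
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("exact p-values with ties agree with a permutation oracle", {
  set.seed(18)
  x <- c(3, 3, 5, 2, 4); y <- c(2, 3, 1, 2, 1, 4)
  f <- make_two_group(x, y)
  mine <- wilcoxon_overexpression(f$m, f$lab, "tgt")$p_value
  pooled <- c(x, y); r <- rank(pooled); w_obs <- sum(r[1:5])
  perm <- replicate(50000, sum(rank(pooled)[sample(11, 5)]))
  expect_lt(abs(mine - mean(perm >= w_obs - 1e-9)), 0.01)
})

test_that("the normal approximation agrees with stats::wilcox.test on large tied data", {
  set.seed(19)
  for (rep in 1:10) {
    x <- rpois(40, 3); y <- rpois(120, 2.5)
    f <- make_two_group(x, y)
    mine <- wilcoxon_overexpression(f$m, f$lab, "tgt")$p_value
    ref <- suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = FALSE,
                  correct = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches an independent oracle across many genes", {
  set.seed(20)
  m <- normalize_cp10k_log(rand_counts(200, 40, seed = 20))
  lab <- group_labels(setNames(rep(c("a", "b"), each = 20), m$cell_ids))
  res <- wilcoxon_overexpression(m, lab, "a")
  expect_equal(res$adjusted_p, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("group mean expression is a per-group mean in group order", {
  vals <- matrix(0, 2, 6, dimnames = list(c("flat", "only_b"),
                                          sprintf("c%d", 1:6)))
  vals["flat", ] <- 2.5
  vals["only_b", 3:4] <- c(1, 3)
  m <- expression_matrix(vals, "cp10k_log")
  lab <- group_labels(setNames(rep(c("a", "b", "c"), each = 2), colnames(vals)),
                      group_order = c("a", "b", "c"))
  expect_equal(group_mean_expression(m, lab, "flat"),
               c(a = 2.5, b = 2.5, c = 2.5))
  expect_equal(group_mean_expression(m, lab, "only_b"), c(a = 0, b = 2, c = 0))

  m2 <- normalize_cp10k_log(rand_counts(30, 24, seed = 6))
  lab2 <- group_labels(setNames(rep(c("x", "y", "z"), 8), m2$cell_ids))
  oracle <- tapply(m2$values["g010", ], lab2$labels[m2$cell_ids], mean)
  expect_equal(unname(group_mean_expression(m2, lab2, "g010")),
               as.numeric(oracle[c("x", "y", "z")]))
})

test_that("gini index has its closed-form values and invariances", {
  expect_equal(gini_index(rep(1, 6)), 0)
  expect_equal(gini_index(c(1, 0, 0, 0, 0, 0)), 5 / 6)
  expect_equal(gini_index(c(2, 1, 1, 1, 1, 0)), 20 / 72)
  expect_equal(gini_index(rep(0, 6)), 0)      # all-zero convention
  expect_error(gini_index(c(1, -1)), "negative")

  set.seed(21)
  for (i in 1:50) {
    x <- rexp(sample(2:10, 1))
    expect_equal(gini_index(x), gini_index(7.3 * x), tolerance = 1e-12)
    expect_equal(gini_index(x), gini_index(sample(x)), tolerance = 1e-12)
    expect_equal(gini_index(x), gini_oracle(x), tolerance = 1e-12)
    expect_gte(gini_index(x), 0)
    expect_lte(gini_index(x), 1)
  }
})

test_that("specific-ligand ranking recovers planted ligands and orders by gini", {
  cfg <- default_paper_like_config(seed = 3L)
  ds <- generate_dataset(cfg)
  norm <- normalize_cp10k_log(ds$expression)
  tbl <- rank_specific_ligands(norm, ds$labels, "PMC_P", cfg$ligand_universe)
  planted <- cfg$specific_ligands$gene_id
  expect_true(all(planted %in% tbl$gene_id[tbl$passes]))
  expect_true(all(diff(tbl$gini) <= 0))                 # sorted descending
  expect_true(all(tbl$adjusted_p < 0.05))               # p filter applied
  decoys <- setdiff(cfg$ligand_universe, planted)
  expect_gte(mean(!decoys %in% tbl$gene_id[tbl$passes]), 0.95)
  sc <- attr(tbl, "scatter")
  expect_equal(nrow(sc), length(cfg$ligand_universe))
  expect_true(all(c("gini", "neg_log10_p") %in% names(sc)))
})

test_that("a ligand's gini does not decrease with its planted fold", {
  ginis <- sapply(c(2, 4, 8), function(fold) {
    cfg <- small_config(
      seed = 50L, n_per_group = 60L,
      named_genes = c(AREG = 5L),
      specific_ligands = data.frame(gene_id = "AREG", target_group = "PMC_P",
                                    fold = fold),
      ligand_universe = "AREG")
    ds <- generate_dataset(cfg)
    norm <- normalize_cp10k_log(ds$expression)
    tbl <- rank_specific_ligands(norm, ds$labels, "PMC_P", "AREG",
                                 p_cutoff = 1.01)
    tbl$gini[tbl$gene_id == "AREG"]
  })
  expect_true(all(diff(ginis) >= 0))
})

test_that("ranking requires a usable universe", {
  m <- normalize_cp10k_log(rand_counts(10, 12, seed = 1))
  lab <- group_labels(setNames(rep(c("a", "b"), 6), m$cell_ids))
  expect_error(rank_specific_ligands(m, lab, "a", c("nope1", "nope2")),
               "universe")
})
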