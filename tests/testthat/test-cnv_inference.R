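norm_fixture <- function(n_genes = 60, n_cells = 20, seed = 2) {
  normalize_cp10k_log(rand_counts(n_genes, n_cells, seed = seed))
}

test_that("relative expression centers on the reference and clips", {
  vals <- matrix(2, 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  vals[2, ] <- c(1, 1, 1, 5)  # reference mean 1, one observation at 5
  vals[3, ] <- 0.01           # below the floor
  m <- expression_matrix(vals, "cp10k_log")
  rel <- compute_relative_expression(m, reference_cells = c("c1", "c2", "c3"))
  expect_equal(unname(rel$values["g1", ]), rep(0, 4))      # constant gene -> 0
  expect_equal(unname(rel$values["g2", "c4"]), 3)           # 4 clipped to 3
  expect_false("g3" %in% rel$retained_gene_ids)             # floored out
  expect_true(all(rel$values >= -3 & rel$values <= 3))

  expect_error(compute_relative_expression(m, character(0)), "empty reference")
  expect_error(compute_relative_expression(m, "c1", floor = 99), "no gene survives")
})

test_that("relative expression matches a brute-force center-then-clip oracle", {
  m <- norm_fixture(200, 40, seed = 13)
  ref <- m$cell_ids[1:10]
  rel <- compute_relative_expression(m, ref, floor = 0.2, clip = 3)
  keep <- rowMeans(m$values) >= 0.2
  oracle <- m$values[keep, ] - rowMeans(m$values[keep, ref])
  oracle <- pmin(pmax(oracle, -3), 3)
  expect_equal(rel$values, oracle, tolerance = 1e-12)
})

make_rel <- function(values, ref_ids) {
  structure(list(values = values, retained_gene_ids = rownames(values),
                 reference_cell_ids = ref_ids),
            class = "relative_expression")
}

test_that("chromosome smoothing truncates windows and never leaks across chromosomes", {
  g <- sprintf("g%02d", 1:10)
  pos <- gene_positions(g, rep(c("chr1", "chr2"), each = 5), rep(1:5 * 100, 2))
  v <- matrix(0, 10, 2, dimnames = list(g, c("c1", "c2")))
  v[3, 1] <- 1                 # impulse mid-chr1
  v[5, 2] <- 1                 # impulse at last gene of chr1
  prof <- smooth_by_chromosome(make_rel(v, "c2"), pos, window = 3)
  expect_equal(unname(prof$cnv_o[1:5, "c1"]), c(0, 1/3, 1/3, 1/3, 0))
  expect_equal(unname(prof$cnv_o[6:10, "c2"]), rep(0, 5))  # chr2 untouched
  expect_equal(rownames(prof$cnv_o), g)                    # window labeled by its gene

  const <- matrix(0.7, 10, 1, dimnames = list(g, "c1"))
  pc <- smooth_by_chromosome(make_rel(const, "c1"), pos, window = 3)
  expect_equal(unname(pc$cnv_o[, 1]), rep(0.7, 10))
})

test_that("smoothing equals the brute-force moving average oracle", {
  set.seed(5)
  g <- sprintf("g%02d", 1:50)
  pos <- gene_positions(g, rep("chr1", 50), 1:50)
  v <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(g, sprintf("c%02d", 1:20)))
  for (w in c(1, 3, 7, 100)) {
    prof <- smooth_by_chromosome(make_rel(v, "c01"), pos, window = w)
    oracle <- apply(v, 2, movavg_oracle, w = w)
    expect_equal(unname(prof$cnv_o), unname(oracle), tolerance = 1e-10)
  }
})

test_that("a chromosome with no retained genes is skipped with a warning", {
  g <- sprintf("g%02d", 1:4)
  pos <- gene_positions(c(g, "gX"), c(rep("chr1", 4), "chr2"), c(1:4, 1))
  v <- matrix(1, 4, 2, dimnames = list(g, c("c1", "c2")))
  expect_warning(smooth_by_chromosome(make_rel(v, "c1"), pos, window = 3),
                 "chr2")
})

test_that("CNV signal score is the mean of squares", {
  g <- sprintf("g%03d", 1:200)
  mk <- function(vals) {
    structure(list(cnv_o = matrix(vals, 200, 1, dimnames = list(g, "c1")),
                   reference_cell_ids = character(0)),
              class = "cnv_profile")
  }
  expect_equal(unname(score_cnv_signal(mk(0))), 0)
  expect_equal(unname(score_cnv_signal(mk(0.5))), 0.25)
  set.seed(8)
  x <- rnorm(200)
  expect_equal(unname(score_cnv_signal(mk(x))), sum(x^2) / 200)
})

test_that("CNV correlation matches Pearson against the observation mean", {
  set.seed(9)
  o <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:30)))
  p <- structure(list(cnv_o = o, reference_cell_ids = character(0)),
                 class = "cnv_profile")
  r <- score_cnv_correlation(p)
  mean_prof <- rowMeans(o)
  oracle <- apply(o, 2, cor, y = mean_prof)
  expect_equal(unname(r), unname(oracle), tolerance = 1e-10)

  # cell equal to the mean profile -> 1; negated -> -1
  o2 <- cbind(o, equal = mean_prof, neg = -mean_prof)
  p2 <- structure(list(cnv_o = o2, reference_cell_ids = character(0)),
                  class = "cnv_profile")
  r2 <- score_cnv_correlation(p2, observation_cells = colnames(o))
  expect_equal(unname(r2["equal"]), 1, tolerance = 1e-10)
  expect_equal(unname(r2["neg"]), -1, tolerance = 1e-10)

  # constant profile is flagged missing
  o3 <- cbind(o, flat = rep(1, 40))
  p3 <- structure(list(cnv_o = o3, reference_cell_ids = character(0)),
                  class = "cnv_profile")
  expect_true(is.na(score_cnv_correlation(p3, colnames(o))["flat"]))
})

test_that("baselines are per-window extrema and mean over reference cells", {
  z <- matrix(c(-0.3, 0.1, 0.2), 1, 3,
              dimnames = list("w1", c("r1", "r2", "r3")))
  p <- structure(list(cnv_o = z, cnv_z = z,
                      reference_cell_ids = c("r1", "r2", "r3")),
                 class = "cnv_profile")
  b <- compute_baselines(p)
  expect_equal(b$base_min, -0.3)
  expect_equal(b$base_max, 0.2)
  expect_equal(b$base_mean, 0)

  set.seed(10)
  z2 <- matrix(rnorm(30 * 8), 30, 8,
               dimnames = list(sprintf("w%02d", 1:30), sprintf("r%d", 1:8)))
  p2 <- structure(list(cnv_o = z2, cnv_z = z2,
                       reference_cell_ids = colnames(z2)),
                  class = "cnv_profile")
  b2 <- compute_baselines(p2)
  expect_equal(b2$base_min, unname(apply(z2, 1, min)))
  expect_equal(b2$base_max, unname(apply(z2, 1, max)))
  expect_equal(b2$base_mean, unname(rowMeans(z2)))
  expect_true(all(b2$base_min <= b2$base_mean & b2$base_mean <= b2$base_max))

  zero <- matrix(0, 2, 3, dimnames = list(c("w1", "w2"), c("r1", "r2", "r3")))
  p0 <- structure(list(cnv_o = zero, cnv_z = zero,
                       reference_cell_ids = colnames(zero)),
                  class = "cnv_profile")
  b0 <- compute_baselines(p0)
  expect_true(all(b0$base_min == 0 & b0$base_mean == 0 & b0$base_max == 0))
})

test_that("finalization applies the three branches with boundary equalities at zero", {
  mk <- function(z) {
    structure(list(cnv_z = matrix(z, 1, length(z),
                                  dimnames = list("w1", paste0("c", seq_along(z)))),
                   cnv_o = matrix(z, 1, length(z),
                                  dimnames = list("w1", paste0("c", seq_along(z)))),
                   reference_cell_ids = character(0)),
              class = "cnv_profile")
  }
  b <- data.frame(window_gene_id = "w1", base_min = -0.1,
                  base_mean = 0, base_max = 0.1)
  class(b) <- c("baseline_pair", "data.frame")

  # upper branch: 0.5 > 0.1 + 0.2 -> 0.5 - 0.1 = 0.4
  # middle: 0.0 -> 0 ; boundary 0.3 (== base_max + margin) -> 0
  # lower: -0.6 < -0.1 - 0.2 -> -0.6 - (-0.1) = -0.5 ; boundary -0.3 -> 0
  out <- finalize_cnv(mk(c(0.5, 0.0, 0.3, -0.6, -0.3)), b, margin = 0.2)
  expect_equal(unname(out$cnv_f[1, ]), c(0.4, 0, 0, -0.5, 0))

  bad <- b; bad$window_gene_id <- "other"
  expect_error(finalize_cnv(mk(0), bad, 0.2), "window mismatch")
})

planted_dataset <- function(seed = 31L, fold = 2) {
  cfg <- simulation_config(
    n_genes = 400L, genes_per_chromosome = 100L,
    groups = c(normal = 60L, T = 60L),
    reference_groups = "normal",
    cnv_segments = data.frame(group = "T", chromosome = "chr2",
                              start_gene_index = 26L, n_genes = 40L,
                              fold = fold),
    seed = seed)
  generate_dataset(cfg)
}

test_that("run_cnv output is invariant to input cell and gene ordering", {
  ds <- planted_dataset()
  res <- run_cnv(ds$expression, ds$positions, ds$labels, "normal", window = 30L)

  set.seed(4)
  shuffled <- ds$expression$values[sample(nrow(ds$expression$values)),
                                   sample(ncol(ds$expression$values))]
  res2 <- run_cnv(expression_matrix(shuffled, "counts"), ds$positions,
                  ds$labels, "normal", window = 30L)
  cells <- colnames(res$profile$cnv_f)
  expect_equal(res2$profile$cnv_f[rownames(res$profile$cnv_f), cells],
               res$profile$cnv_f, tolerance = 1e-12)
})

test_that("run_cnv recovers a planted gain and zeroes reference cells", {
  ds <- planted_dataset()
  res <- run_cnv(ds$expression, ds$positions, ds$labels, "normal", window = 30L)
  f <- res$profile$cnv_f
  seg <- ds$ground_truth$cnv_segments$gene_ids[[1]]
  tc <- names(ds$labels$labels)[ds$labels$labels == "T"]
  is_seg <- rownames(f) %in% seg
  carrier <- rowMeans(f[, intersect(colnames(f), tc)])
  expect_gt(mean(carrier[is_seg]), 0)
  expect_gt(mean(carrier[is_seg]), mean(carrier[!is_seg]))
  # reference cells sit inside their own baseline band
  expect_gte(mean(f[, res$reference_cell_ids] == 0), 0.95)
})

test_that("segment cnv_f responds monotonically to the planted fold", {
  seg_mean <- sapply(c(1.0, 1.5, 2.0), function(fold) {
    ds <- planted_dataset(seed = 77L, fold = fold)
    res <- run_cnv(ds$expression, ds$positions, ds$labels, "normal", window = 30L)
    seg <- if (is.null(ds$ground_truth$cnv_segments)) character(0) else
      ds$ground_truth$cnv_segments$gene_ids[[1]]
    tc <- names(ds$labels$labels)[ds$labels$labels == "T"]
    f <- res$profile$cnv_f
    mean(f[rownames(f) %in% seg, intersect(colnames(f), tc)])
  })
  expect_true(all(diff(seg_mean) >= 0))
})

test_that("an infinite margin zeroes every finalized value", {
  ds <- planted_dataset()
  res <- run_cnv(ds$expression, ds$positions, ds$labels, "normal",
                 window = 30L, margin = Inf)
  expect_true(all(res$profile$cnv_f == 0))
})

test_that("group CNV summaries aggregate correctly", {
  ds <- planted_dataset()
  res <- run_cnv(ds$expression, ds$positions, ds$labels, "normal", window = 30L)
  summ <- summarize_group_cnv(res, ds$labels)
  expect_equal(sum(summ$n), ncol(res$profile$cnv_f))
  carrier <- summ$median[summ$group == "T"]
  refmed <- summ$median[summ$group == "normal"]
  expect_gt(carrier, refmed)

  # identical per-cell levels give identical summaries
  lv <- setNames(rep(c(0.1, 0.2), each = 10), sprintf("c%02d", 1:20))
  lab <- group_labels(setNames(rep(c("a", "b"), 10), names(lv)))
  s2 <- summarize_group_cnv(c(lv[1:10] * 0 + 0.3, lv[11:20] * 0 + 0.3), lab)
  expect_equal(s2$median, rep(0.3, 2))

  lab3 <- group_labels(setNames(rep("a", 20), names(lv)), c("a", "ghost"))
  expect_warning(summarize_group_cnv(lv, lab3), "ghost")
})
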