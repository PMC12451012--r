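test_that("identical config and seed give bit-identical datasets", {
  cfg <- small_config(seed = 11L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$labels$labels, d2$labels$labels)

  d3 <- generate_dataset(small_config(seed = 12L))
  expect_false(identical(d1$expression$values, d3$expression$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_dataset(small_config(seed = 5L)))
  expect_identical(runif(1), before)
})

test_that("null config groups are statistically exchangeable", {
  cfg <- simulation_config(
    n_genes = 300L, genes_per_chromosome = 100L,
    groups = c(normal = 200L, T = 200L),
    reference_groups = "normal", seed = 21L)
  ds <- generate_dataset(cfg)
  totals <- colSums(ds$expression$values)
  grp <- ds$labels$labels[names(totals)]
  ks <- suppressWarnings(ks.test(totals[grp == "normal"], totals[grp == "T"]))
  expect_gt(ks$p.value, 0.01)

  # per-group statistic sits inside its label-permutation null
  gene_means <- function(lab) mean(ds$expression$values[1:50, lab == "T"])
  observed <- gene_means(grp)
  set.seed(1)
  perm <- replicate(10, gene_means(sample(grp)))
  expect_gte(observed, min(perm) - 3 * sd(perm))
  expect_lte(observed, max(perm) + 3 * sd(perm))
})

test_that("a planted fold-2 segment shifts segment-gene means by ~2x", {
  cfg <- simulation_config(
    n_genes = 200L, genes_per_chromosome = 100L,
    groups = c(normal = 300L, T = 300L),
    reference_groups = "normal",
    cnv_segments = data.frame(group = "T", chromosome = "chr1",
                              start_gene_index = 11L, n_genes = 50L, fold = 2),
    seed = 31L)
  ds <- generate_dataset(cfg)
  seg <- ds$ground_truth$cnv_segments$gene_ids[[1]]
  tc <- names(ds$labels$labels)[ds$labels$labels == "T"]
  nc <- names(ds$labels$labels)[ds$labels$labels == "normal"]
  ratio <- mean(ds$expression$values[seg, tc]) /
    mean(ds$expression$values[seg, nc])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  expect_equal(ds$ground_truth$cnv_segments$direction, "gain")
  expect_true(all(seg %in% ds$positions$gene_id))
})

test_that("planted ligand-signature correlation is recovered on a fresh redraw", {
  cfg <- default_paper_like_config(seed = 404L)
  cfg$groups["PMC_P"] <- 500L
  validate_simulation_config(cfg)
  ds <- generate_dataset(cfg)
  norm <- normalize_cp10k_log(ds$expression)
  plant <- ds$ground_truth$signature_plants[[1]]
  sc <- score_signature(norm, setNames(list(plant$signature_genes), plant$name))
  rho <- ligand_signature_correlation(norm, sc, plant$driver_ligand,
                                      ds$labels, region = plant$target_group)$rho
  expect_lt(abs(rho - plant$correlation_strength), 0.15)
})

test_that("config invariants reject inconsistent plants", {
  expect_error(small_config(cnv_segments = data.frame(
    group = "normal", chromosome = "chr1", start_gene_index = 1L,
    n_genes = 5L, fold = 2)), "reference_groups may not carry")
  expect_error(small_config(cnv_segments = data.frame(
    group = "T", chromosome = "chr1", start_gene_index = 31L,
    n_genes = 50L, fold = 2)), "exceeds its chromosome")
  expect_error(small_config(specific_ligands = data.frame(
    gene_id = "G001", target_group = "nope", fold = 3)), "target group")
  expect_error(small_config(cnv_segments = data.frame(
    group = "T", chromosome = "chr1", start_gene_index = 1L,
    n_genes = 5L, fold = -1)), "folds must be > 0")
  expect_error(small_config(signature_plants = list(list(
    name = "x", signature_genes = "G0001", driver_ligand = "G0002",
    correlation_strength = 1.5, target_group = "T"))),
    "correlation_strength")
})

test_that("the default paper-like config encodes the study conditions", {
  cfg <- default_paper_like_config(seed = 1L)
  expect_silent(validate_simulation_config(cfg))
  expect_equal(names(cfg$groups),
               c("normal", "GMC_P", "IM", "PMC_P", "Pro_T", "T"))
  expect_equal(cfg$reference_groups, "normal")
  expect_equal(nrow(cfg$specific_ligands), 5)
  expect_setequal(cfg$specific_ligands$gene_id,
                  c("AREG", "IL1B", "NAMPT", "KLK7", "IGFBP3"))
  expect_true(all(cfg$specific_ligands$target_group == "PMC_P"))
  expect_true(all(cfg$specific_ligands$fold >= 3))
  expect_false(any(cfg$cnv_segments$group %in% cfg$reference_groups))
})

test_that("datasets round-trip through write_dataset", {
  ds <- generate_dataset(small_config(seed = 8L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_expression(file.path(dir, "expression"), "mtx_triplet")
  expect_identical(back$values, ds$expression$values)
  pos <- read_gene_positions(file.path(dir, "gene_positions.tsv"))
  expect_equal(pos$gene_id, ds$positions$gene_id)
  lab <- read_group_labels(file.path(dir, "group_labels.tsv"))
  expect_identical(lab$labels, ds$labels$labels)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
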