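#' Build a simulation configuration
#'
#' Defines a synthetic grouped expression dataset: negative-binomial counts
#' with log-normal baseline gene means, genes laid out consecutively on
#' chromosomes at fixed spacing, and three kinds of planted structure --
#' contiguous copy-number segments (mean-fold multiplication over a gene
#' block), group-specific over-expressed ligands (mean-fold in one target
#' group), and ligand-signature co-expression (a shared Gaussian latent factor
#' on the log-mean scale of the driver ligand and the signature genes in
#' target-group cells, calibrated so their normalized values correlate at
#' approximately the requested Spearman strength).
#'
#' @param n_genes total number of genes.
#' @param genes_per_chromosome genes per chromosome (chromosomes are named
#'   chr1, chr2, ...; the last chromosome may be shorter).
#' @param groups named integer vector: group name -> number of cells.
#' @param reference_groups group names assumed copy-number neutral; they may
#'   not carry CNV segments.
#' @param baseline_mean median negative-binomial mean per gene (counts).
#'   The default 2 puts a 2,000-gene panel at the sequencing depth typical of
#'   10x data (a few thousand UMIs per cell over the detected genes).
#' @param baseline_sdlog log-normal spread (sdlog) of baseline gene means.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed).
#' @param planted_base_mean fixed baseline mean (counts) given to named
#'   planted genes (ligands, signature genes) so planted effects are measured
#'   on a stable expression footing.
#' @param cnv_segments data.frame with columns `group`, `chromosome`,
#'   `start_gene_index` (1-based, within chromosome), `n_genes`, `fold` (> 0;
#'   > 1 gain, < 1 loss), or NULL.
#' @param specific_ligands data.frame with columns `gene_id`, `target_group`,
#'   `fold` (> 0), or NULL.
#' @param signature_plants list of lists with elements `name`,
#'   `signature_genes`, `driver_ligand`, `correlation_strength` (in `[0, 1]`),
#'   `target_group`, or NULL.
#' @param named_genes named integer vector assigning real gene symbols to
#'   global gene indices (these rows are renamed and given
#'   `planted_base_mean`).
#' @param ligand_universe character vector of gene ids forming the secreted
#'   ligand universe for specificity ranking.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   generate bit-identical datasets.
#' @return A validated list of class `simulation_config`.
#' @seealso [default_paper_like_config()], [generate_dataset()]
#' @export
simulation_config <- function(n_genes,
                              genes_per_chromosome,
                              groups,
                              reference_groups,
                              baseline_mean = 2,
                              baseline_sdlog = 1,
                              dispersion = 5,
                              planted_base_mean = 2,
                              cnv_segments = NULL,
                              specific_ligands = NULL,
                              signature_plants = NULL,
                              named_genes = NULL,
                              ligand_universe = NULL,
                              seed = 1L) {
  cfg <- structure(
    list(n_genes = as.integer(n_genes),
         genes_per_chromosome = as.integer(genes_per_chromosome),
         groups = groups,
         reference_groups = reference_groups,
         baseline_mean = baseline_mean,
         baseline_sdlog = baseline_sdlog,
         dispersion = dispersion,
         planted_base_mean = planted_base_mean,
         cnv_segments = cnv_segments,
         specific_ligands = specific_ligands,
         signature_plants = signature_plants,
         named_genes = named_genes,
         ligand_universe = ligand_universe,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Re-checks all configuration invariants; call after editing fields of an
#' existing config.
#'
#' @param cfg a `simulation_config`.
#' @return `cfg`, invisibly, or an error describing the violated invariant.
#' @export
validate_simulation_config <- function(cfg) {
  assert_that(cfg$n_genes >= 1 && cfg$genes_per_chromosome >= 1,
              "n_genes and genes_per_chromosome must be positive")
  assert_that(!is.null(names(cfg$groups)) && all(cfg$groups >= 1),
              "groups must be a named vector of positive cell counts")
  assert_that(!anyDuplicated(names(cfg$groups)), "duplicate group names")
  assert_that(all(cfg$reference_groups %in% names(cfg$groups)),
              "reference_groups must be a subset of group names")
  assert_that(cfg$baseline_mean > 0 && cfg$dispersion > 0 &&
                cfg$baseline_sdlog >= 0 && cfg$planted_base_mean > 0,
              "baseline_mean, dispersion, planted_base_mean must be positive")
  chrom_sizes <- chromosome_sizes(cfg)
  ids <- config_gene_ids(cfg)
  if (!is.null(cfg$named_genes)) {
    idx <- as.integer(cfg$named_genes)
    assert_that(all(idx >= 1 & idx <= cfg$n_genes) && !anyDuplicated(idx) &&
                  !anyDuplicated(names(cfg$named_genes)),
                "named_genes must map unique names to unique in-range indices")
  }
  seg <- cfg$cnv_segments
  if (!is.null(seg) && nrow(seg) > 0) {
    assert_that(all(seg$fold > 0), "cnv_segments folds must be > 0")
    assert_that(all(seg$group %in% names(cfg$groups)),
                "cnv_segments target groups must exist")
    assert_that(!any(seg$group %in% cfg$reference_groups),
                "reference_groups may not carry cnv_segments")
    assert_that(all(seg$chromosome %in% names(chrom_sizes)),
                "cnv_segments chromosome not in layout")
    fits <- seg$start_gene_index >= 1 &
      (seg$start_gene_index + seg$n_genes - 1) <= chrom_sizes[seg$chromosome]
    assert_that(all(fits), "cnv_segment span exceeds its chromosome")
  }
  lig <- cfg$specific_ligands
  if (!is.null(lig) && nrow(lig) > 0) {
    assert_that(all(lig$fold > 0), "specific_ligands folds must be > 0")
    assert_that(all(lig$target_group %in% names(cfg$groups)),
                "specific_ligands target groups must exist")
    assert_that(all(lig$gene_id %in% ids),
                "specific_ligands gene ids must exist (see named_genes)")
  }
  for (pl in cfg$signature_plants %||% list()) {
    assert_that(pl$correlation_strength >= 0 && pl$correlation_strength <= 1,
                "correlation_strength must be in [0, 1]")
    assert_that(pl$target_group %in% names(cfg$groups),
                "signature plant target group must exist")
    assert_that(all(c(pl$driver_ligand, pl$signature_genes) %in% ids),
                "signature plant genes must exist (see named_genes)")
  }
  if (!is.null(cfg$ligand_universe)) {
    assert_that(all(cfg$ligand_universe %in% ids),
                "ligand_universe gene ids must exist")
  }
  invisible(cfg)
}

#' @keywords internal
#' @noRd
chromosome_sizes <- function(cfg) {
  n_chrom <- ceiling(cfg$n_genes / cfg$genes_per_chromosome)
  sizes <- rep(cfg$genes_per_chromosome, n_chrom)
  sizes[n_chrom] <- cfg$n_genes - cfg$genes_per_chromosome * (n_chrom - 1)
  stats::setNames(sizes, paste0("chr", seq_len(n_chrom)))
}

#' @keywords internal
#' @noRd
config_gene_ids <- function(cfg) {
  ids <- sprintf("G%0*d", nchar(as.character(cfg$n_genes)), seq_len(cfg$n_genes))
  if (!is.null(cfg$named_genes)) {
    ids[as.integer(cfg$named_genes)] <- names(cfg$named_genes)
  }
  ids
}

#' Default study-scale configuration
#'
#' The study conditions the package's synthetic analyses run under: 2,000
#' genes on 10 chromosomes; six cell groups of 200 cells named `normal`,
#' `GMC_P`, `IM`, `PMC_P`, `Pro_T`, `T` with `normal` as the copy-number
#' reference; one fold-2 gain of 50 genes on chr5 carried by group `T`; five
#' secreted ligands (`AREG`, `NAMPT`, `IL1B`, `KLK7`, `IGFBP3`) planted as
#' PMC_P-specific at folds 8/7/6/5/5 within a 105-ligand universe (100
#' unplanted decoys `LIG001`..`LIG100`); and the six-gene PMC_2 signature
#' (`CEACAM5`, `ITGA2`, `PHLDA1`, `ANXA1`, `DUSP5`, `FERMT1`) co-expressed
#' with its driver `AREG` in PMC_P cells at Spearman strength 0.6.
#'
#' @param seed integer RNG seed.
#' @return A `simulation_config`.
#' @export
default_paper_like_config <- function(seed = 1L) {
  named <- c(
    AREG = 10L, NAMPT = 30L, IL1B = 50L, KLK7 = 70L, IGFBP3 = 90L,
    CEACAM5 = 110L, ITGA2 = 120L, PHLDA1 = 130L, ANXA1 = 140L,
    DUSP5 = 150L, FERMT1 = 160L,
    stats::setNames(400L + seq_len(100L), sprintf("LIG%03d", seq_len(100L)))
  )
  simulation_config(
    n_genes = 2000L,
    genes_per_chromosome = 200L,
    groups = c(normal = 200L, GMC_P = 200L, IM = 200L,
               PMC_P = 200L, Pro_T = 200L, T = 200L),
    reference_groups = "normal",
    baseline_mean = 2,
    baseline_sdlog = 1,
    dispersion = 5,
    planted_base_mean = 2,
    cnv_segments = data.frame(
      group = "T", chromosome = "chr5", start_gene_index = 51L,
      n_genes = 50L, fold = 2.0, stringsAsFactors = FALSE),
    specific_ligands = data.frame(
      gene_id = c("AREG", "NAMPT", "IL1B", "KLK7", "IGFBP3"),
      target_group = "PMC_P",
      fold = c(8, 7, 6, 5, 5), stringsAsFactors = FALSE),
    signature_plants = list(list(
      name = "PMC_2",
      signature_genes = c("CEACAM5", "ITGA2", "PHLDA1", "ANXA1",
                          "DUSP5", "FERMT1"),
      driver_ligand = "AREG",
      correlation_strength = 0.6,
      target_group = "PMC_P")),
    named_genes = named,
    ligand_universe = c("AREG", "NAMPT", "IL1B", "KLK7", "IGFBP3",
                        sprintf("LIG%03d", seq_len(100L))),
    seed = seed
  )
}

# Standard deviation (log2 scale) of log2(1 + scale * X), X ~ NB(mu, size),
# computed from the pmf. Deterministic; used to calibrate latent-factor
# coefficients.
#' @keywords internal
#' @noRd
nb_log2_sd <- function(mu, size, scale) {
  kmax <- stats::qnbinom(1 - 1e-12, mu = mu, size = size)
  k <- 0:max(kmax, 5)
  p <- stats::dnbinom(k, mu = mu, size = size)
  p <- p / sum(p)
  v <- log2(1 + scale * k)
  m <- sum(p * v)
  sqrt(max(sum(p * (v - m)^2), 1e-12))
}

# Mean and variance of log2(1 + scale * X), X ~ NB(mu, size), from the pmf.
#' @keywords internal
#' @noRd
nb_log2_moments <- function(mu, size, scale) {
  kmax <- stats::qnbinom(1 - 1e-12, mu = mu, size = size)
  k <- 0:max(kmax, 5)
  p <- stats::dnbinom(k, mu = mu, size = size)
  p <- p / sum(p)
  v <- log2(1 + scale * k)
  m <- sum(p * v)
  c(mean = m, var = max(sum(p * (v - m)^2), 1e-12))
}

# Signal sd (between latent values) and noise sd (within) of the log2
# normalized value of a gene with latent coefficient a, via 5-point
# Gauss-Hermite integration over z ~ N(0, 1).
#' @keywords internal
#' @noRd
latent_signal_noise <- function(mu, size, scale, a) {
  z <- c(0, 1.355626, -1.355626, 2.856970, -2.856970)
  w <- c(0.533333, 0.222076, 0.222076, 0.011257, 0.011257)
  w <- w / sum(w)
  mom <- vapply(z, function(zz) {
    nb_log2_moments(mu * exp(a * zz - a^2 / 2), size, scale)
  }, numeric(2))
  mbar <- sum(w * mom[1, ])
  c(signal = sqrt(sum(w * (mom[1, ] - mbar)^2)),
    noise = sqrt(sum(w * mom[2, ])))
}

# Latent-factor coefficient (natural-log scale) shared by the driver ligand
# and the k signature genes so their normalized values reach the requested
# Spearman correlation in target-group cells. The induced Pearson correlation
# is predicted exactly from the count model (the log2(1 + x) response
# saturates, so the signal is attenuated at low expression) and a is solved
# by root-finding; the Spearman target is mapped to a Pearson target by the
# bivariate-normal relation rho_P = 2 sin(pi rho_S / 6).
#' @keywords internal
#' @noRd
plant_coefficient <- function(strength, mu_ligand, mu_signature, k_genes,
                              size, scale) {
  if (strength <= 0) return(0)
  target <- 2 * sin(pi * min(strength, 0.99) / 6)
  predicted <- function(a) {
    sl <- latent_signal_noise(mu_ligand, size, scale, a)
    ss <- rowMeans(vapply(mu_signature, latent_signal_noise, numeric(2),
                          size = size, scale = scale, a = a))
    (sl["signal"] * ss["signal"]) /
      sqrt((sl["signal"]^2 + sl["noise"]^2) *
             (ss["signal"]^2 + ss["noise"]^2 / k_genes))
  }
  upper <- 3
  while (predicted(upper) < target && upper < 12) upper <- upper * 1.5
  stats::uniroot(function(a) predicted(a) - target,
                 lower = 1e-6, upper = upper, tol = 1e-6)$root
}

#' Generate a synthetic grouped expression dataset
#'
#' Draws counts `~ NB(mean = baseline_g x cnv_fold x ligand_fold x latent,
#' size = dispersion)` per the configuration, lays genes out consecutively on
#' chromosomes at 10 kb spacing, and returns the dataset together with the
#' planted ground truth. The same config and seed always produce bit-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `sim_dataset` with elements `expression`
#'   (counts-layer [expression_matrix()]), `positions`
#'   ([gene_positions()]), `labels` ([group_labels()]) and `ground_truth`
#'   (class `ground_truth`: planted CNV segments with resolved gene ids and
#'   gain/loss labels, planted ligands, planted correlation targets, seed).
#' @export
generate_dataset <- function(cfg) {
  validate_simulation_config(cfg)
  gene_ids <- config_gene_ids(cfg)
  chrom_sizes <- chromosome_sizes(cfg)
  chrom <- rep(names(chrom_sizes), chrom_sizes)
  within_idx <- unlist(lapply(chrom_sizes, seq_len), use.names = FALSE)
  positions <- gene_positions(gene_ids, chrom,
                              start = (within_idx - 1L) * 10000L + 1L)

  grp_names <- names(cfg$groups)
  cell_group <- rep(grp_names, times = cfg$groups)
  n_cells <- length(cell_group)
  cell_ids <- sprintf("cell%0*d", nchar(as.character(n_cells)), seq_len(n_cells))
  labels <- group_labels(stats::setNames(cell_group, cell_ids),
                         group_order = grp_names)

  planted_idx <- if (is.null(cfg$named_genes)) integer(0) else
    as.integer(cfg$named_genes)

  # per-group mean fold multipliers (genes x groups)
  fold <- matrix(1, cfg$n_genes, length(grp_names),
                 dimnames = list(gene_ids, grp_names))
  seg <- cfg$cnv_segments
  seg_genes <- list()
  if (!is.null(seg) && nrow(seg) > 0) {
    chrom_offset <- c(0L, cumsum(chrom_sizes))[seq_along(chrom_sizes)]
    names(chrom_offset) <- names(chrom_sizes)
    for (s in seq_len(nrow(seg))) {
      gidx <- chrom_offset[[seg$chromosome[s]]] + seg$start_gene_index[s] +
        seq_len(seg$n_genes[s]) - 1L
      fold[gidx, seg$group[s]] <- fold[gidx, seg$group[s]] * seg$fold[s]
      seg_genes[[s]] <- gene_ids[gidx]
    }
  }
  lig <- cfg$specific_ligands
  if (!is.null(lig) && nrow(lig) > 0) {
    for (s in seq_len(nrow(lig))) {
      fold[lig$gene_id[s], lig$target_group[s]] <-
        fold[lig$gene_id[s], lig$target_group[s]] * lig$fold[s]
    }
  }

  dataset <- with_seed(cfg$seed, {
    base <- stats::rlnorm(cfg$n_genes,
                          meanlog = log(cfg$baseline_mean),
                          sdlog = cfg$baseline_sdlog)
    base[planted_idx] <- cfg$planted_base_mean
    names(base) <- gene_ids

    mu <- base * fold[, match(cell_group, grp_names), drop = FALSE]
    dimnames(mu) <- list(gene_ids, cell_ids)

    # plant ligand-signature co-expression via a shared latent factor
    plant_info <- list()
    for (pl in cfg$signature_plants %||% list()) {
      tcells <- which(cell_group == pl$target_group)
      z <- stats::rnorm(length(tcells))
      scale_cp10k <- 1e4 / sum(base * fold[, pl$target_group])
      mu_l <- base[pl$driver_ligand] * fold[pl$driver_ligand, pl$target_group]
      mu_s <- base[pl$signature_genes] * fold[pl$signature_genes, pl$target_group]
      a <- plant_coefficient(pl$correlation_strength,
                             mu_ligand = mu_l, mu_signature = mu_s,
                             k_genes = length(pl$signature_genes),
                             size = cfg$dispersion, scale = scale_cp10k)
      genes <- c(pl$driver_ligand, pl$signature_genes)
      mu[genes, tcells] <- mu[genes, tcells, drop = FALSE] *
        rep(exp(a * z - a^2 / 2), each = length(genes))
      plant_info[[length(plant_info) + 1L]] <- list(
        name = pl$name %||% pl$driver_ligand,
        driver_ligand = pl$driver_ligand,
        signature_genes = pl$signature_genes,
        correlation_strength = pl$correlation_strength,
        target_group = pl$target_group,
        latent_coefficient = a)
    }

    counts <- matrix(
      stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu),
      nrow = cfg$n_genes, dimnames = dimnames(mu))
    storage.mode(counts) <- "double"
    list(counts = counts, plant_info = plant_info)
  })

  gt_segments <- NULL
  if (!is.null(seg) && nrow(seg) > 0) {
    gt_segments <- seg
    gt_segments$direction <- ifelse(seg$fold > 1, "gain",
                                    ifelse(seg$fold < 1, "loss", "neutral"))
    gt_segments$gene_ids <- I(seg_genes)
  }
  ground_truth <- structure(
    list(cnv_segments = gt_segments,
         specific_ligands = lig,
         signature_plants = dataset$plant_info,
         seed = cfg$seed),
    class = "ground_truth")

  structure(
    list(expression = expression_matrix(dataset$counts, layer = "counts"),
         positions = positions,
         labels = labels,
         ground_truth = ground_truth),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  print(x$expression)
  print(x$labels)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix (Matrix Market triplet directory), gene
#' positions, group labels, and ground truth (JSON) under `dir`.
#'
#' @param dataset a `sim_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression"),
                   format = "mtx_triplet")
  write_gene_positions(dataset$positions, file.path(dir, "gene_positions.tsv"))
  write_group_labels(dataset$labels, file.path(dir, "group_labels.tsv"))
  gt <- dataset$ground_truth
  gt_json <- list(
    cnv_segments = if (is.null(gt$cnv_segments)) list() else gt$cnv_segments,
    specific_ligands = if (is.null(gt$specific_ligands)) list() else
      gt$specific_ligands,
    signature_plants = gt$signature_plants,
    seed = gt$seed)
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
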