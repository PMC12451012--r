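#' Compute reference-centered relative expression
#'
#' First stage of CNV estimation from expression. Genes whose mean normalized
#' expression across all cells falls below `floor` are excluded; each retained
#' gene is centered by its mean over the reference cells; the centered values
#' are clipped to `[-clip, clip]` (values above `clip` replaced by `clip`,
#' below `-clip` by `-clip`).
#'
#' @param m an [expression_matrix()] with layer `"cp10k_log"`.
#' @param reference_cells character vector of reference cell ids (assumed
#'   copy-number neutral); must be a non-empty subset of the matrix cells.
#' @param floor expression floor applied to the mean cp10k-log expression
#'   across all cells (default 0.2).
#' @param clip symmetric clipping bound on centered values (default 3).
#' @return A list of class `relative_expression` with `values` (retained
#'   genes x cells, all in `[-clip, clip]`), `retained_gene_ids`,
#'   `reference_cell_ids`.
#' @export
compute_relative_expression <- function(m, reference_cells,
                                        floor = 0.2, clip = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  assert_that(m$layer == "cp10k_log",
              "relative expression requires cp10k_log normalized input")
  assert_that(floor >= 0 && clip > 0, "floor must be >= 0 and clip > 0")
  reference_cells <- as.character(reference_cells)
  assert_that(length(reference_cells) > 0, "empty reference cell set")
  missing <- setdiff(reference_cells, m$cell_ids)
  assert_that(length(missing) == 0,
              paste0("reference cells absent from matrix: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  keep <- rowMeans(m$values) >= floor
  assert_that(any(keep), "no gene survives the expression floor")
  vals <- m$values[keep, , drop = FALSE]
  ref_mean <- rowMeans(vals[, reference_cells, drop = FALSE])
  rel <- vals - ref_mean
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip
  structure(
    list(values = rel,
         retained_gene_ids = rownames(rel),
         reference_cell_ids = reference_cells),
    class = "relative_expression")
}

# Truncated centered moving average along rows of a matrix (one chromosome).
# Window of `w` genes centered on each gene, shrunk at the ends: row i
# averages rows max(1, i - floor((w-1)/2)) .. min(n, i + ceiling((w-1)/2)).
#' @keywords internal
#' @noRd
moving_average_rows <- function(x, w) {
  n <- nrow(x)
  if (n == 1L || w == 1L) return(x)
  lo <- pmax(1L, seq_len(n) - floor((w - 1) / 2))
  hi <- pmin(n, seq_len(n) + ceiling((w - 1) / 2))
  cs <- rbind(0, apply(x, 2, cumsum))
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  dimnames(out) <- dimnames(x)
  out
}

#' Smooth relative expression along each chromosome
#'
#' Applies a sliding moving average of `window` genes per chromosome (default
#' 100) to the clipped relative expression, yielding the smoothed profile
#' CNV_o. Windows are gene-centered and truncated at chromosome ends (the
#' average runs over `min(window, available)` genes); windows never span
#' chromosomes. One output value per retained gene.
#'
#' @param rel a `relative_expression` from [compute_relative_expression()].
#' @param positions a [gene_positions()] table covering every retained gene.
#' @param window sliding-window width in genes (default 100).
#' @return A list of class `cnv_profile` with `cnv_o` (windows x cells, rows
#'   ordered by chromosome then position), `window_gene_ids`,
#'   `window_chromosomes`, `reference_cell_ids`.
#' @export
smooth_by_chromosome <- function(rel, positions, window = 100L) {
  stopifnot(inherits(rel, "relative_expression"))
  stopifnot(inherits(positions, "gene_positions"))
  assert_that(window >= 1, "window must be >= 1")
  missing <- setdiff(rel$retained_gene_ids, positions$gene_id)
  assert_that(length(missing) == 0,
              paste0("retained genes missing from positions: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  pos <- positions[positions$gene_id %in% rel$retained_gene_ids, , drop = FALSE]
  chrom_order <- attr(positions, "chromosome_order")
  empty <- setdiff(unique(positions$chromosome), unique(pos$chromosome))
  if (length(empty) > 0) {
    warning("chromosome(s) with no retained genes skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  chroms <- chrom_order[chrom_order %in% unique(pos$chromosome)]
  blocks <- lapply(chroms, function(ch) {
    genes <- pos$gene_id[pos$chromosome == ch]  # positions already sorted
    moving_average_rows(rel$values[genes, , drop = FALSE], window)
  })
  cnv_o <- do.call(rbind, blocks)
  structure(
    list(cnv_o = cnv_o,
         window_gene_ids = rownames(cnv_o),
         window_chromosomes = rep(chroms, vapply(blocks, nrow, integer(1))),
         reference_cell_ids = rel$reference_cell_ids),
    class = "cnv_profile")
}

#' Per-cell CNV signal score
#'
#' The extent of copy-number signal of each cell: the mean of squares of its
#' smoothed CNV_o values across the genome.
#'
#' @param p a `cnv_profile` with `cnv_o`.
#' @return Named numeric vector (cell id -> signal score, >= 0).
#' @export
score_cnv_signal <- function(p) {
  stopifnot(inherits(p, "cnv_profile"))
  colMeans(p$cnv_o^2)
}

#' Per-cell CNV correlation score
#'
#' Pearson correlation between each cell's CNV_o profile and the average
#' CNV_o profile over observation (non-reference) cells. Cells whose profile
#' has zero variance (or a zero-variance mean profile) get `NA`.
#'
#' @param p a `cnv_profile` with `cnv_o`.
#' @param observation_cells character vector of observation cell ids;
#'   defaults to all profiled cells not in `p$reference_cell_ids`.
#' @return Named numeric vector (cell id -> correlation in `[-1, 1]` or `NA`).
#' @export
score_cnv_correlation <- function(p, observation_cells = NULL) {
  stopifnot(inherits(p, "cnv_profile"))
  assert_that(nrow(p$cnv_o) >= 2, "need at least 2 windows for correlation")
  cells <- colnames(p$cnv_o)
  if (is.null(observation_cells)) {
    observation_cells <- setdiff(cells, p$reference_cell_ids)
  }
  assert_that(length(observation_cells) > 0, "empty observation cell set")
  mean_profile <- rowMeans(p$cnv_o[, observation_cells, drop = FALSE])
  ctr_m <- mean_profile - mean(mean_profile)
  denom_m <- sqrt(sum(ctr_m^2))
  ctr <- sweep(p$cnv_o, 2, colMeans(p$cnv_o))
  denom_c <- sqrt(colSums(ctr^2))
  r <- as.vector(crossprod(ctr, ctr_m)) / (denom_c * denom_m)
  r[denom_c == 0 | denom_m == 0] <- NA_real_
  stats::setNames(pmin(1, pmax(-1, r)), cells)
}

#' Re-center CNV_o into CNV_z
#'
#' CNV_z(i, j) = CNV_o(i, j) minus the mean CNV_o over all cells at window j,
#' so each window's profile is expressed relative to the dataset-wide average
#' pattern.
#'
#' @param p a `cnv_profile` with `cnv_o`.
#' @return The profile with `cnv_z` added.
#' @export
center_cnv <- function(p) {
  stopifnot(inherits(p, "cnv_profile"))
  p$cnv_z <- p$cnv_o - rowMeans(p$cnv_o)
  p
}

#' Reference baselines at each window
#'
#' From the reference cells' CNV_z values, computes at every gene window the
#' mean baseline and the maximal (BaseMax) and minimal (BaseMin) baselines.
#'
#' @param p a `cnv_profile` with `cnv_z` (see [center_cnv()]).
#' @return A data.frame of class `baseline_pair` with columns
#'   `window_gene_id`, `base_min`, `base_mean`, `base_max`
#'   (`base_min <= base_mean <= base_max` at every window).
#' @export
compute_baselines <- function(p) {
  stopifnot(inherits(p, "cnv_profile"))
  assert_that(!is.null(p$cnv_z), "cnv_z not computed; call center_cnv() first")
  ref <- intersect(p$reference_cell_ids, colnames(p$cnv_z))
  assert_that(length(ref) > 0, "empty reference cell set")
  z <- p$cnv_z[, ref, drop = FALSE]
  out <- data.frame(
    window_gene_id = rownames(z),
    base_min = apply(z, 1, min),
    base_mean = rowMeans(z),
    base_max = apply(z, 1, max),
    stringsAsFactors = FALSE)
  class(out) <- c("baseline_pair", "data.frame")
  out
}

#' Finalize CNV estimates against the reference band
#'
#' The finalized estimate of cell i at window j is
#' `CNV_z(i,j) - BaseMax(j)` when `CNV_z(i,j) > BaseMax(j) + margin`,
#' `CNV_z(i,j) - BaseMin(j)` when `CNV_z(i,j) < BaseMin(j) - margin`,
#' and 0 otherwise. Values equal to either boundary fall in the zero branch.
#'
#' @param p a `cnv_profile` with `cnv_z`.
#' @param b a `baseline_pair` from [compute_baselines()] on the same windows.
#' @param margin half-width added to the reference band (default 0.2).
#' @return The profile with `cnv_f` added.
#' @export
finalize_cnv <- function(p, b, margin = 0.2) {
  stopifnot(inherits(p, "cnv_profile"), inherits(b, "baseline_pair"))
  assert_that(!is.null(p$cnv_z), "cnv_z not computed; call center_cnv() first")
  assert_that(identical(rownames(p$cnv_z), b$window_gene_id),
              "window mismatch between profile and baselines")
  z <- p$cnv_z
  up <- z > (b$base_max + margin)
  dn <- z < (b$base_min - margin)
  f <- matrix(0, nrow(z), ncol(z), dimnames = dimnames(z))
  f[up] <- (z - b$base_max)[up]
  f[dn] <- (z - b$base_min)[dn]
  p$cnv_f <- f
  p
}

#' Run the full CNV-estimation pipeline
#'
#' Executes normalization (if given counts), relative expression (floor,
#' reference centering, clipping), per-chromosome smoothing (CNV_o),
#' re-centering (CNV_z), per-cell signal and correlation scores, reference
#' baselines, and finalization (CNV_f).
#'
#' @param m an [expression_matrix()]; a counts layer is normalized with
#'   [normalize_cp10k_log()] first.
#' @param positions a [gene_positions()] table. Genes absent from it are
#'   dropped before the expression floor is applied.
#' @param labels a [group_labels()] object covering all matrix cells.
#' @param reference_groups group names whose cells form the copy-number
#'   neutral reference.
#' @param floor,clip,window,margin stage parameters; defaults 0.2, 3, 100, 0.2.
#' @return A list of class `cnv_result` with `profile` (a `cnv_profile` with
#'   `cnv_o`, `cnv_z`, `cnv_f`), `scores` (data.frame `cell_id`, `group`,
#'   `signal`, `correlation`), `baselines`, `params`,
#'   `reference_cell_ids`, `observation_cell_ids`.
#' @export
run_cnv <- function(m, positions, labels, reference_groups,
                    floor = 0.2, clip = 3, window = 100L, margin = 0.2) {
  stopifnot(inherits(m, "expr_matrix"), inherits(labels, "group_labels"))
  assert_that(all(reference_groups %in% labels$group_order),
              "reference_groups must be present in labels")
  if (m$layer == "counts") m <- normalize_cp10k_log(m)

  in_pos <- m$gene_ids %in% positions$gene_id
  if (!all(in_pos)) {
    message(sum(!in_pos), " gene(s) without positions dropped before CNV")
    m <- expression_matrix(m$values[in_pos, , drop = FALSE], layer = m$layer)
  }

  reference_cells <- cells_of_groups(m, labels, reference_groups)
  assert_that(length(reference_cells) > 0, "no cells in reference groups")
  observation_cells <- setdiff(m$cell_ids, reference_cells)

  rel <- compute_relative_expression(m, reference_cells,
                                     floor = floor, clip = clip)
  prof <- smooth_by_chromosome(rel, positions, window = window)
  prof <- center_cnv(prof)
  baselines <- compute_baselines(prof)
  prof <- finalize_cnv(prof, baselines, margin = margin)

  scores <- data.frame(
    cell_id = colnames(prof$cnv_o),
    group = unname(labels$labels[colnames(prof$cnv_o)]),
    signal = unname(score_cnv_signal(prof)),
    correlation = unname(score_cnv_correlation(prof, observation_cells)),
    stringsAsFactors = FALSE)

  structure(
    list(profile = prof,
         scores = scores,
         baselines = baselines,
         params = list(floor = floor, clip = clip, window = window,
                       margin = margin, reference_groups = reference_groups),
         reference_cell_ids = reference_cells,
         observation_cell_ids = observation_cells),
    class = "cnv_result")
}

#' Per-group summary of CNV levels
#'
#' Summarizes the per-cell large-scale CNV level by group. The level of a cell
#' is the mean of `|CNV_f|` across windows (margin-robust absolute finalized
#' CNV); a numeric vector of pre-computed per-cell levels is also accepted.
#'
#' @param x a `cnv_result`, a `cnv_profile` with `cnv_f`, or a named numeric
#'   vector of per-cell levels.
#' @param labels a [group_labels()] covering every scored cell.
#' @return A data.frame with one row per non-empty group: `group`, `n`, `q1`,
#'   `median`, `q3`, `mean`. Empty groups are omitted with a warning.
#' @export
summarize_group_cnv <- function(x, labels) {
  stopifnot(inherits(labels, "group_labels"))
  if (inherits(x, "cnv_result")) x <- x$profile
  if (inherits(x, "cnv_profile")) {
    assert_that(!is.null(x$cnv_f), "cnv_f not computed")
    levels_ <- colMeans(abs(x$cnv_f))
  } else {
    assert_that(is.numeric(x) && !is.null(names(x)),
                "x must be a cnv_result, cnv_profile or named numeric vector")
    levels_ <- x
  }
  unlabeled <- setdiff(names(levels_), names(labels$labels))
  assert_that(length(unlabeled) == 0,
              paste0("scored cells without labels: ",
                     paste(utils::head(unlabeled, 5), collapse = ", ")))
  grp <- labels$labels[names(levels_)]
  empty <- setdiff(labels$group_order, unique(grp))
  if (length(empty) > 0) {
    warning("group(s) with no scored cells omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  groups <- labels$group_order[labels$group_order %in% unique(grp)]
  do.call(rbind, lapply(groups, function(g) {
    v <- levels_[grp == g]
    data.frame(group = g, n = length(v),
               q1 = unname(stats::quantile(v, 0.25)),
               median = unname(stats::median(v)),
               q3 = unname(stats::quantile(v, 0.75)),
               mean = mean(v),
               stringsAsFactors = FALSE)
  }))
}

#' Write CNV pipeline outputs
#'
#' Writes cnv_o/cnv_z/cnv_f as gene x cell TSV tables, per-cell scores, and a
#' JSON parameter manifest under `dir`.
#'
#' @param res a `cnv_result` from [run_cnv()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cnv_result <- function(res, dir) {
  stopifnot(inherits(res, "cnv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in c("cnv_o", "cnv_z", "cnv_f")) {
    df <- data.frame(gene_id = rownames(res$profile[[layer]]),
                     res$profile[[layer]], check.names = FALSE)
    data.table::fwrite(df, file.path(dir, paste0(layer, ".tsv")), sep = "\t")
  }
  data.table::fwrite(res$scores, file.path(dir, "cell_scores.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(res$baselines),
                     file.path(dir, "baselines.tsv"), sep = "\t")
  jsonlite::write_json(res$params, file.path(dir, "cnv_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
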