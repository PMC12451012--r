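#' One-vs-rest Wilcoxon over-expression test
#'
#' Tests each gene for over-expression in the target group against all other
#' cells pooled, with a one-sided (target greater) rank-sum test. Mid-ranks
#' are used for ties. When both group sizes are at most 8 the p-value is
#' computed by exact enumeration of all rank assignments; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Benjamini-Hochberg adjustment is applied across the tested genes.
#'
#' @param m an [expression_matrix()] with layer `"cp10k_log"`.
#' @param labels a [group_labels()] object.
#' @param target_group the group tested for over-expression.
#' @param gene_subset optional character vector restricting the tested genes.
#' @return A data.frame: `gene_id`, `statistic` (Mann-Whitney U of the target
#'   group), `p_value`, `adjusted_p`.
#' @export
wilcoxon_overexpression <- function(m, labels, target_group,
                                    gene_subset = NULL) {
  stopifnot(inherits(m, "expr_matrix"), inherits(labels, "group_labels"))
  assert_that(target_group %in% labels$group_order,
              paste0("unknown target group: ", target_group))
  target_cells <- cells_of_groups(m, labels, target_group)
  rest_cells <- setdiff(
    cells_of_groups(m, labels, setdiff(labels$group_order, target_group)),
    target_cells)
  assert_that(length(target_cells) >= 2 && length(rest_cells) >= 2,
              "target group and its complement must each have >= 2 cells")
  genes <- gene_subset %||% m$gene_ids
  missing <- setdiff(genes, m$gene_ids)
  assert_that(length(missing) == 0,
              paste0("genes absent from matrix: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  x <- m$values[genes, target_cells, drop = FALSE]
  y <- m$values[genes, rest_cells, drop = FALSE]
  res <- t(vapply(seq_along(genes), function(i) {
    rank_sum_greater(x[i, ], y[i, ])
  }, numeric(2)))
  data.frame(gene_id = genes,
             statistic = res[, 1],
             p_value = res[, 2],
             adjusted_p = stats::p.adjust(res[, 2], method = "BH"),
             stringsAsFactors = FALSE)
}

# One-sided (x stochastically greater than y) rank-sum test with mid-ranks.
# Returns c(U, p). Exact enumeration over rank subsets when both sizes <= 8,
# else tie-corrected normal approximation with continuity correction.
#' @keywords internal
#' @noRd
rank_sum_greater <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n <= 8 && m <= 8) {
    sums <- utils::combn(N, n, FUN = function(idx) sum(r[idx]))
    w_obs <- sum(r[seq_len(n)])
    p <- mean(sums >= w_obs - 1e-9)
    return(c(U, p))
  }
  ties <- table(r)
  sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(c(U, 1))
  z <- (U - n * m / 2 - 0.5) / sqrt(sigma2)
  c(U, stats::pnorm(z, lower.tail = FALSE))
}

#' Mean expression of a gene per group
#'
#' Averages the values of `gene` within each group, in `group_order`. The
#' values are averaged as given; callers wanting linear-scale averages of a
#' log-transformed matrix should de-log first (see
#' [rank_specific_ligands()]).
#'
#' @param m an [expression_matrix()].
#' @param labels a [group_labels()] object.
#' @param gene a gene id present in the matrix.
#' @return Named numeric vector of per-group means, in group order.
#' @export
group_mean_expression <- function(m, labels, gene) {
  stopifnot(inherits(m, "expr_matrix"), inherits(labels, "group_labels"))
  assert_that(gene %in% m$gene_ids, paste0("gene not in matrix: ", gene))
  grp <- labels$labels[m$cell_ids]
  v <- m$values[gene, ]
  vapply(stats::setNames(labels$group_order, labels$group_order),
         function(g) mean(v[grp == g]), numeric(1))
}

#' Gini index of per-group mean expression
#'
#' Inequality of a ligand's mean expression across groups:
#' `Gini = sum_i sum_j |x_i - x_j| / (2 n^2 xbar)` for the vector `x` of n
#' group means. 0 indicates perfect equality across groups; values approaching
#' 1 indicate concentration in a single group (a point mass gives
#' `(n - 1) / n`). An all-zero vector returns 0 by convention (no expression
#' supports no specificity claim).
#'
#' @param x non-negative numeric vector of per-group mean expression.
#' @return The Gini index, in `[0, 1]`.
#' @export
gini_index <- function(x) {
  assert_that(is.numeric(x) && length(x) >= 1 && all(is.finite(x)),
              "x must be a finite numeric vector")
  assert_that(all(x >= 0), "negative entry in group means")
  s <- sum(x)
  if (s == 0) return(0)
  n <- length(x)
  xs <- sort(x)
  # closed form of the double sum: sum_i sum_j |x_i - x_j| = 2*(2*sum(i*x_(i)) - (n+1)*sum(x))
  g <- (2 * sum(seq_len(n) * xs) - (n + 1) * s) / (n * s)
  min(max(g, 0), 1)  # clamp float noise at the exact-equality boundary
}

#' Rank group-specific over-expressed ligands
#'
#' Identifies ligands specifically elevated in a target group: one-vs-rest
#' Wilcoxon over-expression tests with BH adjustment, per-group mean
#' expression on the linear cp10k scale, and the [gini_index()] of those group
#' means. The returned table is restricted to ligands with
#' `adjusted_p < p_cutoff`, sorted by Gini index descending; `passes` flags
#' `gini > gini_cutoff`.
#'
#' @param m an [expression_matrix()] with layer `"cp10k_log"`.
#' @param labels a [group_labels()] object.
#' @param target_group the group whose specific ligands are sought.
#' @param ligand_universe character vector of candidate ligand gene ids (its
#'   intersection with the matrix genes must be non-empty).
#' @param gini_cutoff specificity cutoff (default 0.25).
#' @param p_cutoff adjusted-p cutoff (default 0.05).
#' @return A data.frame of class `specificity_table`: `gene_id`,
#'   `target_group`, `p_value`, `adjusted_p`, one `mean_<group>` column per
#'   group (linear cp10k scale), `overall_mean`, `gini`, `passes`. The
#'   attribute `scatter` holds `(gene_id, gini, neg_log10_p)` for every tested
#'   ligand (specificity-vs-difference scatter).
#' @export
rank_specific_ligands <- function(m, labels, target_group, ligand_universe,
                                  gini_cutoff = 0.25, p_cutoff = 0.05) {
  stopifnot(inherits(m, "expr_matrix"), inherits(labels, "group_labels"))
  assert_that(m$layer == "cp10k_log",
              "rank_specific_ligands expects cp10k_log input")
  universe <- intersect(ligand_universe, m$gene_ids)
  assert_that(length(universe) > 0,
              "ligand universe does not intersect the matrix genes")
  wt <- wilcoxon_overexpression(m, labels, target_group,
                                gene_subset = universe)

  lin <- expression_matrix(2^m$values[universe, , drop = FALSE] - 1,
                           layer = "cp10k_log")
  grp <- labels$labels[lin$cell_ids]
  gm <- vapply(stats::setNames(labels$group_order, labels$group_order),
               function(g) rowMeans(lin$values[, grp == g, drop = FALSE]),
               numeric(length(universe)))
  if (length(universe) == 1L) gm <- matrix(gm, nrow = 1,
                                           dimnames = list(universe,
                                                           labels$group_order))
  gini <- apply(gm, 1, gini_index)

  tbl <- data.frame(
    gene_id = universe,
    target_group = target_group,
    p_value = wt$p_value,
    adjusted_p = wt$adjusted_p,
    stringsAsFactors = FALSE)
  gm_df <- as.data.frame(gm)
  names(gm_df) <- paste0("mean_", labels$group_order)
  tbl <- cbind(tbl, gm_df,
               overall_mean = rowMeans(gm),
               gini = gini)
  tbl$passes <- tbl$gini > gini_cutoff

  scatter <- data.frame(gene_id = universe, gini = gini,
                        neg_log10_p = -log10(pmax(wt$p_value, 1e-300)),
                        stringsAsFactors = FALSE)

  out <- tbl[tbl$adjusted_p < p_cutoff, , drop = FALSE]
  out <- out[order(-out$gini), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scatter") <- scatter
  attr(out, "cutoffs") <- list(gini_cutoff = gini_cutoff, p_cutoff = p_cutoff)
  class(out) <- c("specificity_table", "data.frame")
  out
}

#' Specificity-vs-difference scatter of ligand candidates
#'
#' Gini index against -log10 p for every tested ligand, with the cutoff lines.
#' Requires ggplot2.
#'
#' @param tbl a `specificity_table` from [rank_specific_ligands()].
#' @return A ggplot object.
#' @export
plot_specificity_scatter <- function(tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  sc <- attr(tbl, "scatter")
  cut <- attr(tbl, "cutoffs")
  ggplot2::ggplot(sc, ggplot2::aes(x = gini, y = neg_log10_p)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = cut$gini_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Specificity (Gini index)",
                  y = expression(-log[10] ~ "p-value"))
}
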