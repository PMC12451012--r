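#' Score gene signatures per cell
#'
#' The signature score of a cell is the mean, over the signature's genes, of
#' the gene's z-scored normalized expression (z computed across all cells).
#' Genes with zero variance contribute 0; signature genes absent from the
#' matrix are dropped with a warning (a signature with no present genes is an
#' error).
#'
#' @param m an [expression_matrix()] with layer `"cp10k_log"`.
#' @param sigs a `signature_set` (named list of gene-id vectors, see
#'   [read_signatures()]) or a plain named list.
#' @return A numeric matrix, cells x signatures (class
#'   `signature_score_matrix`).
#' @export
score_signature <- function(m, sigs) {
  stopifnot(inherits(m, "expr_matrix"))
  assert_that(m$layer == "cp10k_log", "score_signature expects cp10k_log input")
  assert_that(length(sigs) >= 1 && !is.null(names(sigs)),
              "sigs must be a named list of gene vectors")
  mu <- rowMeans(m$values)
  sdev <- apply(m$values, 1, stats::sd)
  z <- (m$values - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  scores <- vapply(names(sigs), function(nm) {
    genes <- unique(sigs[[nm]])
    present <- intersect(genes, m$gene_ids)
    absent <- setdiff(genes, m$gene_ids)
    if (length(absent) > 0) {
      warning(sprintf("signature '%s': %d gene(s) absent from matrix dropped: %s",
                      nm, length(absent),
                      paste(utils::head(absent, 5), collapse = ", ")),
              call. = FALSE)
    }
    assert_that(length(present) > 0,
                sprintf("signature '%s' has no genes present in the matrix", nm))
    colMeans(z[present, , drop = FALSE])
  }, numeric(length(m$cell_ids)))
  scores <- matrix(scores, nrow = length(m$cell_ids),
                   dimnames = list(m$cell_ids, names(sigs)))
  class(scores) <- c("signature_score_matrix", class(scores))
  scores
}

#' Region-restricted ligand-signature Spearman correlation
#'
#' Spearman correlation (mid-rank ties) between a ligand's normalized
#' expression and each signature score, restricted to the cells of one region
#' (group), or to all labeled cells with `region = "ALL"`. Two-sided p-values
#' come from [stats::cor.test()] (exact for n <= 10 without ties, otherwise
#' the t-approximation). A constant ligand or constant score within the region
#' yields `NA` rho (flagged, not an error).
#'
#' @param m an [expression_matrix()] with layer `"cp10k_log"`.
#' @param scores a signature score matrix from [score_signature()].
#' @param ligand a gene id present in the matrix.
#' @param labels a [group_labels()] object.
#' @param region a group name, or `"ALL"` for all labeled cells.
#' @return A data.frame: `signature`, `region`, `n`, `rho`, `p`.
#' @export
ligand_signature_correlation <- function(m, scores, ligand, labels,
                                         region = "ALL") {
  stopifnot(inherits(m, "expr_matrix"), inherits(labels, "group_labels"))
  assert_that(ligand %in% m$gene_ids, paste0("ligand not in matrix: ", ligand))
  if (identical(region, "ALL")) {
    cells <- cells_of_groups(m, labels, labels$group_order)
  } else {
    assert_that(region %in% labels$group_order,
                paste0("unknown region: ", region))
    cells <- cells_of_groups(m, labels, region)
  }
  assert_that(length(cells) >= 3, "region must contain at least 3 cells")
  cells <- intersect(cells, rownames(scores))
  x <- m$values[ligand, cells]
  out <- lapply(colnames(scores), function(sig) {
    y <- scores[cells, sig]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(signature = sig, region = region, n = length(cells),
                        rho = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      alternative = "two.sided",
                      exact = length(cells) <= 10))
    data.frame(signature = sig, region = region, n = length(cells),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
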