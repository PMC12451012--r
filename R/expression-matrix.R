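#' Construct a gene-by-cell expression matrix
#'
#' The central container of the package: a dense numeric matrix with genes as
#' rows and cells (or spatial spots, treated identically) as columns, plus a
#' layer tag recording whether the values are raw counts or
#' counts-per-10k log2-transformed values.
#'
#' @param values numeric matrix, genes x cells, with unique non-empty
#'   rownames (gene ids) and colnames (cell ids).
#' @param layer `"counts"` (non-negative, finite) or `"cp10k_log"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `cell_ids`, `layer`.
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' em <- expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values, layer = c("counts", "cp10k_log")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  assert_that(!is.null(gene_ids) && !is.null(cell_ids),
              "expression matrix must have gene rownames and cell colnames")
  dup_g <- gene_ids[duplicated(gene_ids)]
  assert_that(length(dup_g) == 0,
              paste0("duplicate gene ids: ", paste(unique(dup_g), collapse = ", ")))
  dup_c <- cell_ids[duplicated(cell_ids)]
  assert_that(length(dup_c) == 0,
              paste0("duplicate cell ids: ", paste(unique(dup_c), collapse = ", ")))
  assert_that(all(is.finite(values)), "expression values must be finite")
  if (layer == "counts") {
    assert_that(all(values >= 0), "counts layer must be non-negative")
  }
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         layer = layer),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer = %s\n",
              length(x$gene_ids), length(x$cell_ids), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Normalize counts to counts-per-10k, log2 scale
#'
#' Each cell's counts are scaled to sum to 10,000 and transformed as
#' `log2(x + 1)`. This is the normalization used by every downstream analysis
#' in the package (relative-expression CNV input, Wilcoxon tests, group means,
#' signature scores).
#'
#' @param m an [expression_matrix()] with layer `"counts"`.
#' @return An `expr_matrix` with layer `"cp10k_log"`.
#' @export
normalize_cp10k_log <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  assert_that(m$layer == "counts", "normalize_cp10k_log expects a counts layer")
  totals <- colSums(m$values)
  zero <- m$cell_ids[totals <= 0]
  assert_that(length(zero) == 0,
              paste0("cells with zero total counts: ",
                     paste(zero, collapse = ", ")))
  scaled <- sweep(m$values, 2, 1e4 / totals, `*`)
  expression_matrix(log2(scaled + 1), layer = "cp10k_log")
}

#' Construct group labels for cells
#'
#' @param labels named character vector: names are cell ids, values group names.
#' @param group_order optional character vector giving the display/reporting
#'   order of groups; defaults to order of first appearance. Every label must
#'   appear in `group_order`.
#' @return An object of class `group_labels` with elements `labels` (named
#'   character vector) and `group_order`.
#' @export
group_labels <- function(labels, group_order = NULL) {
  assert_that(!is.null(names(labels)) && all(nzchar(names(labels))),
              "labels must be a named character vector (names = cell ids)")
  labels <- stats::setNames(as.character(labels), names(labels))
  assert_that(!anyDuplicated(names(labels)), "duplicate cell ids in labels")
  if (is.null(group_order)) group_order <- unique(unname(labels))
  missing <- setdiff(unique(labels), group_order)
  assert_that(length(missing) == 0,
              paste0("labels not in group_order: ", paste(missing, collapse = ", ")))
  structure(list(labels = labels, group_order = group_order),
            class = "group_labels")
}

#' @export
print.group_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$group_order))
  cat("<group_labels>", length(x$labels), "cells in",
      length(x$group_order), "groups\n")
  print(tab)
  invisible(x)
}

# Check that every labeled cell exists in the matrix; return cell ids of a
# group subset in matrix order.
#' @keywords internal
#' @noRd
cells_of_groups <- function(m, labels, groups) {
  stopifnot(inherits(labels, "group_labels"))
  unknown <- setdiff(names(labels$labels), m$cell_ids)
  assert_that(length(unknown) == 0,
              paste0("labeled cells absent from matrix: ",
                     paste(utils::head(unknown, 5), collapse = ", ")))
  ids <- names(labels$labels)[labels$labels %in% groups]
  m$cell_ids[m$cell_ids %in% ids]
}
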