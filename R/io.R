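#' Read an expression matrix
#'
#' Two on-disk layouts are supported:
#' * `mtx_triplet`: a directory in the 10x convention holding `matrix.mtx`
#'   (Matrix Market triplet, genes as rows), `features.tsv` (or `genes.tsv`;
#'   first column gene ids) and `barcodes.tsv` (one cell id per line).
#' * `dense_delim`: a single TAB- or comma-delimited table, first column gene
#'   ids, header row cell ids.
#'
#' @param path directory (`mtx_triplet`) or file (`dense_delim`).
#' @param format `"mtx_triplet"` or `"dense_delim"`.
#' @return An [expression_matrix()] with layer `"counts"`. Implicit zeros of
#'   the sparse format are preserved as zero entries.
#' @export
read_expression <- function(path, format = c("mtx_triplet", "dense_delim")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    read_expression_mtx(path)
  } else {
    read_expression_dense(path)
  }
}

#' @keywords internal
#' @noRd
read_expression_mtx <- function(dir) {
  assert_that(dir.exists(dir), paste0("directory not found: ", dir))
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "genes.tsv")
  barc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, barc)) {
    assert_that(file.exists(f), paste0("missing companion file: ", f))
  }
  sm <- Matrix::readMM(mtx)
  features <- data.table::fread(feat, header = FALSE, sep = "\t",
                                data.table = FALSE)
  barcodes <- data.table::fread(barc, header = FALSE, sep = "\t",
                                data.table = FALSE)
  assert_that(nrow(features) == nrow(sm),
              sprintf("dimension mismatch in %s: %d features for %d matrix rows",
                      dir, nrow(features), nrow(sm)))
  assert_that(nrow(barcodes) == ncol(sm),
              sprintf("dimension mismatch in %s: %d barcodes for %d matrix columns",
                      dir, nrow(barcodes), ncol(sm)))
  sm <- as(sm, "TsparseMatrix")
  neg <- which(sm@x < 0)
  if (length(neg) > 0) {
    stop(sprintf("negative entry in %s at gene row %d, cell column %d",
                 mtx, sm@i[neg[1]] + 1L, sm@j[neg[1]] + 1L), call. = FALSE)
  }
  vals <- as.matrix(sm)
  dimnames(vals) <- list(as.character(features[[1]]),
                         as.character(barcodes[[1]]))
  expression_matrix(vals, layer = "counts")
}

#' @keywords internal
#' @noRd
read_expression_dense <- function(file) {
  assert_that(file.exists(file), paste0("file not found: ", file))
  dt <- data.table::fread(file, header = TRUE, data.table = FALSE)
  assert_that(ncol(dt) >= 2, paste0("no cell columns in ", file))
  gene_ids <- as.character(dt[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  assert_that(length(dup) == 0,
              paste0("duplicated gene id(s) in ", file, ": ",
                     paste(dup, collapse = ", ")))
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (anyNA(vals) || any(vals < 0)) {
    bad <- which(is.na(vals) | vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative or missing entry in %s at gene %s, cell %s",
                 file, gene_ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  rownames(vals) <- gene_ids
  expression_matrix(vals, layer = "counts")
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; round-trips values exactly for counts.
#'
#' @param m an [expression_matrix()].
#' @param path output directory (`mtx_triplet`) or file (`dense_delim`).
#' @param format on-disk layout.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("mtx_triplet", "dense_delim")) {
  stopifnot(inherits(m, "expr_matrix"))
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "features.tsv"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t")
  }
  invisible(path)
}

#' Read a gene-position table
#'
#' Reads a delimited table with columns `gene_id`, `chromosome`, `start`
#' (1-based bp; used only for ordering). Rows are sorted deterministically:
#' chromosomes in natural order (chr1 < chr2 < ... < chr10; unrecognized names
#' after recognized ones, alphabetically), then by `start`, ties broken by
#' `gene_id` lexicographically.
#'
#' @param path file path.
#' @return A `gene_positions` data.frame with columns `gene_id`, `chromosome`,
#'   `start`, sorted as above, with attribute `chromosome_order`.
#' @export
read_gene_positions <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chromosome", "start")
  assert_that(all(need %in% names(dt)),
              paste0("gene position table must have columns: ",
                     paste(need, collapse = ", ")))
  gene_positions(dt$gene_id, dt$chromosome, dt$start)
}

#' Construct a gene-position table
#'
#' @param gene_id,chromosome,start parallel vectors.
#' @return see [read_gene_positions()].
#' @export
gene_positions <- function(gene_id, chromosome, start) {
  gene_id <- as.character(gene_id)
  chromosome <- as.character(chromosome)
  assert_that(!anyNA(suppressWarnings(as.numeric(start))) &&
                all(as.numeric(start) == floor(as.numeric(start))),
              "start must be integer base-pair coordinates")
  start <- as.integer(start)
  assert_that(all(start >= 0), "start must be >= 0")
  dup <- unique(gene_id[duplicated(gene_id)])
  assert_that(length(dup) == 0,
              paste0("duplicate gene_id in positions: ",
                     paste(dup, collapse = ", ")))
  chrom_order <- chromosome_order(chromosome)
  ord <- order(match(chromosome, chrom_order), start, gene_id)
  out <- data.frame(gene_id = gene_id[ord], chromosome = chromosome[ord],
                    start = start[ord], stringsAsFactors = FALSE)
  attr(out, "chromosome_order") <- chrom_order
  class(out) <- c("gene_positions", "data.frame")
  out
}

#' Read a GMT signature file
#'
#' Each line: signature name, description, then one or more gene ids,
#' TAB-separated. Duplicate genes within a signature are dropped (first
#' occurrence kept); signature order follows file order.
#'
#' @param path GMT file.
#' @return A named list of character vectors (class `signature_set`).
#' @export
read_signatures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    genes <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    assert_that(length(fields) >= 3 && length(genes) >= 1,
                sprintf("line %d of %s: signature with empty gene list", k, path))
    assert_that(!(fields[1] %in% names(sigs)),
                sprintf("line %d of %s: duplicate signature name '%s'",
                        k, path, fields[1]))
    sigs[[fields[1]]] <- genes
  }
  structure(sigs, class = c("signature_set", "list"))
}

#' Write a signature set as GMT
#' @param sigs named list of gene-id vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  lines <- vapply(names(sigs), function(nm) {
    paste(c(nm, nm, sigs[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read cell group labels
#'
#' Two-column TAB-separated table: `cell_id`, `group` (header optional when
#' the columns are so named).
#'
#' @param path file path.
#' @param group_order optional explicit group ordering.
#' @return A [group_labels()] object.
#' @export
read_group_labels <- function(path, group_order = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("cell_id", "group") %in% names(dt))) {
    dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
    names(dt)[1:2] <- c("cell_id", "group")
  }
  group_labels(stats::setNames(as.character(dt$group), as.character(dt$cell_id)),
               group_order = group_order)
}

#' Write cell group labels
#' @param labels a [group_labels()] object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_group_labels <- function(labels, path) {
  data.table::fwrite(
    data.frame(cell_id = names(labels$labels), group = unname(labels$labels)),
    path, sep = "\t")
  invisible(path)
}

#' Write a gene-position table
#' @param positions a `gene_positions` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(positions, path) {
  data.table::fwrite(as.data.frame(positions), path, sep = "\t")
  invisible(path)
}
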