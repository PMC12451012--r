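# Shared fixtures and independent oracles for the test suite.

# random counts matrix with dimnames
rand_counts <- function(n_genes, n_cells, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  expression_matrix(m, "counts")
}

# a small, fast simulation: 240 genes on 4 chromosomes, 3 groups
small_config <- function(seed = 1L, n_per_group = 30L, ...) {
  simulation_config(
    n_genes = 240L, genes_per_chromosome = 60L,
    groups = c(normal = n_per_group, PMC_P = n_per_group, T = n_per_group),
    reference_groups = "normal",
    seed = seed, ...)
}

# independent brute-force oracles ------------------------------------------

gini_oracle <- function(x) {
  n <- length(x)
  if (sum(x) == 0) return(0)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

movavg_oracle <- function(v, w) {
  n <- length(v)
  sapply(seq_len(n), function(i) {
    lo <- max(1, i - floor((w - 1) / 2))
    hi <- min(n, i + ceiling((w - 1) / 2))
    mean(v[lo:hi])
  })
}

bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUROC of score separating positives from negatives (rank formula, mid-ranks)
auroc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# one-gene two-group fixture for rank-sum tests
make_two_group <- function(x, y) {
  vals <- matrix(c(x, y), 1, dimnames = list(
    "g", sprintf("c%02d", seq_len(length(x) + length(y)))))
  m <- expression_matrix(vals, "cp10k_log")
  lab <- group_labels(setNames(rep(c("tgt", "rest"), c(length(x), length(y))),
                               colnames(vals)))
  list(m = m, lab = lab)
}

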