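#!/usr/bin/env Rscript
# Quadrant-gated mIHC quantification on a synthetic intensity table: protein
# A-positive cells form the baseline, the B/C plane is split into quadrants
# at per-channel thresholds, and the triple-positive fraction is reported per
# region against the planted truth. Writes results/mihc/.

suppressMessages(library(nichescan))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

sim <- simulate_mihc_intensities(n_cells_per_region = 2500L, seed = seed)
gated <- gate_positive_cells(sim$table, sim$config)
frac <- triple_positive_fraction(gated)
merged <- merge(frac, sim$truth, by = "region")
merged <- merged[order(merged$planted_fraction), ]

dir.create("results/mihc", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(as.data.frame(sim$table), "results/mihc/intensities.csv")
data.table::fwrite(gated, "results/mihc/gated_cells.csv")
data.table::fwrite(merged, "results/mihc/triple_positive_fractions.csv")

cat("triple-positive fractions by region (gated vs planted):\n")
print(merged, row.names = FALSE)
cat(sprintf("\nmax |gated - planted| = %.3f over %d cells\n",
            max(abs(merged$fraction - merged$planted_fraction)),
            sum(merged$n_total)))
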