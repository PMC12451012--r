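#!/usr/bin/env Rscript
# Generate the study dataset: six epithelial groups (normal, GMC_P, IM,
# PMC_P, Pro_T, T) of 200 cells over a 2,000-gene panel on 10 chromosomes,
# with a fold-2 copy-number gain in T, five PMC_P-specific secreted ligands,
# and the PMC_2 signature co-expressed with AREG in PMC_P. Writes the dataset
# and its ground truth under results/dataset/.

suppressMessages(library(nichescan))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

cfg <- default_paper_like_config(seed = seed)
ds <- generate_dataset(cfg)
write_dataset(ds, "results/dataset")
write_signatures(
  setNames(lapply(ds$ground_truth$signature_plants, `[[`, "signature_genes"),
           vapply(ds$ground_truth$signature_plants, `[[`, character(1), "name")),
  "results/dataset/signatures.gmt")
writeLines(cfg$ligand_universe, "results/dataset/ligand_universe.txt")

cat("dataset:", nrow(ds$expression$values), "genes x",
    ncol(ds$expression$values), "cells; seed", seed, "\n")
cat("planted CNV:", ds$ground_truth$cnv_segments$n_genes, "genes, fold",
    ds$ground_truth$cnv_segments$fold, "in group",
    ds$ground_truth$cnv_segments$group, "\n")
cat("planted ligands:",
    paste(ds$ground_truth$specific_ligands$gene_id, collapse = ", "),
    "-> PMC_P\n")
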