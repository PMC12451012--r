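# nichescan

Characterizing a precancerous tissue niche from grouped single-cell or
spatial transcriptomic expression data.

Early gastric cancer arises through spatially ordered epithelial states —
normal mucosa, intestinal metaplasia, a precancerous transition zone next to
the tumor, and tumor. Given a gene × cell (or spot) count matrix and a group
label per cell (e.g. `normal`, `GMC_P`, `IM`, `PMC_P`, `Pro_T`, `T`),
`nichescan` answers four questions that recur in characterizing such a niche:

1. **Copy number from expression.** Genes are floored at mean normalized
   expression 0.2, centered on copy-number-neutral reference cells, clipped
   to [−3, 3], and smoothed in 100-gene windows per chromosome (CNV_o). After
   re-centering on the all-cell average (CNV_z), each window's reference band
   [BaseMin − 0.2, BaseMax + 0.2] — the extrema of the reference cells —
   defines the finalized estimate:

   CNV_f(i,j) = CNV_z − BaseMax if CNV_z > BaseMax + 0.2;
   CNV_z − BaseMin if CNV_z < BaseMin − 0.2; 0 otherwise.

   Per-cell signal (mean of squared CNV_o) and correlation scores, and
   per-group CNV-level summaries, are reported alongside.

2. **Group-specific secreted ligands.** One-sided Wilcoxon rank-sum tests
   (target group vs all others; exact enumeration at small sizes, tie- and
   continuity-corrected normal approximation otherwise; BH adjustment)
   combined with the Gini index of per-group mean expression,

   Gini = Σᵢ Σⱼ |xᵢ − xⱼ| / (2 n² x̄),

   over the n group means x; ligands pass at adjusted p < 0.05 and
   Gini > 0.25.

3. **Region-restricted ligand–signature correlation.** Per-cell signature
   scores (mean of per-gene z-scored expression) and Spearman correlation
   between a ligand and each signature, computed inside one region only.

4. **mIHC quadrant gating.** Per-cell channel intensities are gated at
   user-set thresholds; among protein-A-positive cells the B/C plane splits
   into quadrants, the upper-right quadrant being triple-positive (A+B+C+)
   cells, reported as a fraction of all cells per region.

A seeded negative-binomial simulator (`generate_dataset()`,
`default_paper_like_config()`) plants CNV segments, group-specific ligands
and ligand–signature co-expression with known ground truth, so the whole
pipeline is testable end to end without patient data. See the methods
vignette (`vignettes/niche-characterization.Rmd`) for the model, parameter
and calibration details.

## Worked example

The repository doubles as an analysis workflow: `analysis/01_simulate.R`
through `analysis/05_mihc_gating.R` run the full study on the default
synthetic dataset (six groups × 200 cells, 2,000 genes on 10 chromosomes)
and write their tables under `results/`.

```sh
Rscript analysis/01_simulate.R 1    # seed 1
Rscript analysis/02_cnv.R
Rscript analysis/03_ligand_specificity.R
```

`02_cnv.R` prints the per-group CNV levels and the recovery of the planted
fold-2, 50-gene gain carried by group `T`:

```
per-group CNV level (mean |CNV_f|):
  group   n q1       median          q3         mean
 normal 200  0 0.0000000000 0.000000000 0.000000e+00
  GMC_P 200  0 0.0000000000 0.000000000 5.271389e-06
     IM 200  0 0.0000000000 0.000000000 2.630651e-06
  PMC_P 200  0 0.0000000000 0.000000000 3.680090e-06
  Pro_T 200  0 0.0000000000 0.000000000 0.000000e+00
      T 200  0 0.0009073559 0.005015687 2.974967e-03

planted segment recovery: AUROC 0.998 over 1986 windows
reference cells with CNV_f exactly 0: 100.0%
```

Only the carrier group `T` shows a non-zero CNV level; ranking genes by the
carrier group's mean CNV_f separates the 50 planted genes from the other
1,936 almost perfectly (AUROC 0.998), and every reference cell finalizes to
exactly zero, as the baseline construction guarantees.

`03_ligand_specificity.R` recovers exactly the five planted PMC_P ligands
from a 105-candidate universe:

```
ligands passing (adjusted p < 0.05, Gini > 0.25):
 gene_id       p_value   adjusted_p      gini
    AREG  1.123252e-83 2.358829e-82 0.4650364
   NAMPT 6.612167e-100 6.942775e-98 0.4153083
    IL1B  1.599295e-98 8.396299e-97 0.3934617
    KLK7  1.499772e-93 5.249204e-92 0.3627491
  IGFBP3  4.802265e-90 1.260594e-88 0.3340253

5 of 105 candidates called specific to PMC_P
```

`04_signature_correlation.R` then finds the planted AREG–PMC_2-signature
association only inside the target region (Spearman rho 0.654 in `PMC_P` at
a planted strength of 0.6, versus −0.06 across all cells), and
`05_mihc_gating.R` recovers planted triple-positive fractions per region to
within 0.004 on 10,000 synthetic cells.

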