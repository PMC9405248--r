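# isomiRtand

Serum small-RNA biomarker discovery for neuropsychiatric outcome groups
in infant TSC (tuberous sclerosis complex) cohorts: isomiR variant-space
quantification, differential expression, reference-gene-ratio ROC
screening, permutation robustness testing, and LASSO panel selection —
with a synthetic-cohort generator that makes the whole pipeline testable
when patient sera are unavailable.

## The problem

Infants with TSC are at high risk of developing TSC-associated
neuropsychiatric disorders (TAND): intellectual disability (ID), autism
spectrum disorder (ASD), or both.  Circulating miRNAs — and their
sequence variants, isomiRs — are candidate non-invasive biomarkers for
early risk assessment.  The analysis problem is: given small-RNA
sequencing of serum from a cohort stratified as Control / ID / ASD /
ASD+ID, find single features and small panels whose expression ratios
discriminate the outcome groups, and quantify how surprising each
classifier is under a permutation null.

## The method

1. **isomiR reference.**  For each canonical mature miRNA of length *L*,
   enumerate `2*(4+16+64) + (L-18) + 1` variants: the canonical, all
   non-templated 5'- and 3'-extensions of 1–3 bases, and all 3'-trims
   down to 18 nt, named `<id>_miRNA`, `<id>_G_5prime`, `<id>_AT_3prime`,
   `<id>_trim3`.
2. **Quantification.**  Reads are quality-trimmed (leading/trailing
   floor, sliding window of 4 at phred 15, minimum 17 nt), adapter-
   stripped, and assigned by exact sequence equality; collisions resolve
   deterministically to the least-modified identifier.  Collapsing
   variants per canonical miRNA gives the miRNA-level matrix.
3. **Differential expression.**  Median-of-ratios normalisation, per-
   feature negative-binomial Wald tests (pooled method-of-moments
   dispersion, t reference), Benjamini–Hochberg control at
   `padj < 0.05`.
4. **ROC screen.**  Per comparison, a stable reference feature
   (coefficient of variation < 0.3) normalises every feature into a
   ratio; each ratio is scored by folded AUC (= Mann–Whitney
   `U/(n1*n2)`) with a Youden-optimal operating point, a per-feature
   permutation p, and a selection-aware permutation p for the top
   classifier (null of the maximum AUC).
5. **Panels.**  L1-penalised logistic regression over log2 ratios
   (coordinate descent, KKT-verified), lambda by stratified CV, and an
   unpenalised refit of the selected signature scored by panel AUC.

Five comparisons are registered: Control-vs-ID, Control-vs-ASD,
Control-vs-ASD+ID, ID-vs-ASD+ID, ASD-vs-ASD+ID.

## Worked example

```r
library(isomiRtand)

# a synthetic cohort at the study's group sizes (30/10/6/13) with one
# planted Control-vs-ID marker
cfg <- cohort_config(
  n_features = 50, baseline_mean = 100, dispersion = 0.1, seed = 42,
  planted_effects = data.frame(feature_id = "syn-miR-0001",
                               comparison = "Control-vs-ID", log2fc = 3))
sim <- simulate_counts(cfg)

de <- run_de(sim$counts, sim$samples, "Control-vs-ID")
head(de$table[, c("feature_id", "log2FoldChange", "pvalue", "padj")], 3)
#>     feature_id log2FoldChange       pvalue         padj
#> 1 syn-miR-0001      2.9898155 2.890690e-18 1.445345e-16
#> 2 syn-miR-0035     -0.5914770 1.174136e-04 2.935339e-03
#> 3 syn-miR-0029     -0.4499365 7.885246e-03 1.314208e-01

scr <- run_roc_screen(sim$counts, sim$samples, "Control-vs-ID",
                      B = 999, seed = 1)
scr$table[1, c("feature_id", "auc", "sensitivity", "specificity", "perm_p")]
#>     feature_id auc sensitivity specificity perm_p
#> 1 syn-miR-0001   1           1           1  0.001
```

The planted marker is recovered with an estimated log2 fold change of
2.99 (truth: 3, direction "over", `padj = 1.4e-16`) and tops the
classifier table with folded AUC 1.0 at a Youden threshold with 100%
sensitivity and 100% specificity; its permutation p is the estimator
floor `1/(B+1)`.
`fit_panel()` on a comparison with split signal returns the selected
signature, its coefficients, and both in-sample and cross-validated
panel AUCs.

(The numbers above are from this exact script; rerunning it reproduces
them byte for byte.)

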