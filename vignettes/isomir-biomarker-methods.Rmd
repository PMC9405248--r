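---
title: "Methods: isomiR quantification and serum biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR quantification and serum biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`isomiRtand` implements a small-RNA biomarker-discovery pipeline for serum
cohorts stratified by neuropsychiatric outcome — Control, intellectual
disability (ID), autism spectrum disorder (ASD), and ASD+ID, the four
outcome groups of tuberous-sclerosis (TSC) infant cohorts.  The pipeline
covers: isomiR variant-space construction and exact-match quantification
from reads, differential expression, reference-gene-ratio ROC screening
with permutation robustness testing, and LASSO panel selection.  Because
patient sera are rarely shareable, a synthetic-cohort generator is a
first-class component: it produces data with the statistical structure the
downstream stages assume, plus a ground-truth ledger, so every stage can
be validated end to end.

# The isomiR variant space

A canonical mature miRNA of length $L$ (18–25 nt) induces a variant
family:

* the canonical sequence itself (`<id>_miRNA`);
* all $4 + 16 + 64 = 84$ non-templated 5'-extensions of 1–3 bases
  (`<id>_G_5prime`);
* the 84 corresponding 3'-extensions (`<id>_AT_3prime`);
* 3'-trims of $1 \ldots (L - 18)$ bases, never below 18 nt
  (`<id>_trim3`).

The family size is therefore $2 \cdot 84 + (L - 18) + 1$, i.e. 173 for a
22-nt canonical.  Extensions are pure enumeration over the DNA alphabet,
not genome-templated: this matches the construction of a combinatorial
custom reference and avoids any genome dependency.  5'-trimming and
combined trim+extension variants are deliberately not generated; the
variant classes are a disjoint union.  All sequence handling is in
upper-case DNA space (RNA input is transliterated U→T), because that is
what a sequencer emits.

Distinct identifiers can collide on the same sequence (e.g. one miRNA's
canonical sequence equals another's 1-nt 3'-extension).  `build_reference()`
reports every collision and resolves each sequence to a single winner by a
deterministic tie-break — canonical > trim3 > ext3 > ext5, then
lexicographic identifier — i.e. the least-modified explanation of a read.
This rule is a declared convention: under exact-match-only alignment,
"best alignment" degenerates to a tie among identical sequences and any
upstream aligner's behaviour would be equally conventional.

# Read QC and quantification

Reads are quality-trimmed in the classic small-RNA recipe: leading and
trailing bases below phred 3 are removed (the floor is configurable; the
recipe's published parameters state the step but not the floor), then a
sliding window of 4 bases cuts the read just before the first window whose
mean quality drops below phred 15.  The 3' adapter (TruSeq small-RNA by
default) is stripped at the leftmost exact occurrence of an adapter prefix
with at least 8 nt of overlap.  Anything shorter than 17 nt is discarded.
Assignment to the reference is exact sequence equality — no mismatches, no
substring matching — so adapter stripping is solely responsible for insert
recovery.  Counts are tabulated per variant; collapsing all variants of a
canonical miRNA yields the miRNA-level matrix, and the collapse conserves
totals exactly.

# Differential expression

The DE stage is self-contained (it does not wrap an external DE package,
which also makes its behaviour exactly reproducible from this document):

* **Expression filter**: a feature is kept if it has ≥ 1 read in at least
  one sample of the comparison.
* **Normalisation**: median-of-ratios size factors.  For sparse serum-like
  matrices with no all-nonzero feature, the `poscounts` variant (geometric
  mean over positive counts) is used by the pipeline wrappers; the classic
  estimator is the default of `size_factors()` and fails with guidance.
* **Test**: per feature, group means of normalised counts; a common NB
  dispersion $\alpha$ (variance $\mu + \alpha\mu^2$) estimated by pooled
  method of moments (floored at $10^{-8}$, no empirical-Bayes shrinkage);
  Wald statistic = log2 fold change / delta-method SE.
* **Reference distribution**: the statistic is referred to
  $t_{n_A + n_B - 2}$, not the standard normal.  With per-feature
  moment dispersions the normal reference is well calibrated in the bulk
  but anticonservative in the far tail — exactly where BH at
  $p_{adj} < 0.05$ over thousands of features reads.  In calibration runs
  (200 null cohorts at the study's 30-vs-10 sizes, 2000 features) the
  normal reference produced a family-wise error of ~0.4, the t reference
  0.035, while bulk uniformity (KS) and power (≥ 0.9 for |log2FC| = 2 at
  baseline 100, dispersion 0.1) are unchanged.  The t reference is the
  standard finite-sample absorption of variance-estimation noise.
* **Multiplicity**: Benjamini–Hochberg step-up; NAs (features with a zero
  group mean) are excluded from the denominator.  Significance is
  $p_{adj} < 0.05$.

Covariates are not modelled; the contrasts are plain two-group
comparisons, and five are registered: Control-vs-ID, Control-vs-ASD,
Control-vs-ASD+ID, ID-vs-ASD+ID, ASD-vs-ASD+ID (second group = positive
class).

# Ratio features and ROC screening

For each comparison a stably expressed reference feature is selected among
the comparison's samples: coefficient of variation of normalised
expression below 0.3.  "Coefficient of variation" is our reading of a
stability rule quoted as a "covariance" threshold — covariance proper is
not a unitless per-gene statistic, and CV thresholds are standard
reference-gene practice.  Among qualifiers, the minimal CV wins, preferring
features above the cohort's median expression (a low-CV, well-expressed
reference), with identifier order as the final tie-break.  An established
reference (e.g. a qPCR reference gene) can be supplied as an override.

Every feature is divided by the reference, with pseudocount 1 on both
numerator and denominator to guard serum-typical zeros.  Each ratio is a
single-feature classifier scored by ROC/AUC (midrank Mann–Whitney; the
direction is folded so AUC ≥ 0.5 and recorded).  The operating point
maximises Youden's $J$ = sensitivity + specificity − 1, ties broken toward
sensitivity.  The top-k table (default 10) sorts by folded AUC,
sensitivity, specificity, then identifier.

Robustness is assessed by label permutation preserving group sizes, with
the finite-sample estimator $p = (1 + \#\{AUC_{perm} \ge AUC_{obs}\}) /
(B + 1)$ (default $B = 999$ for smoke runs; the full 30,000 is a single
argument).  Because screening many features and permutation-testing only
the winner is anti-conservative, the pipeline additionally reports a
selection-aware $p$: the permutation null of the *maximum* folded AUC over
all features, which is calibrated under the global null (rejection rate
0.042 at nominal 0.05 in 500 replicates).

# LASSO panels

Panels are selected by $\ell_1$-penalised logistic regression on the log2
ratio features (logging stabilises heavily skewed ratios):
$\min_{\beta_0,\beta} -\ell(\beta_0, \beta)/n + \lambda \|\beta\|_1$,
solved by IRLS with cyclic coordinate descent; the intercept is
unpenalised, columns are standardised internally, and every returned fit
satisfies the KKT conditions to $10^{-8}$ (checked; the solver refuses to
return otherwise).  At $\lambda \ge \lambda_{max} = \max_j |x_j^\top (y -
\bar y)| / n$ the exact null model is returned; at $\lambda = 0$ the fit
matches an unpenalised Newton–Raphson solution.

$\lambda$ is chosen by stratified K-fold cross-validation (default 5
folds, standardisation computed inside each training fold, warm-started
paths on a 30-point log grid down to $0.05\,\lambda_{max}$).  Both the
deviance minimiser `lambda_min` and the sparser `lambda_1se` are
returned; the SE uses the per-observation held-out deviance convention of
the reference implementation.  The two rules serve different goals and
both are exposed:

* `lambda_1se` is selection-consistent in practice: on pure-noise
  cohorts it returns the empty model ~97% of the time (matching the
  reference implementation's behaviour; the deviance minimiser keeps
  noise features in roughly a third of null datasets — a documented
  property of CV-minimising LASSO, not an implementation defect).
* `lambda_min` is prediction-oriented and is the default of
  `fit_panel()`: with signal genuinely split across features it selects
  the complementary markers and the refit panel beats the best single
  marker in ~91% of simulated cohorts.

The selected signature is refitted by unpenalised logistic regression; the
per-sample linear predictor is the panel score and its ROC/AUC the panel
performance.  Perfect separation falls back to a ridge-stabilised fit
($\lambda_{ridge} = 10^{-6}$) with a warning.  The in-sample panel AUC is
reported (as panel figures in this literature usually are) alongside a
clearly-labelled cross-validated AUC of the fixed signature.  At isomiR
resolution the candidate set is capped (default 200) by a label-blind
variance prefilter so the coordinate descent stays at interactive scale.

# The synthetic cohort generator

`cohort_config()` defaults encode the study conditions the pipeline
targets: group sizes Control 30 / ID 10 / ASD 6 / ASD+ID 13; negative
binomial counts with mean `baseline_mean` × per-sample depth factor
(log-normal, sd 0.25) × $2^{\log_2 FC}$ for planted effects, and variance
$\mu + \alpha\mu^2$ with $\alpha$ = 0.1 by default (a typical bulk
small-RNA dispersion); per-feature baselines are jittered log-normally
(sd 0.5) around `baseline_mean` = 100 so the panel spans a realistic
abundance range.  Planted effects name a feature, a comparison, and a
log2 fold change applied to the comparison's positive group; the truth
ledger records them for recovery tests.

Read-level simulation splits each miRNA count multinomially over its
variant family (70% canonical, 15% 3'-extension, 10% 3'-trim, 5%
5'-extension by default — 3'-modifications dominate observed isomiR
distributions), then writes each count as that many reads: insert +
TruSeq small-RNA 3' adapter + random padding to 151 nt, with phred33
qualities drawn per base from a clamped normal (mean 35, sd 3).  Only one
mate is simulated and consumed: small-RNA inserts (≤ 28 nt) are fully
contained in a single 151-nt read, so the second mate is redundant for
insert recovery.  Default depth targets are desk-scale (~10^5
reads/sample), far below a production run's ~12 M; no sequencing-error
model, UMIs, or batch structure are simulated.  Consequently, passing
round-trip tests demonstrate the *bookkeeping* correctness of
quantification (trimming, adapter handling, exact matching, counting,
collapsing), not robustness to sequencing error or alignment ambiguity
beyond enumerated collisions; and planted-effect recovery demonstrates
statistical calibration under the NB model, not under real serum
technical variation.

# Numerical choices and problem sizes

* Determinism: every stage takes a seed; the orchestrator derives named
  substream seeds from one root so a run is replayable stage by stage,
  and repeated runs produce byte-identical summary JSON.
* Coordinate-descent coefficients below $10^{-10}$ are zeroed on return;
  boundary updates at $\lambda = \lambda_{max}$ otherwise leave float
  dust that would masquerade as selections.
* Validation simulations in the test suite use: 200 null cohorts × 2000
  features for FDR calibration; 500 null replicates at $B = 999$ for
  permutation calibration; 100 cohorts each for marker recovery and
  panel gain; ~10^6 simulated reads for the quantification round trip.
  These sizes were chosen to keep the full suite at interactive scale
  while leaving the binomial noise of each estimated rate well inside
  the asserted bands.

# Known limitations

* Exact-match quantification cannot count reads carrying sequencing
  errors; with real data the unassigned fraction is informative and is
  reported per sample in the QC summary.
* The DE stage has no dispersion shrinkage, no independent filtering and
  no fold-change moderation; it is slightly under-powered relative to
  empirical-Bayes implementations at very small n.
* In-sample AUCs (single-marker and panel) are optimistic; the
  selection-aware permutation p and the cross-validated panel AUC are
  the honest companions, and both are computed by default.
* The generator does not emulate batch effects, hemolysis signatures, or
  compositional artefacts of serum RNA; conclusions about those require
  real cohorts.
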