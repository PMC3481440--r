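---
title: "Methods: confounder-reduced survival clustering of multi-omics cohorts"
author: "chemoclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confounder-reduced survival clustering of multi-omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoclust)
```

This vignette is the package's account of its statistical machinery: the
model assumptions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic cohorts do and do not
emulate, and the numerical conventions (boundaries, tie-breaks, degenerate
inputs) that make runs reproducible.

## The estimation problem

Given feature-by-sample matrices of log2 gene expression, gene-level
copy-number log2 ratios and CpG methylation beta values, plus clinical
records (age, stage, processing batch, treatment history, follow-up), the
pipeline estimates a binary molecular classification of tumors — poor
prognosis (PPT) versus good prognosis (GPT) under one fixed chemotherapy
regimen — together with the feature set that defines it and a held-out
validation of the split. Progression-free survival (PFS, days from
surgical resection to progression/recurrence/death, right-censored at last
follow-up) is the supervising outcome; the clustering is *semi-supervised*
because survival drives feature selection and scoring while the final
grouping is unsupervised hierarchical clustering on the discretized
profiles.

Two nuisance structures are handled explicitly. *Confounding*: batch, age
and stage can correlate with both molecular features and outcome; batch is
removed by location/scale adjustment, age and stage by hypothesis-test
filters on every candidate feature. *Suppression*: pooling patients on
heterogeneous regimens dilutes subtype signal; the eligibility rules
restrict the training cohort to one regimen and quarantine samples with
additional drugs into a testing cohort used only for validation.

## Batch correction

Per feature $i$ and batch $j$, expression values are adjusted as
$g^*_{ijk} = M_i + (g_{ijk} - M_{ij})\,\hat\sigma_i/\hat\sigma_{ij}$, with
$M$ medians and $\hat\sigma$ either the sample SD (default) or the MAD
with consistency constant 1.4826, so the two estimators coincide in
expectation on normal data. The adjustment assumes batches are randomly
composed (no batch-outcome association), which the generator enforces and
real analyses must check. All statistics use observed entries only;
adjusted missing entries stay missing.

Beta values are bounded in $[0,1]$ and mildly bimodal, so a linear L/S map
would leave the range. Instead each feature/batch gets the piecewise-linear
map $b \mapsto b\,M'_i/M'_{ij}$ for $b \le M'_{ij}$ and
$b \mapsto M'_i + (b - M'_{ij})(1-M'_i)/(1-M'_{ij})$ above, which fixes 0
and 1, is non-decreasing, and sends the batch median exactly onto the
pooled median.

Numerical conventions: the median of an even count is the mean of the two
central order statistics; consequently the *adjusted batch median* equals
the pooled median exactly for expression (the map is affine) and for
methylation whenever the within-batch observed count is odd — for even
counts the piecewise map can leave a small discrepancy because the two
central values may straddle the knot. Degenerate cases: a batch with zero
(or undefined) within-batch scale for a feature is set to the pooled
median and flagged; single-sample batches pass through unadjusted with a
warning; batch medians of exactly 0 or 1 disable the corresponding branch
and are flagged. Batches under 25 samples trigger a warning because L/S
estimates get noisy there. Applying the expression correction twice is
idempotent up to the re-estimated pooled scale (second-pass changes are a
few percent of one SD; the test suite bounds them at 0.12 log2 units on a
50×40 matrix). Copy-number ratios are never corrected: the comparative
hybridization against normal DNA on the same array already cancels
batch-level intensity effects, and the pipeline asserts this by refusing
copy-number input to the correction functions.

## Sample selection

Eligibility (defaults in `selection_rules()`): stage III or IV; each
required drug (paclitaxel, carboplatin) started within 30 days of surgery
and given for at least 4 recorded cycles. The 30-day/4-cycle rule is
applied *per drug* — the stricter, reproducible reading of a jointly
phrased rule. Cycles come from the clinical record; no inference from
dates. Training = eligible samples with no other drug started strictly
before the failure/censoring day; testing = the remaining eligible
samples. Relaxing the delay or cycle thresholds can only grow the eligible
set (tested as a monotonicity property). Filter order (stage first, then
drugs) only affects exclusion-reason bookkeeping, not the final sets.

## Feature selection

Copy-number status: gain strictly above 0.4, loss strictly below −0.5
(log2 ratio), normal in the closed interval between. Methylation status:
per-feature empirical quantiles (R's default linear-interpolation type 7)
of the batch-corrected beta values, hyper strictly above the 0.75
quantile, hypo strictly below the 0.25 quantile. Quantiles are
*per-feature* rather than global — a global beta cutoff would make
"hypermethylated" vacuous for bimodal CpGs — and the numeric cutoffs are
stored so held-out samples are categorized with the training criterion.

The scan runs a two-group log-rank test per feature and contrast (gain vs
normal, loss vs normal; hyper vs all-non-hyper, hypo vs all-non-hypo),
gated on both groups holding at least $\max(\lceil 0.15\,n\rceil, 13)$
samples — the two printed readings of the rule coincide at $n = 85$ — and
keeps contrasts with $p < 0.05$. No multiple-testing correction is applied
anywhere in the scans; this mirrors the procedure's design and is a
documented limitation, with the type-I level of the scan verified on null
cohorts (per-contrast rejection rate ≈ 0.05; note the per-feature union of
two contrasts is ~2α by construction).

Refinement. Copy number: a candidate is dropped when the two *tested*
groups differ in age (Wilcoxon rank-sum $p < 0.05$) or in stage III/IV
composition (Fisher exact $p < 0.05$). Methylation: dropped when
$|\rho_{\text{Spearman}}(\beta, \text{age})| > 0.5$ (absolute value, since
hypomethylation may correlate negatively with age) or when beta differs
between stage III and IV samples (Wilcoxon $p < 0.05$), both computed over
the tested samples. Finally the concordance filter keeps features whose
two groups differ in mean log2 expression of the mapped gene by at least
$\log_2 1.3$ — equivalent to a 1.3× ratio of geometric means — with the
boundary inclusive (a 1e-12 tolerance absorbs float error); methylation
features without a mapped gene in the expression matrix are dropped and
reported.

## F-scores, clustering, integration

Each surviving feature maps samples to a ternary F-score: members of the
longer-survival status group (by the log-rank observed-vs-expected event
comparison) get +1, the shorter-survival group −1, and the untested status
(loss under a gain-vs-normal feature, and vice versa) or missing values 0.
For methylation every non-missing sample belongs to one of the two tested
groups, so only missingness yields 0. A feature selected under both of its
contrasts is scored by the smaller-p contrast. The survival *direction* is
defined by observed < expected events — the quantity the log-rank
statistic itself compares — because the scoring needs an orientation the
test p-value does not carry. A printed piecewise definition of the
gain-contrast score in the source material is typographically garbled; the
implementation follows the symmetric logic of the loss-contrast definition
and the surrounding prose, as documented here.

Samples are clustered on
$d_{kk'} = \#(F_k \ne F_{k'}) / \#[(F_k \ne 0) \vee (F_{k'} \ne 0)]$,
with $d = 1$ (flagged) for pairs sharing no informative feature, using
complete-linkage agglomeration implemented in-package: ternary profiles
produce heavily tied distances, so merges at equal heights are resolved
deterministically toward the pair with lexicographically smallest original
member indices (the tie behaviour of `stats::hclust` is unspecified;
`hclust` serves as a cross-check oracle on tie-free inputs). The tree is
cut into exactly two clusters (a largest-gap cut is available but off by
default); the cluster with the lower mean F-score is the PPT set, with
ties broken toward the smaller cluster. The classification is flagged
"proposed" only when the PPT-vs-GPT log-rank $p < 0.05$. The final PPT set
is the union of the copy-number and methylation PPT clusters; everything
else is GPT.

## Weighted-KNN validation

Held-out samples are discretized with the training features, directions
and numeric cutoffs (training beta quantiles by default — reusing test
quantiles would leak information; a flag enables the recompute variant for
sensitivity analysis). The discriminant for test sample $f$ is
$P_f = \sum_{h=1}^{K} (1/d_{fh})\,l_h \big/ \sum_{h=1}^{K} 1/d_{fh}$ with
$d_{fh} = \max[\#(F_f \ne F_h), 1] / \#[(F_f \ne 0) \vee (F_h \ne 0)]$;
the max() keeps weights finite for identical profiles. $K = 3$ by
default; neighbor ties at equal distance are broken by training sample id
order. $P_f > 0$ is called good, otherwise poor — the boundary $P_f = 0$
is poor. $P_f$ is always a convex combination of ±1 labels.

## Differential expression

Per gene, a two-sided Welch t-test (the group sizes are unequal by
construction; a pooled-variance flag exists for sensitivity runs) on log2
values and the linear fold change $2^{\bar g_A - \bar g_B}$; a gene passes
at fold change ≥ 1.5 (boundary inclusive) and $p < 0.01$. The two
comparisons — CN-PPT vs GPT and methylation-PPT vs GPT — are run
separately and never pooled. Genes missing in more than half of either
group are excluded and counted. No FDR correction by default (an optional
BH column is available), matching the raw-threshold design.

## The synthetic cohort generator

`sim_config()` defaults are the generator's fixed study conditions, chosen
once to mirror the cohort shape the procedure targets at desk scale:

* 200 samples in 13 batches, 2,000 genes, 1,000 CpGs; the eligibility
  rules carve out ≈ 85 training and ≈ 83 testing samples (the generator
  assigns treatment-history roles stratified by subtype so these shares
  are stable across seeds).
* Truth subtypes partition the cohort: 21% copy-number-driven PPTs, 26%
  methylation-driven PPTs (the published cluster sizes of the motivating
  cohort mapped onto a forced partition), remainder GPT.
* A 40-gene contiguous segment on chromosome 1 amplified in cn-PPT samples
  (gain mean 0.8 log2 ratio, measurement SD 0.2) with a concordant
  log2(1.8) expression shift; 40 CpGs hypomethylated by 0.3 beta units in
  meth-PPT samples, mapped to genes carrying the same expression shift so
  the concordance filter is satisfiable; beta noise SD 0.08, expression
  noise SD 0.35.
* Survival: proportional-hazards Weibull (shape 1 = exponential by
  default; the survival law of the motivating study is unstated, so the
  shape is exposed), baseline median PFS 396 days, hazard ratio 3 for
  either PPT subtype, independent uniform administrative censoring over a
  window solved at config time to yield ≈ 17% censoring at the baseline
  hazard. Age does not drive hazard by default: age/stage confounding is
  injected only on designated decoy features (10 copy-number features
  whose gains concentrate in the oldest quartile, 10 CpGs tracking age) so
  the refinement filters have true positives to remove.
* Batch effects: per-batch expression location shifts (SD 0.3 log2) and
  scale factors (0.8–1.25), per-batch beta median shifts (±0.04), all
  removed by the correction stage; 2% missing entries in expression and
  copy number. Beta values are clipped to [0,1] after shifts (they are
  proportions).

With a `null_config()` — hazard ratio 1 and all effect sizes zero — the
truth labels still exist but every marginal feature distribution is
exchangeable across subtypes, giving the pipeline's negative control.

What the generator does *not* emulate: probe-level microarray signal,
genome-scale correlation structure (LD, co-amplification beyond the one
planted segment), platform-specific missingness mechanisms, informative
censoring, or treatment-by-subtype interactions. Passing tests therefore
demonstrate the procedure's statistical behaviour under its own
assumptions, not performance on any real cohort.

## Power structure of the planted design, and a known red property

Two recovery properties are tracked at the default conditions. The
*sample-level* property — at hazard ratio 3, ≥ 80% of true PPT samples
land in the training PPT union and the held-out classification separates
survival at $p < 0.05$, in ≥ 80% of 50 seeds — holds: even a handful of
selected planted features suffices, because the gain/hypomethylation
patterns themselves separate the subtypes cleanly in the Jaccard geometry.

The *feature-level* property (≥ 80% of planted features through the full
funnel, both modalities) does not hold at this cohort size, and the
corresponding test is intentionally left failing. The cause is structural:
with the subtypes forming a partition and both carrying hazard ratio 3,
each scan's reference group (e.g. "normal copy number") contains the
*other* poor-prognosis subtype, diluting the survival contrast from 3 to
roughly 1.7–2.0; at 85 training samples the per-feature log-rank is then
underpowered, and because one seed's survival realization is shared by all
its planted features, the scan passes or fails them in blocks (measured
aggregates ≈ 0.68 for copy number, ≈ 0.74 for methylation over 50 seeds).
No measurement-noise or effect-size knob changes this — the dilution lives
in the survival draw — and raising the cohort size would leave the stated
desk-scale conditions. The discrepancy is documented rather than papered
over by weakened thresholds.

## Problem sizes and numerical tolerances used by the test suite

Batch-median alignment is asserted to 1e-9 on a randomized 500×200 matrix
in 8 batches of 25 (odd within-batch counts, where the methylation map's
median identity is exact). Oracle comparisons: the log-rank asymptotic p
against a 70-split exhaustive permutation null at n = 8 (within 0.02);
Fisher against hypergeometric enumeration (1e-7); exact Wilcoxon against
full enumeration at n ≤ 8 (1e-9). Type-I control uses 1,000 null
replicates per primitive (accepted band 0.03–0.07); the null scan uses 8
seeds × 600 CpGs at n = 85; the planted battery uses 50 seeds at the
default cohort size. These sizes are the package's own reproducibility
choices and are restated in `scripts/acceptance.R`, which recomputes all
headline quantities from scratch.

## Known limitations

Raw p-value thresholds throughout (by design, documented above); exactly
two clusters per modality; no Cox modelling, stratified log-rank or
confidence bands; gene-level copy number only (no segmentation); the
weighted-KNN validation justifies the split but is not a calibrated
classifier. Gene-ontology enrichment of the DE lists is out of scope — the
ranked gene table exports to any external enrichment tool.
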