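# chemoclust

Semi-supervised survival clustering of multi-omics chemotherapy-response
cohorts, with explicit reduction of confounding (processing batch, patient
age, tumor stage) and suppression (mixed treatment) effects.

## The problem and who this is for

Large tumor collections profiled on several platforms — log2 gene
expression, copy-number log2 ratios, CpG methylation beta values — invite
survival analyses of chemotherapy response, but naive analyses are
undermined twice over: measurements shift by processing batch, and pooling
patients on heterogeneous drug regimens masks subtype-specific signal.
`chemoclust` implements an integrated procedure for deriving molecular
classifications of poor- versus good-prognosis tumors (PPT / GPT) under a
single first-line regimen (paclitaxel + carboplatin by default), for
biostatisticians working with cohorts of this shape and for methodologists
who want a fully simulated, ground-truthed test bed.

## The procedure

1. **Batch correction.** Location/scale adjustment per feature and batch:
   `g* = M_i + (g − M_ij)·σ̂_i/σ̂_ij` for log2 expression (SD or MAD scale
   estimator); a bounded piecewise-linear rescaling for beta values that
   fixes 0 and 1 and maps each batch median onto the pooled median
   (`b·M′_i/M′_ij` below the batch median, affine onto `(M′_i, 1]` above).
   Copy-number ratios are measured against co-hybridized normal DNA and are
   never corrected.
2. **Sample selection.** PFS = days from surgical resection to progression,
   recurrence or death (censored at last follow-up). Eligible samples are
   stage III/IV with both required drugs started within 30 days of surgery
   and given for ≥ 4 cycles; samples never given any other drug before the
   failure event form the *training* cohort, eligible samples with extra
   drugs are held out for *testing*.
3. **Feature selection.** Copy-number status (gain > 0.4, loss < −0.5) and
   per-feature methylation quantile status (hyper > q0.75, hypo < q0.25)
   are scanned feature-by-feature with a two-group log-rank test (gain vs
   normal, loss vs normal; hyper vs rest, hypo vs rest), requiring both
   groups ≥ max(⌈0.15 n⌉, 13) and p < 0.05; candidates confounded with age
   (Wilcoxon, or |Spearman| > 0.5 for beta values) or stage (Fisher exact,
   or stage-wise Wilcoxon) are removed, and survivors must show a
   concordant ≥ 1.3× expression fold change.
4. **F-score discretization and clustering.** Each selected feature maps
   samples to {+1 favorable, 0 unknown, −1 unfavorable} via the log-rank
   survival direction; samples are clustered by the mismatch/informative
   Jaccard distance with complete linkage, cut into two clusters, and the
   unfavorable-enriched cluster is the PPT set. The CN-derived and
   methylation-derived PPT sets are unioned; a classification is proposed
   when the PPT-vs-GPT log-rank p < 0.05.
5. **Validation and DE.** Held-out samples are discretized with the
   training cutoffs and classified by weighted K-nearest neighbors
   (K = 3, weights 1/d, `d = max(#mismatch, 1)/#informative`); finally
   differentially expressed genes between each PPT set and the GPT group
   are called at fold change ≥ 1.5 and Welch p < 0.01.

A seeded synthetic-cohort generator (`sim_config()` / `generate_cohort()`)
produces cohorts with planted batch effects, a contiguous amplified gene
segment, a hypomethylated CpG set, confounded decoy features, treatment
histories and right-censored Weibull/exponential survival, plus
ground-truth labels — so the whole pipeline is testable offline.

## Worked example

```r
library(chemoclust)
cohort <- generate_cohort(sim_config(seed = 1))
fit <- chemoclust(cohort$expression, cohort$copy_number,
                  cohort$methylation, cohort$clinical)
summary(fit)
#> Sample selection
#>   200 samples with all three profiles
#>   168 eligible (stage + treatment rules): 85 training, 83 testing
#>   32 excluded (cycles=10, missing_carboplatin=7, stage=8, start_delay=7)
#> Copy-number feature funnel
#>   39 survival-associated -> 35 after confounder refinement -> 35 after fold-change
#>   clusters: 18 PPT / 67 GPT (log-rank p = 0.000107)
#> Methylation feature funnel
#>   140 survival-associated -> 132 after confounder refinement -> 43 after fold-change
#>   clusters: 22 PPT / 63 GPT (log-rank p = 0.00148)
#> Integrated training classification
#>   40 PPT (CN 18, methylation 22, overlap 0) vs 45 GPT; log-rank p = 2.5e-08 (proposed)

predict(fit)
#> chemoclust_prediction: 39 PPT (CN 17, methylation 22, overlap 0) / 44 GPT
#>   PPT vs GPT log-rank p = 0.001598
```

Reading the output: of 200 simulated samples, 168 satisfy the
treatment-uniformity rules (85 training, 83 testing). The survival scan
plus refinements keep 35 copy-number features and 43 CpGs; clustering
splits the training cohort into 18 copy-number PPTs and 22 methylation
PPTs whose union (40 PPT vs 45 GPT) separates progression-free survival at
p = 2.5×10⁻⁸. The held-out cohort, classified only with training-derived
rules, reproduces the separation (p = 0.0016). Differentially expressed
genes between a PPT set and the GPT group come from
`differential_expression()`; `plot(fit)` draws the Kaplan–Meier curves.

On a null cohort (`null_config()`: no planted effects) the same pipeline
reports an unproposed classification and α-level feature counts — the
negative control.

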