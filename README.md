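# cgsreclass

Combined genetic scores and net reclassification improvement for type 2
diabetes risk prediction.

## The problem

Common variants associated with type 2 diabetes (T2D) each carry small
allelic odds ratios (mostly 1.1–1.5), far too weak to predict disease
individually. The standard aggregation is a **combined genetic score
(CGS)**: per subject, the count of risk alleles over a panel of
susceptibility loci, optionally weighted by each locus's effect size

    CGS_unweighted = Σᵢ dᵢ,      CGS_weighted = Σᵢ (βᵢ / β̄) · dᵢ,

with `dᵢ ∈ {0,1,2}` the risk-allele dosage and `βᵢ` the per-SNP log odds
ratio. The substantive question is whether the score improves T2D
prediction *beyond* clinical variables (sex, age, BMI) in a case-control
cohort. Discrimination is measured by the Mann–Whitney AUC; incremental
clinical value by the five-category **net reclassification improvement**

    NRI = (P↑ − P↓ | cases) + (P↓ − P↑ | controls)

across absolute-risk categories <5%, 5–<10%, 10–<15%, 15–<20%, ≥20%.
Because case-control sampling distorts the intercept, each model's
intercept is shifted by `log[ρ/(1−ρ) × n_control/n_case]` so predicted
risks refer to a population prevalence ρ (default 10%).

The package is aimed at genetic epidemiologists who need the full chain —
genotype QC (exact Hardy–Weinberg test, call rates), score construction
(mean-dosage imputation, weighting, rounding, quartiles), additive-model
association with permutation-based family-wise correction, and
prevalence-adjusted reclassification analysis — plus a synthetic
case-control cohort generator so everything runs and is testable without
access to individual-level data.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage
1 simulates a study-scale cohort (5882 cases / 2569 controls, 14 SNPs at
published Chinese control frequencies and odds ratios, 2.7% missing
genotypes); stages 2–5 run QC, association, scoring and prediction;
stage 6 re-derives the published reclassification arithmetic.

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_genotype_qc.R
Rscript analysis/03_association.R
Rscript analysis/04_genetic_score.R
Rscript analysis/05_risk_prediction.R
Rscript analysis/06_published_tables.R
```

Stage 5 prints, for this cohort realisation:

```
-- unweighted CGS --
per-score OR: 1.267
AUC clinical 0.753 -> clinical+CGS 0.777 (CGS only 0.612)
NRI = 12.0% (net cases 5.78%, net controls 6.27%; 95% CI 9.5-14.6%, P = 1.5e-20)
```

Reading: each extra risk allele multiplies the T2D odds by ~1.27 after
adjusting for sex, age and BMI; adding the score to the clinical model
raises the AUC by ~0.02 — the classic "statistically strong, AUC-blind"
pattern — while the NRI shows ~12% of subjects are net correctly
reclassified across risk categories. Stage 6 confirms the published
cross-tabulations are internally exact:

```
unweighted: cases up 22.0% / down 16.6%; controls down 15.4% / up 9.8%
  net cases 5.38% + net controls 5.62% = NRI 11.0% (2891 reclassified)
weighted: cases up 22.2% / down 17.8%; controls down 17.1% / up 10.1%
  net cases 4.36% + net controls 6.99% = NRI 11.4% (3021 reclassified)
```

The same machinery is available directly:

```r
library(cgsreclass)
ch <- simulate_cohort(simulation_config(), seed = 1)
s  <- score_set(impute_mean_dosage(ch$genotypes))
ra <- reclassification_analysis(ch$phenotypes$status,
                                ch$phenotypes[, c("sex", "age", "bmi")],
                                s$rounded_score, prevalence = 0.10)
ra$nri$nri    # net reclassification improvement
```

See `vignettes/combined-genetic-score-methods.Rmd` for the models,
parameter conventions, generator assumptions and numerical choices.

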