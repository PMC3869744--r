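---
title: "Combined genetic scores and net reclassification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined genetic scores and net reclassification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsreclass)
```

# The scientific problem

Genome-wide association studies have identified dozens of common variants
that each raise the odds of type 2 diabetes (T2D) only modestly
(allelic odds ratios of roughly 1.1–1.5, with TCF7L2 an outlier at ~2).
Individually they are useless for prediction, so the field aggregates them
into a *combined genetic score* (CGS): for each subject, the number of
risk alleles carried across a panel of susceptibility loci, optionally
weighted by each locus's effect size.  The question this package
operationalises is whether such a score adds predictive value for T2D
*beyond* the cheap clinical variables a clinician already has — sex, age
and BMI — in a Chinese case-control setting: 5882 T2D patients and 2569
healthy controls (adolescent, adult and elderly sub-cohorts) genotyped at
14 beta-cell-function loci.

Two complementary lenses are used.  *Discrimination*: the area under the
ROC curve (AUC), which is famously insensitive to added markers once a
moderately good clinical model exists.  *Reclassification*: the
categorical net reclassification improvement (NRI), which asks whether
adding the score moves cases up and controls down across clinically
meaningful absolute-risk categories.

# Models

## Per-SNP association

Disease log-odds are modelled as linear in the risk-allele dosage
$d \in \{0,1,2\}$ (the additive genetic model), adjusted for sex, age and
BMI:

$$\operatorname{logit} P(\text{T2D}) = \beta_0 + \beta_1 d + \gamma^\top C.$$

Odds ratios are reported per risk allele with Wald 95% CIs,
$\exp(\hat\beta_1 \pm 1.96\,\widehat{se})$.  Fits are maximum likelihood by
iteratively reweighted least squares (convergence tolerance $10^{-8}$, at
most 50 iterations); non-convergence or a blown-up standard error
(complete separation) is an error, not a silent result.

Multiple testing across the SNP panel is corrected by permutation: case
labels are shuffled $B$ times, each SNP refit, and the maximum $|Z|$ over
SNPs recorded per permutation.  The family-wise adjusted p-value of SNP
$i$ is $(1 + \#\{b: \max_j |Z_j^{(b)}| \ge |Z_i|\})/(B+1)$.  We chose the
max-statistic (family-wise) scheme over pointwise label permutation
because published permutation p-values of this design are larger than the
pointwise p-values by roughly a family-size factor; both are emitted, the
family-wise value is the headline column.  A direction-consistency
summary uses the exact binomial tail: the probability that $k$ or more of
$n$ SNPs agree in direction with prior reports by chance is
$P(X \ge k)$, $X \sim \mathrm{Bin}(n, 1/2)$.

## Score construction

Score SNPs are those with literature-consistent direction and $P < 0.05$.
Missing dosages (the generator defaults to the 2.7% overall rate of the
emulated study) are imputed by the SNP's mean observed dosage over the
*combined* case-control cohort — a deliberate single-cohort rule: imputing
per status group would leak the outcome into the score.  The unweighted
score sums dosages; the weighted score uses

$$w_i = \hat\beta_i \,/\, \overline{\hat\beta},$$

i.e. each SNP's log-OR relative to the panel mean.  Normalising by the
mean keeps the weighted score on the allele-count scale (the emulated
study's weighted score spans 1–13 against 2–14 unweighted), and makes the
weights invariant to rescaling all betas.  Scores are rounded to the
nearest integer, halves away from zero — the rounding direction is a
convention, chosen once for bit-reproducibility.

Quartile groups are formed on the *rounded* score with the constraint
that equal scores share a group: integer cut-points are chosen so the
cumulative proportions are nearest to 25/50/75% (ties toward the smaller
cut score).  Group sizes are therefore unequal by design; an exhaustive
search over cut triples in the test suite confirms the cuts minimise the
summed deviation from the quartile targets.  Tail bins
($\le$ lower, …, $\ge$ upper) collapse the sparse score extremes for
bin-wise odds ratios.

## Risk prediction and NRI

Three in-sample logistic models are fitted: clinical (sex, age, BMI),
score only, and clinical + score.  Because the data are case-control, the
fitted intercept reflects the sampling fraction, not the population; each
model's intercept is shifted by

$$\log\!\left[\frac{\rho}{1-\rho}\cdot\frac{n_{\text{control}}}{n_{\text{case}}}\right]$$

so that inverse-logit linear predictors estimate absolute risk at an
assumed population prevalence $\rho$ (default 0.10, the T2D prevalence
the emulated study assumed).  Setting $\rho$ to the sample case fraction
recovers the unadjusted fitted probabilities exactly — a useful identity
that the tests exploit.

Adjusted risks are stratified into five categories — <5%, 5–<10%,
10–<15%, 15–<20%, $\ge$20% — with inclusive lower bounds (a risk of
exactly 5% is in the second category, exactly 20% in the fifth).
Reclassification is cross-tabulated separately for cases and controls
(baseline categories in rows, with-score categories in columns), and

$$\mathrm{NRI} = \left(P_{\uparrow} - P_{\downarrow}\right)_{\text{cases}}
  + \left(P_{\downarrow} - P_{\uparrow}\right)_{\text{controls}},$$

with asymptotic standard error
$\sqrt{(p_{\uparrow,\text{case}}+p_{\downarrow,\text{case}})/n_{\text{case}}
 + (p_{\uparrow,\text{ctrl}}+p_{\downarrow,\text{ctrl}})/n_{\text{ctrl}}}$.
The published interval for the emulated study's unweighted NRI (7.5–14.5%)
is wider than this formula implies from the printed proportions
(the formula gives roughly 8.5–13.5%), suggesting the original interval
came from a different (likely resampling-based) method.  We therefore do
not silently match it: the asymptotic method is the default and a seeded
multinomial bootstrap over the table cells (2000 resamples) is available
via `nri(..., ci_method = "bootstrap")`.

AUC is the Mann–Whitney pair-counting estimator (ties count one half),
with a Hanley–McNeil asymptotic CI — chosen because intervals of the
"0.75 (0.74–0.76)" style are reported without a named method, and
Hanley–McNeil is the conventional default.

# The synthetic cohort generator

No individual-level data accompany the emulated study, so the generator
is the package's test bed.  It draws control genotypes genotype-wise from
Hardy–Weinberg proportions at the published control frequencies, and case
genotypes from Hardy–Weinberg proportions at the shifted frequency
$p_{\text{case}} = p\,\mathrm{OR}/(1 - p + p\,\mathrm{OR})$ implied by
the allelic odds ratio.  This allelic-independence construction has two
properties the tests rely on: the per-allele odds ratio of the implied
genotype distributions is *exactly* the specified OR (so the additive
logistic model is correctly specified and parameter-recovery tests have
an exact target), and it is invertible in closed form.  A liability-scale
generator would emulate polygenic biology more faithfully but would make
the target OR only approximate.

Covariates mirror the emulated cohort structure: cases aged 56.8 ± 13.3
years with BMI 25.1 ± 3.9; controls split into adolescent
(15.3 ± 1.9 y, BMI 19.9 ± 3.6), adult (41.3 ± 10.5, 22.9 ± 3.3) and
elderly (72.3 ± 5.3, 23.2 ± 3.3) sub-cohorts in the 1057/586/926
proportions, ~46% male throughout.  Covariates are independent of
genotype (the analysis adjusts for them but posits no
genotype–covariate dependence); missingness is completely at random at
2.7%.  A single global seed drives one RNG stream, so identical
configurations reproduce cohorts bit-for-bit.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium between loci,
genotype–covariate confounding (e.g. population stratification),
age-structured incidence, adolescent controls converting to diabetes
later in life (the sensitivity analysis removing adolescents is mirrored
by `include_adolescents = FALSE`, not by a conversion model), and any
non-additivity of true genetic effects.

# Derived clinical traits

HOMA-IR $= \mathrm{FPI}[\mathrm{mU/l}] \times \mathrm{FPG}[\mathrm{mmol/l}]/22.5$
and HOMA-$\beta = \mathrm{FPI} \times 20/(\mathrm{FPG} - 3.5)$; HOMA-$\beta$
is undefined at FPG $\le$ 3.5 mmol/l and returned as missing with a
message.  Insulin reported in pmol/l is converted to mU/l with the
conventional divisor 6.0 — the exact assay factor used originally is not
stated, so no acceptance-level check depends on it.  eGFR uses the
abbreviated MDRD formula with the Chinese ethnicity coefficient 1.233 and
the female factor 0.742 applied multiplicatively.  FPI, HOMA-IR and
HOMA-$\beta$ are natural-log transformed (base unstated originally; $e$
is the regression convention).  Winsorization replaces values beyond
mean ± 4 SD — computed once, before any replacement, separately within
strata — with the boundary; a single pass is consistent with the tiny
(<0.2%) replacement fraction expected at 4 SD.

# Numerical choices and degenerate inputs

* The exact Hardy–Weinberg test enumerates all heterozygote counts
  sharing the allele margin's parity, in log-space for stability, and
  sums probabilities $\le$ the observed one (two-sided
  probability-ordering, no mid-p).  Monomorphic sites return 1.  The test
  suite verifies equality with a direct enumeration oracle for every
  genotype configuration up to 50 subjects.
* QC thresholds (call rate > 0.95, HWE $P > 0.01$ in pooled controls) are
  configuration defaults and *flag* SNPs rather than dropping them — the
  exclusion mechanics of the original design are unreported, so nothing
  is removed silently.  Pooled controls are the default HWE stratum;
  per-sub-cohort testing is available by subsetting.
* Permutation p-values use the $(1 + \text{count})/(B+1)$ estimator, so
  they are never zero; within the permutation loop a separated refit
  contributes its (near-zero) Wald $Z$ rather than aborting the stream.
* Constant dosages, single-class outcomes, empty strata, crossed bin
  cuts, fully missing SNPs and out-of-range probabilities all raise typed
  validation errors (`cgs_validation_error`, `cgs_fit_error`,
  `cgs_key_error`) rather than propagating NaN.
* An NRI with nobody reclassified has zero standard error; its p-value is
  defined as 1.

# Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic data.
Parameter-recovery checks use the full study-scale design
(5882/2569 subjects) over 100 replicates; null-calibration checks use
200 replicates at 4000 (interaction) and 2100 (NRI) subjects; oracle
equivalences run on exhaustive small cases (all HWE configurations to
$n \le 50$, all label permutations of 8 subjects).  These sizes give
Monte-Carlo error comfortably inside the asserted tolerances while
keeping a full run in minutes.

# Known limitations

In-sample AUC and NRI are optimistic relative to external validation (a
cross-validated mode is deliberately out of scope here, matching the
emulated design).  The asymptotic NRI standard error ignores the
correlation induced by fitting both models on the same subjects.  The
categorical NRI depends on the category bounds; the 5/10/15/20% bounds
are fixed as defaults and any comparison across studies with different
bounds is not meaningful.  The generator's allelic-independence
construction cannot represent LD, so "score SNPs" are effectively
independent information channels — real panels with correlated SNPs
would show smaller incremental value than these simulations.
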