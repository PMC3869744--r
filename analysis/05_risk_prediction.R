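#!/usr/bin/env Rscript
# Stage 5: incremental predictive value of the score.
#
# Three logistic models (clinical = sex + age + BMI; score only; both),
# each with the intercept shifted by log[rho/(1-rho) x n_ctrl/n_case] so
# predicted risks refer to a population prevalence of 10%.  Discrimination
# by pair-counting AUC; reclassification across the five risk categories
# (<5, 5-<10, 10-<15, 15-<20, >=20%) summarised by the categorical NRI.
# Writes reclassification tables and NRI JSON under results/.

suppressPackageStartupMessages(library(cgsreclass))

pheno <- read.delim("results/cohort/phenotypes.tsv")
clin <- pheno[, c("sex", "age", "bmi")]
status <- pheno$status

for (nm in c("unweighted", "weighted")) {
  s <- read.delim(sprintf("results/scores_%s.tsv", nm))
  ra <- reclassification_analysis(status, clin, s$rounded_score,
                                  prevalence = 0.10)
  cat(sprintf("\n-- %s CGS --\n", nm))
  cat(sprintf("per-score OR: %.3f\n",
              fit_logistic_additive(status, s$rounded_score, clin)$or_))
  cat(sprintf("AUC clinical %.3f -> clinical+CGS %.3f (CGS only %.3f)\n",
              ra$models$clinical$auc, ra$models$clinical_plus_cgs$auc,
              ra$models$cgs_only$auc))
  cat(sprintf("NRI = %.1f%% (net cases %.2f%%, net controls %.2f%%; 95%% CI %.1f-%.1f%%, P = %.2g)\n",
              100 * ra$nri$nri, 100 * ra$nri$net_case,
              100 * ra$nri$net_control, 100 * ra$nri$ci[1],
              100 * ra$nri$ci[2], ra$nri$p))

  w <- function(m, f) write.table(
    data.frame(without_cgs = rownames(m), m, check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- c("<5%", "5-<10%", "10-<15%", "15-<20%", ">=20%")
  dimnames(ra$reclass$table_cases) <- dimnames(ra$reclass$table_controls) <-
    list(lab, lab)
  w(ra$reclass$table_cases, sprintf("results/reclass_%s_cases.tsv", nm))
  w(ra$reclass$table_controls, sprintf("results/reclass_%s_controls.tsv", nm))
  jsonlite::write_json(ra$nri[c("nri", "se", "ci", "p", "net_case",
                                "net_control")],
                       sprintf("results/nri_%s.json", nm),
                       auto_unbox = TRUE, digits = NA)
}
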