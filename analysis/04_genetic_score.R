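#!/usr/bin/env Rscript
# Stage 4: build the combined genetic scores.
#
# Score SNPs are those with literature-consistent direction and P < 0.05
# in stage 3.  Missing dosages are mean-imputed over the combined cohort,
# the unweighted score is the risk-allele count, the weighted score
# multiplies each dosage by beta_i / mean(beta), and both are rounded to
# the nearest integer.  Subjects are grouped into score quartiles and the
# case/control score distributions are compared by Student's t-test.
# Writes scores, quartile table and score distribution under results/.

suppressPackageStartupMessages(library(cgsreclass))

geno <- read_genotypes("results/cohort/dosages.tsv")
pheno <- read.delim("results/cohort/phenotypes.tsv")
assoc <- read.delim("results/association.tsv")

score_snps <- assoc$snp[assoc$p < 0.05 & assoc$beta > 0]
cat(sprintf("score built from %d SNPs: %s\n", length(score_snps),
            paste(score_snps, collapse = ", ")))

imputed <- impute_mean_dosage(geno[, score_snps, drop = FALSE])
betas <- assoc$beta[match(score_snps, assoc$snp)]
names(betas) <- score_snps
weights <- compute_weights(betas)

scores_u <- score_set(imputed)
scores_w <- score_set(imputed, weights)
write.table(scores_u, "results/scores_unweighted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scores_w, "results/scores_weighted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

status <- pheno$status
for (nm in c("unweighted", "weighted")) {
  s <- if (nm == "unweighted") scores_u else scores_w
  tt <- t_test_scores(s$rounded_score[status == 1],
                      s$rounded_score[status == 0])
  cat(sprintf("%s CGS: mean cases %.2f vs controls %.2f (t-test P = %.2g)\n",
              nm, tt$mean_cases, tt$mean_controls, tt$p))
}

dist <- data.frame(score = sort(unique(scores_u$rounded_score)))
dist$n_cases <- sapply(dist$score, function(s)
  sum(scores_u$rounded_score == s & status == 1))
dist$n_controls <- sapply(dist$score, function(s)
  sum(scores_u$rounded_score == s & status == 0))
write.table(dist, "results/score_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("quartile sizes (unweighted):",
    paste(table(scores_u$quartile), collapse = " / "), "\n")
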