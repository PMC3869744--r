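# End-to-end orchestration: simulate (or load) -> QC -> score ->
# associate -> predict -> reclassify -> report.  Every stage writes only
# plain TSV/JSON artifacts so each report number is re-derivable from the
# intermediate files.

#' Build a pipeline run configuration
#'
#' @param sim a \code{\link{simulation_config}} (used when no input paths
#'   are given)
#' @param genotype_path,phenotype_path optional paths to pre-existing
#'   dosage and phenotype tables (TSV; see \code{\link{read_genotypes}})
#' @param seed integer seed recorded in every output
#' @param call_rate_min,hwe_p_min QC thresholds
#' @param weighted also compute the weighted score (default TRUE)
#' @param B_perm permutations for the association table (0 disables)
#' @param prevalence population prevalence for risk adjustment
#' @param risk_bounds risk-category cut-points
#' @param ci_method NRI CI method
#' @param out_dir output directory
#' @return list of class \code{cgs_run_config}
#' @export
run_config <- function(sim = simulation_config(), genotype_path = NULL,
                       phenotype_path = NULL, seed = 1L,
                       call_rate_min = 0.95, hwe_p_min = 0.01,
                       weighted = TRUE, B_perm = 0L, prevalence = 0.10,
                       risk_bounds = c(0.05, 0.10, 0.15, 0.20),
                       ci_method = "asymptotic", out_dir = tempfile("cgs_run_")) {
  for (p in c(genotype_path, phenotype_path)) {
    assert_that(file.exists(p), paste0("input path does not exist: ", p))
  }
  structure(list(sim = sim, genotype_path = genotype_path,
                 phenotype_path = phenotype_path, seed = as.integer(seed),
                 call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 weighted = weighted, B_perm = as.integer(B_perm),
                 prevalence = prevalence, risk_bounds = risk_bounds,
                 ci_method = ci_method, out_dir = out_dir),
            class = "cgs_run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies genotype QC, builds the
#' unweighted and weighted combined genetic scores, fits per-SNP and
#' per-score additive associations, and evaluates the score's incremental
#' predictive value (AUC and categorical NRI).  Identical config + seed
#' give byte-identical numeric outputs.
#'
#' @param config a \code{\link{run_config}}
#' @return invisibly, a list with all stage results; artifacts are written
#'   under \code{config$out_dir}
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "cgs_run_config"), "config must come from run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  tsv <- function(x, f) utils::write.table(x, out(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)

  # -- simulate / load ------------------------------------------------
  if (is.null(config$genotype_path)) {
    cohort <- simulate_cohort(config$sim, seed = config$seed)
    panel <- study_snp_panel(significant_only = FALSE)
    panel <- panel[match(colnames(cohort$genotypes), panel$id), , drop = FALSE]
    write_cohort(cohort, config$out_dir)
  } else {
    geno <- read_genotypes(config$genotype_path)
    pheno <- utils::read.delim(config$phenotype_path, stringsAsFactors = FALSE)
    cohort <- list(genotypes = geno, phenotypes = pheno, truth = NULL)
    panel <- study_snp_panel(significant_only = FALSE)
    panel <- panel[match(colnames(geno), panel$id), , drop = FALSE]
  }
  geno <- cohort$genotypes
  pheno <- cohort$phenotypes
  status <- pheno$status
  clinical <- data.frame(sex = pheno$sex, age = pheno$age, bmi = pheno$bmi)

  # -- QC -------------------------------------------------------------
  qc <- summarize_snp(geno, panel, status,
                      call_rate_min = config$call_rate_min,
                      hwe_p_min = config$hwe_p_min)
  tsv(qc, "qc_summary.tsv")

  # -- per-SNP association (published-table layout) -------------------
  assoc <- association_table(geno, panel, status, covariates = clinical,
                             B = config$B_perm, seed = config$seed)
  tsv(assoc, "association.tsv")

  # -- score SNP selection: literature-consistent direction, p < 0.05 --
  score_snps <- assoc$snp[assoc$p < 0.05 & assoc$beta > 0]
  if (length(score_snps) < 2) score_snps <- assoc$snp[assoc$beta > 0]
  tsv(data.frame(id = score_snps), "score_snps.tsv")

  # -- scores ---------------------------------------------------------
  imputed <- impute_mean_dosage(geno[, score_snps, drop = FALSE])
  scores_u <- score_set(imputed)
  betas <- assoc$beta[match(score_snps, assoc$snp)]
  names(betas) <- score_snps
  weights <- if (config$weighted) compute_weights(betas) else NULL
  scores_w <- if (config$weighted) score_set(imputed, weights) else NULL
  tsv(scores_u, "scores_unweighted.tsv")
  if (!is.null(scores_w)) tsv(scores_w, "scores_weighted.tsv")
  if (!is.null(weights)) {
    tsv(data.frame(id = names(weights), weight = unname(weights)), "weights.tsv")
  }

  # -- per-score association + t-test + quartile table ---------------
  score_assoc <- fit_logistic_additive(status, scores_u$rounded_score, clinical)
  tt <- t_test_scores(scores_u$rounded_score[status == 1],
                      scores_u$rounded_score[status == 0])
  quart <- quartile_summary(scores_u, pheno)
  tsv(quart, "quartile_table.tsv")

  # -- score distribution / bin ORs (figure content) ------------------
  dist <- score_distribution(scores_u$rounded_score, status)
  tsv(dist, "score_distribution.tsv")

  # -- prediction + reclassification ---------------------------------
  ra <- reclassification_analysis(status, clinical, scores_u$rounded_score,
                                  prevalence = config$prevalence,
                                  bounds = config$risk_bounds,
                                  ci_method = config$ci_method)
  write_reclass_tables(ra$reclass, config$out_dir, prefix = "reclass_unweighted")
  ra_w <- NULL
  if (!is.null(scores_w)) {
    ra_w <- reclassification_analysis(status, clinical, scores_w$rounded_score,
                                      prevalence = config$prevalence,
                                      bounds = config$risk_bounds,
                                      ci_method = config$ci_method)
    write_reclass_tables(ra_w$reclass, config$out_dir, prefix = "reclass_weighted")
  }
  roc <- roc_points(ra$models$clinical_plus_cgs$predicted_risk, status)
  tsv(roc, "roc_clinical_plus_cgs.tsv")

  summary <- list(
    seed = config$seed,
    n_case = sum(status == 1), n_control = sum(status == 0),
    n_excluded = ra$models$n_excluded,
    prevalence = config$prevalence,
    mean_cgs_cases = tt$mean_cases, mean_cgs_controls = tt$mean_controls,
    t_test_p = tt$p,
    per_allele_or_unweighted = score_assoc$or_,
    auc_clinical = ra$models$clinical$auc,
    auc_clinical_plus_cgs = ra$models$clinical_plus_cgs$auc,
    nri_unweighted = ra$nri$nri,
    nri_weighted = if (!is.null(ra_w)) ra_w$nri$nri else NULL,
    package_version = as.character(utils::packageVersion("cgsreclass"))
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(cohort = cohort, qc = qc, association = assoc,
                 scores_unweighted = scores_u, scores_weighted = scores_w,
                 score_assoc = score_assoc, t_test = tt,
                 quartile_table = quart,
                 reclass_unweighted = ra, reclass_weighted = ra_w,
                 summary = summary, out_dir = config$out_dir))
}

# per-quartile clinical summary (published quartile-table layout)
quartile_summary <- function(scores, pheno) {
  q <- scores$quartile
  do.call(rbind, lapply(sort(unique(q)), function(k) {
    idx <- q == k
    data.frame(quartile = k, n = sum(idx),
               score_median = stats::median(scores$rounded_score[idx]),
               score_min = min(scores$rounded_score[idx]),
               score_max = max(scores$rounded_score[idx]),
               male_pct = 100 * mean(pheno$sex[idx] == 1),
               age_mean = mean(pheno$age[idx]),
               bmi_mean = mean(pheno$bmi[idx]))
  }))
}

# counts of each rounded score by status
score_distribution <- function(rounded, status) {
  u <- sort(unique(rounded))
  data.frame(score = u,
             n_cases = vapply(u, function(s) sum(rounded == s & status == 1), numeric(1)),
             n_controls = vapply(u, function(s) sum(rounded == s & status == 0), numeric(1)))
}

# ROC curve points over unique thresholds
roc_points <- function(risk, status) {
  th <- sort(unique(risk), decreasing = TRUE)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  data.frame(threshold = th,
             tpr = vapply(th, function(t) sum(risk >= t & status == 1) / n1, numeric(1)),
             fpr = vapply(th, function(t) sum(risk >= t & status == 0) / n0, numeric(1)))
}

# reclassification tables + NRI summary in the published layout
write_reclass_tables <- function(reclass, dir, prefix) {
  w <- function(m, f) {
    df <- data.frame(without_cgs = rownames(m) %||% seq_len(nrow(m)), m,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(reclass$table_cases, paste0(prefix, "_cases.tsv"))
  w(reclass$table_controls, paste0(prefix, "_controls.tsv"))
  res <- nri(reclass)
  jsonlite::write_json(
    list(nri = res$nri, se = res$se, ci = res$ci, p = res$p,
         net_case = res$net_case, net_control = res$net_control,
         n_reclassified = reclass$n_reclassified),
    file.path(dir, paste0(prefix, "_nri.json")), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
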