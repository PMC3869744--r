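# Synthetic case-control cohort generator.
#
# Genotypes are drawn genotype-wise from Hardy-Weinberg proportions:
# controls at the specified control risk-allele frequency, cases at the
# frequency implied by the allelic odds ratio (the allelic-independence
# approximation, which is exactly invertible and matches the additive
# log-odds parameterisation used in the association analyses).  Covariates
# are independent of genotype; missingness is completely at random.

#' Case risk-allele frequency implied by an allelic odds ratio
#'
#' Under the allelic odds-ratio definition OR = [p_case/(1-p_case)] /
#' [p_ctrl/(1-p_ctrl)], the case frequency is
#' p_case = p OR / (1 - p + p OR).
#'
#' @param p_control control risk-allele frequency in (0,1)
#' @param or_allelic allelic odds ratio, > 0
#' @return case risk-allele frequency
#' @export
#' @examples
#' case_allele_freq(0.656, 1.45)  # ~0.734
case_allele_freq <- function(p_control, or_allelic) {
  assert_that(is.numeric(p_control) && all(p_control > 0) && all(p_control < 1),
              "p_control must lie strictly in (0, 1)")
  assert_that(is.numeric(or_allelic) && all(is.finite(or_allelic)) &&
                all(or_allelic > 0), "or_allelic must be > 0")
  p_control * or_allelic / (1 - p_control + p_control * or_allelic)
}

#' Build a simulation configuration
#'
#' Defaults reproduce the published study conditions: 5882 cases and 2569
#' controls (adolescent/adult/elderly sub-cohorts), the 8-SNP score panel
#' at the published control frequencies and odds ratios, population
#' prevalence 10%, and 2.7% missing genotypes.
#'
#' @param n_case,n_control cohort sizes (>= 1)
#' @param prevalence assumed population prevalence in (0,1)
#' @param snp_specs data.frame with columns \code{id}, \code{p_control},
#'   \code{or} (one row per SNP); defaults to the study panel
#' @param missing_rate per-dosage missingness probability in [0,1)
#' @param sex_male_prob probability a subject is male
#' @param case_age,case_bmi length-2 (mean, sd) for case covariates
#' @param control_groups data.frame defining control sub-cohorts with
#'   columns \code{label}, \code{n_frac}, \code{age_mean}, \code{age_sd},
#'   \code{bmi_mean}, \code{bmi_sd}
#' @param include_adolescents logical; drop the adolescent control
#'   sub-cohort when \code{FALSE} (mirrors the study's sensitivity
#'   analysis; controls remain fixed non-cases)
#' @return object of class \code{cgs_sim_config}
#' @export
simulation_config <- function(n_case = 5882L, n_control = 2569L,
                              prevalence = 0.10,
                              snp_specs = NULL,
                              missing_rate = 0.027,
                              sex_male_prob = 0.46,
                              case_age = c(56.8, 13.3),
                              case_bmi = c(25.1, 3.9),
                              control_groups = NULL,
                              include_adolescents = TRUE) {
  if (is.null(snp_specs)) {
    p <- study_snp_panel()
    snp_specs <- data.frame(id = p$id, p_control = p$freq_controls,
                            or = p$or_published, stringsAsFactors = FALSE)
  }
  assert_that(is.data.frame(snp_specs) && nrow(snp_specs) >= 1 &&
                all(c("id", "p_control", "or") %in% names(snp_specs)),
              "snp_specs must be a data.frame with id, p_control, or")
  assert_that(is_proportion(snp_specs$p_control),
              "all control frequencies must lie in (0, 1)")
  assert_that(all(snp_specs$or > 0), "all odds ratios must be > 0")
  assert_that(n_case >= 1 && n_control >= 1,
              "n_case and n_control must be >= 1")
  assert_that(is_proportion(prevalence), "prevalence must lie in (0, 1)")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  if (is.null(control_groups)) {
    # Table-1 sub-cohort structure: adolescents / adults / elderly
    control_groups <- data.frame(
      label = c("adolescent", "adult", "elderly"),
      n_frac = c(1057, 586, 926) / 2569,
      age_mean = c(15.3, 41.3, 72.3), age_sd = c(1.9, 10.5, 5.3),
      bmi_mean = c(19.9, 22.9, 23.2), bmi_sd = c(3.6, 3.3, 3.3),
      stringsAsFactors = FALSE
    )
  }
  if (!include_adolescents) {
    control_groups <- control_groups[control_groups$label != "adolescent", ,
                                     drop = FALSE]
    control_groups$n_frac <- control_groups$n_frac / sum(control_groups$n_frac)
  }
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 prevalence = prevalence, snp_specs = snp_specs,
                 missing_rate = missing_rate,
                 sex_male_prob = sex_male_prob,
                 case_age = case_age, case_bmi = case_bmi,
                 control_groups = control_groups),
            class = "cgs_sim_config")
}

# one HWE genotype draw per subject at allele frequency p
draw_hwe_genotypes <- function(n, p) {
  stats::rbinom(n, size = 2L, prob = p)
}

#' Simulate a case-control cohort with ground truth
#'
#' Controls are drawn genotype-wise from Hardy-Weinberg proportions at each
#' SNP's control frequency; cases at \code{case_allele_freq(p, OR)}.  Sex,
#' age and BMI are drawn per group and are independent of genotype.  Each
#' dosage is independently set missing with probability
#' \code{missing_rate}.  The same \code{seed} reproduces the cohort
#' bit-for-bit.
#'
#' @param config a \code{\link{simulation_config}}
#' @param seed integer seed for the single RNG stream
#' @return list with \code{phenotypes} (data.frame: subject_id, status
#'   (1 = case), sex, age, bmi, cohort_label), \code{genotypes} (numeric
#'   matrix subjects x SNPs, risk-allele dosages with \code{NA} for
#'   missing) and \code{truth} (per-SNP true OR and control frequency plus
#'   the seed).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  assert_that(inherits(config, "cgs_sim_config"), "config must come from simulation_config()")
  set.seed(as.integer(seed))
  n_case <- config$n_case
  n_ctrl <- config$n_control
  n <- n_case + n_ctrl
  snps <- config$snp_specs
  m <- nrow(snps)

  status <- c(rep(1L, n_case), rep(0L, n_ctrl))

  # control sub-cohort labels by fixed fractions (deterministic split)
  cg <- config$control_groups
  sizes <- diff(c(0L, round(cumsum(cg$n_frac) * n_ctrl)))
  ctrl_label <- rep(cg$label, times = sizes)
  cohort_label <- c(rep("case", n_case), ctrl_label)

  sex <- stats::rbinom(n, 1L, config$sex_male_prob)  # 1 = male
  age <- numeric(n)
  bmi <- numeric(n)
  age[1:n_case] <- stats::rnorm(n_case, config$case_age[1], config$case_age[2])
  bmi[1:n_case] <- stats::rnorm(n_case, config$case_bmi[1], config$case_bmi[2])
  for (g in seq_len(nrow(cg))) {
    idx <- which(cohort_label == cg$label[g])
    age[idx] <- stats::rnorm(length(idx), cg$age_mean[g], cg$age_sd[g])
    bmi[idx] <- stats::rnorm(length(idx), cg$bmi_mean[g], cg$bmi_sd[g])
  }
  age <- pmax(age, 1)
  bmi <- pmax(bmi, 10)

  p_case <- case_allele_freq(snps$p_control, snps$or)
  geno <- matrix(NA_real_, nrow = n, ncol = m,
                 dimnames = list(sprintf("S%05d", seq_len(n)), snps$id))
  for (j in seq_len(m)) {
    geno[1:n_case, j] <- draw_hwe_genotypes(n_case, p_case[j])
    geno[(n_case + 1):n, j] <- draw_hwe_genotypes(n_ctrl, snps$p_control[j])
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    geno[miss] <- NA_real_
  }

  phenotypes <- data.frame(
    subject_id = rownames(geno),
    status = status, sex = sex, age = age, bmi = bmi,
    cohort_label = cohort_label, stringsAsFactors = FALSE
  )
  truth <- list(snp = data.frame(id = snps$id, or_true = snps$or,
                                 p_control_true = snps$p_control,
                                 p_case_true = p_case,
                                 stringsAsFactors = FALSE),
                seed = as.integer(seed),
                prevalence = config$prevalence)
  list(phenotypes = phenotypes, genotypes = geno, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Phenotypes and dosages as tab-separated tables (missing code \code{NA})
#' plus a JSON truth file.
#'
#' @param cohort result of \code{\link{simulate_cohort}}
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ph <- file.path(dir, "phenotypes.tsv")
  gt <- file.path(dir, "dosages.tsv")
  tr <- file.path(dir, "truth.json")
  utils::write.table(cohort$phenotypes, ph, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_genotypes(cohort$genotypes, gt)
  jsonlite::write_json(cohort$truth, tr, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(phenotypes = ph, genotypes = gt, truth = tr))
}
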