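# Association testing under the additive genetic model: per-SNP and
# per-score logistic regression, linear trait models, permutation-based
# family-wise correction, the binomial direction-consistency probability,
# Cochran's Q / I-squared heterogeneity, interaction tests and the
# two-sample t comparison of score distributions.

#' Logistic regression of case status on an additive dosage
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (tolerance 1e-8, at most 50 iterations) with optional covariate
#' adjustment; Wald 95% CI on the OR scale.
#'
#' @param outcome binary vector (1 = case)
#' @param dosage numeric vector (risk-allele dosage or score)
#' @param covariates optional numeric matrix / data.frame of adjusters
#' @return one-row data.frame: beta, se, or_, ci_low, ci_high, p, z
#' @export
fit_logistic_additive <- function(outcome, dosage, covariates = NULL) {
  assert_that(length(unique(outcome[!is.na(outcome)])) == 2,
              "outcome must contain both classes")
  assert_that(stats::var(dosage, na.rm = TRUE) > 0,
              "dosage has zero variance")
  df <- data.frame(.y = outcome, .x = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  assert_that(nrow(df) > ncol(df), "need more subjects than parameters")
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) {
    stop(errorCondition("logistic fit did not converge",
                        class = c("cgs_fit_error", "error")))
  }
  co <- summary(fit)$coefficients
  b <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  if (se > 1e3) {
    stop(errorCondition("unstable fit (possible complete separation)",
                        class = c("cgs_fit_error", "error")))
  }
  z <- b / se
  data.frame(beta = b, se = se, or_ = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)), z = z)
}

#' Linear regression of a quantitative trait on an additive dosage
#'
#' Ordinary least squares with optional covariates; t-test p-value for the
#' dosage slope.
#'
#' @inheritParams fit_logistic_additive
#' @param trait numeric response
#' @return one-row data.frame: beta, se, p, t
#' @export
fit_linear_trait <- function(trait, dosage, covariates = NULL) {
  df <- data.frame(.y = trait, .x = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  assert_that(nrow(df) > ncol(df), "need more subjects than parameters")
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    stop(errorCondition("rank-deficient design", class = c("cgs_fit_error", "error")))
  }
  co <- summary(fit)$coefficients
  data.frame(beta = co[".x", "Estimate"], se = co[".x", "Std. Error"],
             p = co[".x", "Pr(>|t|)"], t = co[".x", "t value"])
}

#' Permutation-based multiple-testing correction
#'
#' Case/control labels are permuted B times; at each permutation every SNP
#' is refit and the maximum |Z| across SNPs recorded.  The family-wise
#' adjusted p-value of SNP i is (1 + #\{b: max_j |Z_j(b)| >= |Z_i|\}) /
#' (B + 1); a pointwise (per-SNP) permutation p-value is returned
#' alongside.  Reproducible under a fixed seed.
#'
#' @param outcome binary vector (permuted)
#' @param dosage_matrix subjects x SNPs dosage matrix (mean-imputed or with
#'   NA rows dropped per SNP)
#' @param covariates optional adjusters (kept fixed with the subjects)
#' @param B number of permutations (>= 1)
#' @param seed integer RNG seed
#' @return data.frame per SNP: z_obs, p_perm_fw (family-wise, headline),
#'   p_perm_pointwise
#' @export
permutation_adjust <- function(outcome, dosage_matrix, covariates = NULL,
                               B = 10000L, seed = 1L) {
  assert_that(B >= 1, "B must be >= 1")
  set.seed(as.integer(seed))
  snps <- colnames(dosage_matrix) %||% paste0("snp", seq_len(ncol(dosage_matrix)))
  # raw Wald |Z| per SNP; unlike fit_logistic_additive this never rejects
  # an unstable (separated) relabelling — such fits simply contribute
  # their (near-zero) Wald z to the permutation distribution
  wald_z <- function(y, d, cov) {
    df <- data.frame(.y = y, .x = d)
    if (!is.null(cov)) df <- cbind(df, as.data.frame(cov))
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    abs(co[".x", "Estimate"] / co[".x", "Std. Error"])
  }
  zs <- function(y) {
    vapply(seq_len(ncol(dosage_matrix)), function(j) {
      d <- dosage_matrix[, j]
      ok <- !is.na(d)
      wald_z(y[ok], d[ok],
             if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE])
    }, numeric(1))
  }
  z_obs <- zs(outcome)
  exceed_fw <- numeric(length(z_obs))
  exceed_pt <- numeric(length(z_obs))
  for (b in seq_len(B)) {
    zb <- zs(sample(outcome))
    exceed_fw <- exceed_fw + (max(zb) >= z_obs)
    exceed_pt <- exceed_pt + (zb >= z_obs)
  }
  data.frame(id = snps, z_obs = z_obs,
             p_perm_fw = (1 + exceed_fw) / (B + 1),
             p_perm_pointwise = (1 + exceed_pt) / (B + 1),
             stringsAsFactors = FALSE)
}

#' Binomial probability of direction consistency
#'
#' Exact upper-tail probability that at least \code{n_consistent} of
#' \code{n_total} independent effects point in the reported direction when
#' each direction is a fair coin: P(X >= k), X ~ Binomial(n, 1/2).
#'
#' @param n_consistent,n_total counts with 0 <= n_consistent <= n_total
#' @return exact probability
#' @export
#' @examples
#' binomial_direction_test(12, 14)  # 6.5e-3
binomial_direction_test <- function(n_consistent, n_total) {
  assert_that(n_consistent >= 0 && n_consistent <= n_total,
              "need 0 <= n_consistent <= n_total")
  stats::pbinom(n_consistent - 1, size = n_total, prob = 0.5,
                lower.tail = FALSE)
}

#' Cochran's Q and I-squared heterogeneity of stratum effects
#'
#' Inverse-variance weights w = 1/se^2; Q = sum w (beta - beta_pooled)^2;
#' p from chi-square with k - 1 df; I^2 = max(0, (Q - df)/Q).
#'
#' @param betas,ses aligned numeric vectors of stratum effects (log-OR
#'   scale) and standard errors (> 0), k >= 2 strata
#' @return list: Q, df, p, i2, beta_pooled
#' @export
cochran_q_i2 <- function(betas, ses) {
  assert_that(length(betas) >= 2 && length(betas) == length(ses),
              "need >= 2 strata with matching ses")
  assert_that(all(ses > 0), "all standard errors must be > 0")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  df <- length(betas) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       i2 = max(0, (Q - df) / Q), beta_pooled = pooled)
}

#' Multiplicative interaction between a score and a binary stratum
#'
#' Logistic model with main effects and the product term; the Wald p-value
#' of the product coefficient tests effect-modification.
#'
#' @param outcome binary vector
#' @param cgs numeric score
#' @param stratum_flag binary indicator (both levels must be present)
#' @param covariates optional adjusters
#' @return one-row data.frame for the product term: beta, se, p, z
#' @export
interaction_test <- function(outcome, cgs, stratum_flag, covariates = NULL) {
  assert_that(length(unique(stratum_flag)) == 2,
              "stratum_flag must have both levels populated")
  df <- data.frame(.y = outcome, .s = cgs, .f = stratum_flag)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- stats::glm(.y ~ . + .s:.f, data = df, family = stats::binomial())
  co <- summary(fit)$coefficients
  row <- grep("^\\.s:\\.f", rownames(co))
  b <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
  data.frame(beta = b, se = se, z = b / se,
             p = 2 * stats::pnorm(-abs(b / se)))
}

#' Student's t comparison of score distributions
#'
#' Classical pooled-variance two-sample t-test (not Welch).
#'
#' @param scores_cases,scores_controls numeric vectors, >= 2 values each
#' @return list: t, df, p, mean_cases, mean_controls
#' @export
t_test_scores <- function(scores_cases, scores_controls) {
  assert_that(length(scores_cases) >= 2 && length(scores_controls) >= 2,
              "need >= 2 scores per group")
  tt <- stats::t.test(scores_cases, scores_controls, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_cases = mean(scores_cases), mean_controls = mean(scores_controls))
}

#' Per-SNP association table in the published layout
#'
#' Fits each SNP's additive logistic model (adjusted for the supplied
#' covariates) and assembles the association table: alleles, case/control
#' risk-allele frequencies, OR with 95% CI, p-value and (optionally)
#' permutation-adjusted p-values.
#'
#' @param matrix dosage matrix (NA allowed; subjects with a missing dosage
#'   are dropped SNP-wise)
#' @param panel SNP panel data.frame
#' @param status binary vector (1 = case)
#' @param covariates optional adjusters
#' @param B permutations for the family-wise correction; skipped when 0
#' @param seed RNG seed for permutations
#' @return data.frame mirroring the published association-table columns
#' @export
association_table <- function(matrix, panel, status, covariates = NULL,
                              B = 0L, seed = 1L) {
  qc <- summarize_snp(matrix, panel, status)
  fits <- lapply(colnames(matrix), function(s) {
    d <- matrix[, s]
    ok <- !is.na(d)
    fit_logistic_additive(status[ok], d[ok],
                          if (is.null(covariates)) NULL
                          else covariates[ok, , drop = FALSE])
  })
  fits <- do.call(rbind, fits)
  idx <- match(colnames(matrix), panel$id)
  out <- data.frame(
    chr = panel$chr[idx] %||% NA, snp = colnames(matrix),
    gene = if ("gene" %in% names(panel)) panel$gene[idx] else NA,
    risk_allele = panel$risk_allele[idx],
    nonrisk_allele = panel$nonrisk_allele[idx],
    freq_cases = qc$risk_allele_freq_cases,
    freq_controls = qc$risk_allele_freq_controls,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, fits)
  if (B > 0) {
    pp <- permutation_adjust(status, matrix, covariates, B = B, seed = seed)
    out$p_perm <- pp$p_perm_fw
    out$p_perm_pointwise <- pp$p_perm_pointwise
  }
  out
}
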