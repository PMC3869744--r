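# Genotype quality control: exact Hardy-Weinberg test in controls,
# call rates and allele-frequency summaries.

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test by probability ordering of heterozygote counts:
#' with the allele margin fixed, the p-value is the sum of the conditional
#' probabilities of every heterozygote count whose probability does not
#' exceed that of the observed count.  No mid-p correction.
#'
#' @param n_hom_risk,n_het,n_hom_nonrisk genotype counts (>= 0, not all 0)
#' @return exact p-value in (0, 1]
#' @export
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
hwe_exact_test <- function(n_hom_risk, n_het, n_hom_nonrisk) {
  counts <- c(n_hom_risk, n_het, n_hom_nonrisk)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "genotype counts must be non-negative integers")
  n <- sum(counts)
  assert_that(n >= 1, "at least one subject is required")
  n_r <- 2 * n_hom_risk + n_het     # risk alleles
  n_n <- 2 * n_hom_nonrisk + n_het  # non-risk alleles
  n_minor <- min(n_r, n_n)
  if (n_minor == 0) return(1)      # monomorphic: single configuration

  # possible heterozygote counts share the parity of the minor-allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # conditional probability of each het count given allele margin:
  # P(h) = 2^h n! nr! nn! / [ ((nr-h)/2)! h! ((nn-h)/2)! (2n)! ]
  logp <- hets * log(2) + lgamma(n + 1) -
    lgamma((n_r - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_n - hets) / 2 + 1) +
    lgamma(n_r + 1) + lgamma(n_n + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP QC summary
#'
#' Call rate, risk-allele frequencies by status and the exact
#' Hardy-Weinberg p-value computed in controls only (the sample in which
#' Hardy-Weinberg proportions are expected to hold).
#'
#' @param matrix dosage matrix (subjects x SNPs, risk-allele counts, NA
#'   missing)
#' @param panel SNP panel data.frame; all matrix columns must appear in it
#' @param status binary vector aligned to rows (1 = case, 0 = control)
#' @param call_rate_min,hwe_p_min QC thresholds; failing SNPs are flagged,
#'   not dropped
#' @return data.frame, one row per SNP: call_rate, maf,
#'   risk_allele_freq_cases, risk_allele_freq_controls, hwe_p_controls,
#'   pass_qc
#' @export
summarize_snp <- function(matrix, panel, status,
                          call_rate_min = 0.95, hwe_p_min = 0.01) {
  assert_that(length(status) == nrow(matrix),
              "status must align with matrix rows")
  missing_snps <- setdiff(colnames(matrix), panel$id)
  if (length(missing_snps)) {
    stop(errorCondition(
      paste0("SNP absent from panel: ", paste(missing_snps, collapse = ", ")),
      class = c("cgs_key_error", "error")))
  }
  is_ctrl <- status == 0
  res <- lapply(colnames(matrix), function(s) {
    d <- matrix[, s]
    obs <- !is.na(d)
    raf <- function(x) if (length(x)) sum(x) / (2 * length(x)) else NA_real_
    f_case <- raf(d[obs & status == 1])
    f_ctrl <- raf(d[obs & is_ctrl])
    f_all <- raf(d[obs])
    dc <- d[obs & is_ctrl]
    hwe <- hwe_exact_test(sum(dc == 2), sum(dc == 1), sum(dc == 0))
    data.frame(id = s, call_rate = mean(obs), maf = min(f_all, 1 - f_all),
               risk_allele_freq_cases = f_case,
               risk_allele_freq_controls = f_ctrl,
               hwe_p_controls = hwe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pass_qc <- out$call_rate > call_rate_min & out$hwe_p_controls > hwe_p_min
  rownames(out) <- NULL
  out
}
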