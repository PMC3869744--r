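# Combined genetic score (CGS) construction: mean-dosage imputation,
# unweighted and effect-size-weighted scores, rounding, quartile grouping
# and tail binning.

#' Mean-dosage imputation of missing genotypes
#'
#' Missing dosages at a SNP are replaced by that SNP's mean observed
#' dosage over the combined (case + control) cohort; observed entries are
#' unchanged, so each SNP's mean dosage is preserved exactly.
#'
#' @param matrix dosage matrix (subjects x SNPs, NA missing)
#' @return real-valued matrix with no missing entries
#' @export
impute_mean_dosage <- function(matrix) {
  means <- colMeans(matrix, na.rm = TRUE)
  fully_missing <- colnames(matrix)[!is.finite(means)]
  assert_that(length(fully_missing) == 0,
              paste0("SNP(s) with no observed dosages: ",
                     paste(fully_missing, collapse = ", ")))
  for (j in seq_len(ncol(matrix))) {
    na <- is.na(matrix[, j])
    if (any(na)) matrix[na, j] <- means[j]
  }
  matrix
}

#' Relative-effect weights from per-SNP log odds ratios
#'
#' w_i = beta_i / mean(beta), so the weights average exactly 1 and the
#' weighted score stays on the allele-count scale.  Weights are invariant
#' to rescaling all betas by a common factor.
#'
#' @param betas named vector of per-SNP log ORs, all > 0 (risk-allele
#'   oriented)
#' @return weight vector, mean exactly 1
#' @export
compute_weights <- function(betas) {
  bad <- which(betas <= 0)
  if (length(bad)) {
    who <- if (is.null(names(betas))) bad else names(betas)[bad]
    abort_validation(paste0("non-positive beta (risk allele misoriented?) for: ",
                            paste(who, collapse = ", ")))
  }
  betas / mean(betas)
}

#' Combined genetic score
#'
#' raw score = sum_i w_i x dosage_i; with unit weights this is the plain
#' risk-allele count.  Rounded scores use half-away-from-zero rounding.
#'
#' @param matrix imputed dosage matrix (no missing entries)
#' @param weights per-SNP weight vector, or NULL for the unweighted score
#' @return data.frame: subject_id, raw_score, rounded_score
#' @export
compute_cgs <- function(matrix, weights = NULL) {
  assert_that(!anyNA(matrix), "matrix must be imputed (no missing dosages)")
  if (is.null(weights)) weights <- rep(1, ncol(matrix))
  assert_that(length(weights) == ncol(matrix),
              "weights length must equal the number of SNPs")
  raw <- as.numeric(matrix %*% weights)
  data.frame(subject_id = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
             raw_score = raw, rounded_score = round_half_away(raw),
             stringsAsFactors = FALSE)
}

#' Quartile groups of rounded scores
#'
#' Integer scores are partitioned at cut-points chosen so the cumulative
#' group proportions are nearest to 25/50/75%.  All subjects sharing a
#' rounded score share a quartile, so group sizes may be unequal (or a
#' middle group empty when the score distribution is very concentrated).
#'
#' @param rounded_scores integer vector (>= 4 subjects)
#' @return integer vector of quartile labels 1..4
#' @export
assign_quartiles <- function(rounded_scores) {
  assert_that(length(rounded_scores) >= 4, "need >= 4 subjects")
  u <- sort(unique(rounded_scores))
  assert_that(length(u) >= 2, "constant scores cannot be grouped into quartiles")
  cum <- cumsum(tabulate(match(rounded_scores, u))) / length(rounded_scores)
  # for each target k/4 pick the cut score with nearest cumulative
  # proportion (ties to the smaller score); monotone targets give
  # monotone cuts
  cuts <- vapply(1:3, function(k) u[which.min(abs(cum - k / 4))], numeric(1))
  q <- 1L + (rounded_scores > cuts[1]) + (rounded_scores > cuts[2]) +
    (rounded_scores > cuts[3])
  as.integer(q)
}

#' Tail-collapsed score bins
#'
#' Bins \{<= lower, lower+1, ..., upper-1, >= upper\}: both tail bins are
#' inclusive, interior scores keep their own bin.
#'
#' @param rounded_scores integer vector
#' @param lower_tail_cut,upper_tail_cut integer cut scores,
#'   lower < upper, both within the observed range
#' @return ordered factor of bin labels
#' @export
bin_scores <- function(rounded_scores, lower_tail_cut, upper_tail_cut) {
  assert_that(lower_tail_cut < upper_tail_cut, "cuts must satisfy lower < upper")
  rng <- range(rounded_scores)
  assert_that(lower_tail_cut >= rng[1] && upper_tail_cut <= rng[2],
              "cuts must lie within the observed score range")
  interior <- if (upper_tail_cut - lower_tail_cut >= 2) {
    as.character(seq(lower_tail_cut + 1, upper_tail_cut - 1))
  } else character(0)
  levels <- c(paste0("<=", lower_tail_cut), interior,
              paste0(">=", upper_tail_cut))
  lab <- ifelse(rounded_scores <= lower_tail_cut, levels[1],
                ifelse(rounded_scores >= upper_tail_cut,
                       levels[length(levels)],
                       as.character(rounded_scores)))
  factor(lab, levels = levels, ordered = TRUE)
}

#' Full score set: raw, rounded, quartile, bin
#'
#' @inheritParams compute_cgs
#' @param lower_tail_cut,upper_tail_cut optional bin cuts; bins omitted
#'   when NULL
#' @return data.frame with subject_id, raw_score, rounded_score, quartile
#'   and (optionally) score_bin
#' @export
score_set <- function(matrix, weights = NULL,
                      lower_tail_cut = NULL, upper_tail_cut = NULL) {
  s <- compute_cgs(matrix, weights)
  s$quartile <- assign_quartiles(s$rounded_score)
  if (!is.null(lower_tail_cut) && !is.null(upper_tail_cut)) {
    s$score_bin <- bin_scores(s$rounded_score, lower_tail_cut, upper_tail_cut)
  }
  s
}
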