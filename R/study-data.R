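# Published summary data from the Hong Kong Chinese type 2 diabetes
# case-control study (5882 cases / 2569 controls) that this package's
# analysis chain reproduces in structure: the 14-SNP beta-cell panel with
# risk-allele frequencies and odds ratios, and the published five-category
# reclassification cross-tabulations.  These printed tables are inputs to
# the arithmetic checks and to the synthetic cohort generator; no
# individual-level data are included.

#' SNP panel of 14 beta-cell-function loci with published study estimates
#'
#' Per-SNP metadata for the 14 type 2 diabetes susceptibility variants:
#' literature risk and non-risk alleles, published risk-allele frequencies
#' in cases and controls, and the published allelic odds ratio (adjusted
#' for sex, age and BMI).  The \code{significant} flag marks the 8 SNPs
#' with P < 0.05 that enter the combined genetic score.
#'
#' @param significant_only logical; if \code{TRUE} (default) return only the
#'   8 score SNPs, otherwise all 14.
#' @return data.frame with columns \code{id}, \code{chr}, \code{gene},
#'   \code{risk_allele}, \code{nonrisk_allele}, \code{freq_cases},
#'   \code{freq_controls}, \code{or_published}, \code{significant}.
#' @export
#' @examples
#' study_snp_panel()
study_snp_panel <- function(significant_only = TRUE) {
  panel <- data.frame(
    id = c("rs10923931", "rs4607103", "rs4402960", "rs734312", "rs7756992",
           "rs864745", "rs13266634", "rs10811661", "rs1111875", "rs7903146",
           "rs2237892", "rs5219", "rs7961581", "rs4430796"),
    chr = c("1", "3", "3", "4", "6", "7", "8", "9", "10", "10", "11", "11",
            "12", "17"),
    gene = c("NOTCH2", "ADAMTS9", "IGF2BP2", "WFS1", "CDKAL1", "JAZF1",
             "SLC30A8", "CDKN2A/B", "HHEX", "TCF7L2", "KCNQ1", "KCNJ11",
             "TSPAN8/LGR5", "HNF1B"),
    risk_allele = c("T", "C", "T", "A", "G", "A", "C", "T", "G", "T", "C",
                    "T", "C", "G"),
    nonrisk_allele = c("G", "T", "G", "G", "A", "G", "T", "C", "A", "C",
                       "T", "C", "T", "A"),
    freq_cases = c(0.037, 0.680, 0.251, 0.817, 0.506, 0.783, 0.568, 0.618,
                   0.302, 0.034, 0.719, 0.342, 0.228, 0.267),
    freq_controls = c(0.029, 0.691, 0.230, 0.799, 0.459, 0.771, 0.527,
                      0.579, 0.274, 0.019, 0.656, 0.325, 0.229, 0.254),
    or_published = c(1.24, 0.97, 1.16, 1.14, 1.22, 1.08, 1.22, 1.21, 1.22,
                     2.09, 1.45, 1.07, 0.98, 1.09),
    stringsAsFactors = FALSE
  )
  panel$significant <- panel$id %in% c("rs4402960", "rs734312", "rs7756992",
                                       "rs13266634", "rs10811661",
                                       "rs1111875", "rs7903146", "rs2237892")
  if (significant_only) panel[panel$significant, , drop = FALSE] else panel
}

#' Published study sample sizes and design constants
#'
#' @return list with \code{n_case}, \code{n_control} (genotyped),
#'   \code{n_case_analysis}, \code{n_control_analysis} (complete-case N of
#'   the reclassification tables), assumed population prevalence
#'   \code{prevalence}, overall \code{missing_rate} of genotypes, and the
#'   risk-category bounds used for reclassification.
#' @export
study_design <- function() {
  list(n_case = 5882L, n_control = 2569L,
       n_case_analysis = 5820L, n_control_analysis = 2560L,
       prevalence = 0.10, missing_rate = 0.027,
       risk_bounds = c(0.05, 0.10, 0.15, 0.20))
}

#' Published five-category reclassification cross-tabulations
#'
#' The 5x5 cross-tabulations of predicted-risk categories without the
#' combined genetic score (rows) against categories with the score
#' (columns), separately for T2D cases and healthy controls, as published
#' for the unweighted and weighted scores.  Categories are
#' <5%, 5-<10%, 10-<15%, 15-<20%, >=20%.
#'
#' @param score one of \code{"unweighted"}, \code{"weighted"}
#' @return list with 5x5 integer matrices \code{cases} and \code{controls}
#' @export
published_reclassification <- function(score = c("unweighted", "weighted")) {
  score <- match.arg(score)
  lab <- c("<5%", "5-<10%", "10-<15%", "15-<20%", ">=20%")
  m <- function(...) matrix(c(...), nrow = 5, byrow = TRUE,
                            dimnames = list(without = lab, with = lab))
  if (score == "unweighted") {
    list(
      cases = m(248, 106,   0,   0,    0,
                129, 679, 290,  73,    0,
                  0, 278, 500, 316,  134,
                  0,  34, 240, 307,  361,
                  0,   0,  61, 225, 1839),
      controls = m(1151,  41,   0,  0,   0,
                    100, 224,  64,  5,   0,
                      0, 118, 132, 68,  13,
                      0,  11,  79, 80,  59,
                      0,   0,  20, 66, 329)
    )
  } else {
    list(
      cases = m(252,  93,   9,   0,    0,
                139, 678, 250,  87,   17,
                  0, 307, 460, 292,  169,
                  0,  25, 261, 283,  373,
                  0,   0,  69, 235, 1821),
      controls = m(1151,  41,   0,  0,   0,
                    114, 207,  64,  8,   0,
                      1, 128, 122, 66,  14,
                      0,  19,  73, 72,  65,
                      0,   0,  34, 68, 313)
    )
  }
}
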