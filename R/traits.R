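# Derived clinical traits and preprocessing transforms.

#' Homeostasis-model indices of insulin resistance and beta-cell function
#'
#' HOMA-IR = FPI[mU/l] x FPG[mmol/l] / 22.5;
#' HOMA-beta = FPI x 20 / (FPG - 3.5).
#' HOMA-beta is undefined at FPG <= 3.5 mmol/l and is returned as NA there.
#'
#' @param fpg fasting plasma glucose, mmol/l (> 0)
#' @param fpi_mU_per_l fasting plasma insulin, mU/l (>= 0)
#' @return list with vectors \code{homa_ir} and \code{homa_beta}
#' @export
#' @examples
#' homa_indices(4.7, 10)
homa_indices <- function(fpg, fpi_mU_per_l) {
  assert_that(all(fpg > 0, na.rm = TRUE), "fpg must be > 0")
  assert_that(all(fpi_mU_per_l >= 0, na.rm = TRUE), "fpi must be >= 0")
  homa_ir <- fpi_mU_per_l * fpg / 22.5
  homa_beta <- ifelse(fpg > 3.5, fpi_mU_per_l * 20 / (fpg - 3.5), NA_real_)
  n_undef <- sum(fpg <= 3.5, na.rm = TRUE)
  if (n_undef > 0) {
    message(sprintf("HOMA-beta undefined (FPG <= 3.5 mmol/l) for %d value(s); set to NA",
                    n_undef))
  }
  list(homa_ir = homa_ir, homa_beta = homa_beta)
}

#' Estimated GFR by the abbreviated MDRD formula with Chinese coefficient
#'
#' eGFR = 186 x (Scr x 0.011)^-1.154 x age^-0.203 x 0.742[if female]
#' x 1.233[if Chinese], with serum creatinine in umol/l.
#'
#' @param scr serum creatinine, umol/l (> 0)
#' @param age years (> 0)
#' @param female,chinese logical flags
#' @return eGFR in ml/min/1.73m^2
#' @export
egfr_mdrd_chinese <- function(scr, age, female, chinese = TRUE) {
  assert_that(all(scr > 0, na.rm = TRUE), "scr must be > 0")
  assert_that(all(age > 0, na.rm = TRUE), "age must be > 0")
  186 * (scr * 0.011)^-1.154 * age^-0.203 *
    ifelse(female, 0.742, 1) * ifelse(chinese, 1.233, 1)
}

#' Winsorize at mean +/- 4 SD within strata
#'
#' Single pass: the mean and SD are computed once per stratum before any
#' replacement; values beyond mean +/- 4 SD are set to the nearest bound.
#' Missing values are preserved.
#'
#' @param values numeric vector (may contain NA)
#' @param groups stratum labels aligned with \code{values}; a single
#'   stratum if omitted
#' @param k number of SDs defining the bounds (default 4)
#' @return winsorized vector, same length and order
#' @export
winsorize_4sd <- function(values, groups = NULL, k = 4) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  assert_that(length(groups) == length(values),
              "groups must align with values")
  out <- values
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- values[idx]
    obs <- v[!is.na(v)]
    assert_that(length(obs) >= 2,
                sprintf("stratum '%s' needs >= 2 non-missing values", g))
    m <- mean(obs); s <- stats::sd(obs)
    out[idx] <- pmin(pmax(v, m - k * s), m + k * s)
  }
  out
}

#' Derived phenotype flags and transformed traits
#'
#' Central obesity: waist >= 90 cm (male) or >= 80 cm (female), thresholds
#' inclusive.  Overweight: BMI >= 25 kg/m^2.  Fasting insulin is converted
#' pmol/l -> mU/l with the conventional divisor 6.0 (a convention; the
#' HOMA formulas take mU/l while assays commonly report pmol/l).  FPI,
#' HOMA-IR and HOMA-beta are natural-log transformed.
#'
#' @param sex_male logical
#' @param waist cm
#' @param bmi kg/m^2
#' @param fpg fasting plasma glucose, mmol/l
#' @param fpi_pmol_l fasting plasma insulin, pmol/l
#' @return data.frame with central_obesity, overweight, fpi_mU_per_l,
#'   homa_ir, homa_beta and the log-transformed columns
#' @export
derive_flags <- function(sex_male, waist, bmi, fpg, fpi_pmol_l) {
  central_obesity <- ifelse(sex_male, waist >= 90, waist >= 80)
  overweight <- bmi >= 25
  fpi <- fpi_pmol_l / 6.0
  h <- homa_indices(fpg, fpi)
  safe_log <- function(x, name) {
    bad <- !is.na(x) & x <= 0
    assert_that(!any(bad), sprintf("%s must be positive for log transform", name))
    log(x)
  }
  data.frame(central_obesity = central_obesity, overweight = overweight,
             fpi_mU_per_l = fpi, homa_ir = h$homa_ir, homa_beta = h$homa_beta,
             log_fpi = safe_log(fpi, "FPI"),
             log_homa_ir = safe_log(h$homa_ir, "HOMA-IR"),
             log_homa_beta = safe_log(h$homa_beta, "HOMA-beta"))
}
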