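# Risk prediction and reclassification: prevalence-adjusted predicted
# risks from case-control logistic models, pair-counting AUC, five-category
# risk stratification, reclassification cross-tabulations and the
# categorical net reclassification improvement (NRI).

#' Prevalence adjustment of a case-control logistic intercept
#'
#' Adds log[rho/(1-rho) x n_control/n_case] to the intercept so that
#' fitted probabilities estimate absolute population risk at prevalence
#' rho rather than the case-control sampling fraction.
#'
#' @param beta0 fitted intercept
#' @param rho assumed population prevalence, strictly in (0,1)
#' @param n_control,n_case sample sizes (>= 1)
#' @return adjusted intercept
#' @export
#' @examples
#' adjust_intercept(0, 0.1, 2569, 5882)
adjust_intercept <- function(beta0, rho, n_control, n_case) {
  assert_that(is_proportion(rho), "rho must lie strictly in (0, 1)")
  assert_that(n_control >= 1 && n_case >= 1, "counts must be >= 1")
  beta0 + log(rho / (1 - rho) * n_control / n_case)
}

#' Area under the ROC curve by pair counting
#'
#' Mann-Whitney estimator: the proportion of case-control pairs in which
#' the case has the higher predicted risk, ties counted one half.
#'
#' @param risks_cases,risks_controls numeric vectors, both nonempty
#' @return AUC in [0, 1]
#' @export
auc_mann_whitney <- function(risks_cases, risks_controls) {
  n1 <- length(risks_cases); n0 <- length(risks_controls)
  assert_that(n1 >= 1 && n0 >= 1, "both groups must be nonempty")
  r <- rank(c(risks_cases, risks_controls), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil standard error of the AUC
auc_se_hanley <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}

#' AUC with an asymptotic 95% confidence interval
#'
#' @inheritParams auc_mann_whitney
#' @return list: auc, se (Hanley-McNeil), ci (length-2, clipped to [0,1])
#' @export
auc_with_ci <- function(risks_cases, risks_controls) {
  a <- auc_mann_whitney(risks_cases, risks_controls)
  se <- auc_se_hanley(a, length(risks_cases), length(risks_controls))
  list(auc = a, se = se,
       ci = c(max(0, a - 1.96 * se), min(1, a + 1.96 * se)))
}

#' Five-category risk stratification
#'
#' Default categories <5%, 5-<10%, 10-<15%, 15-<20%, >=20%: half-open
#' intervals with inclusive lower bounds from the second category upward.
#'
#' @param risk predicted risks in [0, 1]
#' @param bounds increasing cut-points in (0, 1)
#' @return integer categories 1..(length(bounds)+1)
#' @export
categorize_risk <- function(risk, bounds = c(0.05, 0.10, 0.15, 0.20)) {
  assert_that(all(risk >= 0 & risk <= 1, na.rm = TRUE),
              "risks must lie in [0, 1]")
  assert_that(all(diff(bounds) > 0), "bounds must be strictly increasing")
  findInterval(risk, bounds) + 1L
}

#' Reclassification cross-tabulations by outcome group
#'
#' Separate k x k tables of baseline-model categories (rows) against
#' updated-model categories (columns) for cases and controls; movements
#' strictly above the diagonal are "up", strictly below "down".
#'
#' @param cats_without,cats_with aligned integer category vectors
#' @param status binary vector (1 = case)
#' @param n_categories number of categories (default 5)
#' @return object of class \code{cgs_reclass}: tables, up/down counts and
#'   proportions per group, net per-group proportions
#' @export
reclassification_table <- function(cats_without, cats_with, status,
                                   n_categories = 5L) {
  assert_that(length(cats_without) == length(cats_with) &&
                length(cats_with) == length(status),
              "category and status vectors must be aligned")
  tab <- function(keep) {
    table(factor(cats_without[keep], levels = seq_len(n_categories)),
          factor(cats_with[keep], levels = seq_len(n_categories)))
  }
  res <- list(table_cases = unclass(tab(status == 1)),
              table_controls = unclass(tab(status == 0)))
  reclass_from_tables(res$table_cases, res$table_controls)
}

#' Reclassification summary from a pair of published-style tables
#'
#' Accepts pre-tabulated k x k count matrices (cases and controls) and
#' derives the up/down counts and signed net proportions per group.
#'
#' @param table_cases,table_controls square count matrices with rows =
#'   baseline categories, columns = updated categories
#' @return object of class \code{cgs_reclass}
#' @export
reclass_from_tables <- function(table_cases, table_controls) {
  stopifnot(nrow(table_cases) == ncol(table_cases),
            all(dim(table_cases) == dim(table_controls)))
  up <- function(m) sum(m[upper.tri(m)])
  down <- function(m) sum(m[lower.tri(m)])
  n_case <- sum(table_cases); n_ctrl <- sum(table_controls)
  assert_that(n_case > 0 && n_ctrl > 0, "both group tables must be populated")
  out <- list(
    table_cases = table_cases, table_controls = table_controls,
    n_case = n_case, n_control = n_ctrl,
    up_case = up(table_cases), down_case = down(table_cases),
    up_control = up(table_controls), down_control = down(table_controls)
  )
  out$p_up_case <- out$up_case / n_case
  out$p_down_case <- out$down_case / n_case
  out$p_up_control <- out$up_control / n_ctrl
  out$p_down_control <- out$down_control / n_ctrl
  out$net_case <- out$p_up_case - out$p_down_case
  out$net_control <- out$p_down_control - out$p_up_control
  out$n_reclassified <- out$up_case + out$down_case +
    out$up_control + out$down_control
  class(out) <- "cgs_reclass"
  out
}

#' Categorical net reclassification improvement
#'
#' NRI = (P_up - P_down | cases) + (P_down - P_up | controls).  The
#' asymptotic SE is sqrt[(p_up,case + p_down,case)/n_case +
#' (p_up,ctrl + p_down,ctrl)/n_ctrl]; alternatively a seeded bootstrap
#' over the cell counts.
#'
#' @param reclass a \code{cgs_reclass} object
#' @param ci_method \code{"asymptotic"} (default) or \code{"bootstrap"}
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed bootstrap seed
#' @return list: nri, se, ci, p, net_case, net_control
#' @export
nri <- function(reclass, ci_method = c("asymptotic", "bootstrap"),
                n_boot = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  est <- reclass$net_case + reclass$net_control
  se_asym <- sqrt((reclass$p_up_case + reclass$p_down_case) / reclass$n_case +
                    (reclass$p_up_control + reclass$p_down_control) /
                    reclass$n_control)
  if (ci_method == "asymptotic") {
    se <- se_asym
    ci <- est + c(-1.96, 1.96) * se
  } else {
    set.seed(as.integer(seed))
    boot_group <- function(m, n) {
      # resample subjects within a group by multinomial draw over cells
      stats::rmultinom(n_boot, size = n, prob = as.vector(m) / n)
    }
    bc <- boot_group(reclass$table_cases, reclass$n_case)
    bk <- boot_group(reclass$table_controls, reclass$n_control)
    k <- nrow(reclass$table_cases)
    upm <- as.vector(upper.tri(matrix(0, k, k)))
    dnm <- as.vector(lower.tri(matrix(0, k, k)))
    stat <- (colSums(bc[upm, , drop = FALSE]) -
               colSums(bc[dnm, , drop = FALSE])) / reclass$n_case +
      (colSums(bk[dnm, , drop = FALSE]) -
         colSums(bk[upm, , drop = FALSE])) / reclass$n_control
    se <- stats::sd(stat)
    ci <- unname(stats::quantile(stat, c(0.025, 0.975)))
  }
  # degenerate case: nobody reclassified in either group
  z <- if (se_asym > 0) est / se_asym else 0
  list(nri = est, se = se, ci = ci, p = 2 * stats::pnorm(-abs(z)),
       net_case = reclass$net_case, net_control = reclass$net_control)
}

#' Fit the three risk-prediction models
#'
#' Model 1: clinical covariates only (sex, age, BMI); model 2: the
#' combined genetic score only; model 3: clinical covariates plus the
#' score.  All three share the same prevalence adjustment of the intercept
#' and are fitted in-sample on complete cases.
#'
#' @param status binary vector (1 = case)
#' @param clinical data.frame of clinical covariates
#' @param score numeric combined genetic score
#' @param prevalence assumed population prevalence (default 0.10)
#' @return list of three fits (\code{clinical}, \code{cgs_only},
#'   \code{clinical_plus_cgs}); each holds coefficients,
#'   intercept_adjustment, predicted risks, log-likelihood and AUC with CI
#' @export
fit_risk_models <- function(status, clinical, score, prevalence = 0.10) {
  ok <- stats::complete.cases(clinical) & !is.na(score) & !is.na(status)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("excluding %d subject(s) with incomplete covariates", n_excluded))
  }
  status <- status[ok]
  clinical <- clinical[ok, , drop = FALSE]
  score <- score[ok]
  n_case <- sum(status == 1); n_ctrl <- sum(status == 0)

  fit_one <- function(design) {
    fit <- stats::glm(status ~ ., data = design, family = stats::binomial())
    adj <- adjust_intercept(0, prevalence, n_ctrl, n_case)
    lp <- stats::predict(fit, type = "link") + adj
    risk <- stats::plogis(lp)
    a <- auc_with_ci(risk[status == 1], risk[status == 0])
    list(coefficients = stats::coef(fit),
         vcov = stats::vcov(fit),
         intercept_adjustment = adj,
         logLik = as.numeric(stats::logLik(fit)),
         predicted_risk = risk, auc = a$auc, auc_se = a$se, auc_ci = a$ci,
         glm = fit)
  }
  list(
    clinical = fit_one(clinical),
    cgs_only = fit_one(data.frame(cgs = score)),
    clinical_plus_cgs = fit_one(cbind(clinical, cgs = score)),
    status = status, n_case = n_case, n_control = n_ctrl,
    n_excluded = n_excluded, prevalence = prevalence
  )
}

#' Predicted absolute risk for new subjects
#'
#' Inverse-logit of the prevalence-adjusted linear predictor of a fit
#' produced by \code{\link{fit_risk_models}}.
#'
#' @param fit one element of a \code{fit_risk_models} result
#' @param newdata data.frame with the model's covariates
#' @return predicted risks in (0, 1)
#' @export
predicted_risk <- function(fit, newdata) {
  vars <- names(fit$coefficients)[-1]
  plain <- setdiff(vars, names(newdata))
  assert_that(length(plain) == 0,
              paste0("missing covariate(s): ", paste(plain, collapse = ", ")))
  lp <- stats::predict(fit$glm, newdata = newdata, type = "link") +
    fit$intercept_adjustment
  stats::plogis(lp)
}

#' End-to-end reclassification analysis of adding the score
#'
#' Fits the clinical and clinical-plus-score models, categorises the
#' prevalence-adjusted risks, cross-tabulates and returns the NRI.
#'
#' @inheritParams fit_risk_models
#' @param bounds risk-category cut-points
#' @param ci_method forwarded to \code{\link{nri}}
#' @return list: models, reclass (a \code{cgs_reclass}), nri
#' @export
reclassification_analysis <- function(status, clinical, score,
                                      prevalence = 0.10,
                                      bounds = c(0.05, 0.10, 0.15, 0.20),
                                      ci_method = "asymptotic") {
  models <- fit_risk_models(status, clinical, score, prevalence)
  cw <- categorize_risk(models$clinical$predicted_risk, bounds)
  cn <- categorize_risk(models$clinical_plus_cgs$predicted_risk, bounds)
  rc <- reclassification_table(cw, cn, models$status,
                               n_categories = length(bounds) + 1L)
  list(models = models, reclass = rc, nri = nri(rc, ci_method = ci_method))
}
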