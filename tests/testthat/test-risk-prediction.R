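# Risk prediction: prevalence adjustment, AUC, risk categories,
# reclassification tables and NRI

test_that("intercept adjustment equals log[rho/(1-rho) x n_ctrl/n_case]", {
  expect_equal(adjust_intercept(0, 0.5, 1000, 1000), 0)
  expect_equal(adjust_intercept(0, 0.1, 2569, 5882),
               log(0.1 / 0.9 * 2569 / 5882))
  expect_equal(adjust_intercept(0, 0.1, 2569, 5882), -3.026, tolerance = 1e-3)
  expect_equal(adjust_intercept(1.5, 0.3, 10, 10), 1.5 + log(0.3 / 0.7))
  # rho equal to the sample case fraction leaves the intercept unchanged
  expect_equal(adjust_intercept(-2, 5882 / 8451, 2569, 5882), -2)
  expect_error(adjust_intercept(0, 0, 10, 10), class = "cgs_validation_error")
  expect_error(adjust_intercept(0, 1, 10, 10), class = "cgs_validation_error")
})

test_that("AUC pair counting matches brute-force enumeration with half ties", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc_mann_whitney(rep(0.3, 5), rep(0.3, 7)), 0.5)
  expect_equal(auc_mann_whitney(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(4)
  for (r in 1:15) {
    cases <- round(runif(11), 2)   # rounding forces some ties
    ctrls <- round(runif(9), 2)
    expect_equal(auc_mann_whitney(cases, ctrls), auc_oracle(cases, ctrls))
  }
  expect_error(auc_mann_whitney(numeric(0), 1), class = "cgs_validation_error")
})

test_that("auc(score) + auc(-score) = 1 on tie-free data", {
  set.seed(6)
  a <- rnorm(40); b <- rnorm(30)
  expect_equal(auc_mann_whitney(a, b) + auc_mann_whitney(-a, -b), 1)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  risk <- runif(200)
  status <- rbinom(200, 1, risk)
  ours <- auc_mann_whitney(risk[status == 1], risk[status == 0])
  theirs <- as.numeric(pROC::auc(pROC::roc(status, risk, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("risk categories use inclusive lower bounds from category 2", {
  expect_equal(categorize_risk(0.049), 1L)
  expect_equal(categorize_risk(0.05), 2L)
  expect_equal(categorize_risk(0.0999), 2L)
  expect_equal(categorize_risk(0.10), 3L)
  expect_equal(categorize_risk(0.20), 5L)
  expect_equal(categorize_risk(c(0, 1)), c(1L, 5L))
  expect_error(categorize_risk(1.2), class = "cgs_validation_error")
})

test_that("reclassification tables conserve margins and count movements", {
  # identical categories -> purely diagonal
  cats <- c(1, 2, 3, 4, 5, 3, 2)
  status <- c(1, 1, 1, 0, 0, 0, 1)
  rc <- reclassification_table(cats, cats, status)
  expect_equal(rc$up_case + rc$down_case + rc$up_control + rc$down_control, 0)
  expect_true(all(rc$table_cases[upper.tri(rc$table_cases)] == 0))

  # 3-case toy (1->2 up, 2->2 stay, 3->1 down) plus one unmoved control
  rc2 <- reclassification_table(c(1, 2, 3, 2), c(2, 2, 1, 2), c(1, 1, 1, 0),
                                n_categories = 3)
  expect_equal(rc2$up_case, 1)
  expect_equal(rc2$down_case, 1)
  expect_equal(rc2$up_control + rc2$down_control, 0)

  # margins: row sums equal baseline category counts
  set.seed(10)
  cw <- sample(1:5, 300, replace = TRUE)
  cn <- pmin(5, pmax(1, cw + sample(-1:1, 300, replace = TRUE)))
  st <- rbinom(300, 1, 0.5)
  rc3 <- reclassification_table(cw, cn, st)
  expect_equal(rowSums(rc3$table_cases),
               as.vector(table(factor(cw[st == 1], levels = 1:5))),
               ignore_attr = TRUE)
  expect_equal(colSums(rc3$table_controls),
               as.vector(table(factor(cn[st == 0], levels = 1:5))),
               ignore_attr = TRUE)
  expect_equal(sum(rc3$table_cases) + sum(rc3$table_controls), 300)
  expect_error(reclassification_table(1:3, 1:2, c(1, 0, 1)),
               class = "cgs_validation_error")
})

test_that("published cross-tabulations reproduce the printed NRI decomposition", {
  t4 <- published_reclassification("unweighted")
  rc <- reclass_from_tables(t4$cases, t4$controls)
  expect_equal(rc$up_case, 1280)
  expect_equal(rc$down_case, 967)
  expect_equal(rc$up_control, 250)
  expect_equal(rc$down_control, 394)
  res <- nri(rc)
  expect_equal(100 * res$net_case, 5.38, tolerance = 0.005)
  expect_equal(100 * res$net_control, 5.63, tolerance = 0.005)
  expect_equal(100 * res$nri, 11.0, tolerance = 0.05)
  expect_equal(res$nri, rc$net_case + rc$net_control)

  t5 <- published_reclassification("weighted")
  res5 <- nri(reclass_from_tables(t5$cases, t5$controls))
  expect_equal(100 * res5$net_case, 4.36, tolerance = 0.005)
  expect_equal(100 * res5$net_control, 6.99, tolerance = 0.005)
  expect_equal(100 * res5$nri, 11.4, tolerance = 0.05)
})

test_that("NRI is order-invariant and zero on diagonal tables", {
  m <- diag(c(5, 6, 7, 8, 9))
  rc <- reclass_from_tables(m, m)
  expect_equal(nri(rc)$nri, 0)
  set.seed(20)
  cw <- sample(1:5, 200, replace = TRUE)
  cn <- sample(1:5, 200, replace = TRUE)
  st <- rbinom(200, 1, 0.4)
  ord <- sample(200)
  r1 <- nri(reclassification_table(cw, cn, st))
  r2 <- nri(reclassification_table(cw[ord], cn[ord], st[ord]))
  expect_equal(r1, r2)
})

test_that("bootstrap NRI interval is seeded and brackets the estimate", {
  t4 <- published_reclassification("unweighted")
  rc <- reclass_from_tables(t4$cases, t4$controls)
  b1 <- nri(rc, ci_method = "bootstrap", n_boot = 500, seed = 42)
  b2 <- nri(rc, ci_method = "bootstrap", n_boot = 500, seed = 42)
  expect_identical(b1, b2)
  expect_lt(b1$ci[1], b1$nri)
  expect_gt(b1$ci[2], b1$nri)
})

test_that("three prediction models share the adjustment and nest in likelihood", {
  cfg <- simulation_config(n_case = 1200, n_control = 600)
  ch <- simulate_cohort(cfg, seed = 13)
  s <- compute_cgs(impute_mean_dosage(ch$genotypes))
  clin <- data.frame(sex = ch$phenotypes$sex, age = ch$phenotypes$age,
                     bmi = ch$phenotypes$bmi)
  fits <- fit_risk_models(ch$phenotypes$status, clin, s$rounded_score,
                          prevalence = 0.10)
  expect_gte(fits$clinical_plus_cgs$logLik, fits$clinical$logLik)
  expect_gt(fits$cgs_only$auc, 0.5)
  expect_true(all(fits$clinical$predicted_risk > 0 &
                    fits$clinical$predicted_risk < 1))
  expect_equal(fits$clinical$intercept_adjustment,
               fits$cgs_only$intercept_adjustment)
  # prevalence equal to the sample case fraction leaves risks at the
  # unadjusted fitted probabilities
  fits2 <- fit_risk_models(ch$phenotypes$status, clin, s$rounded_score,
                           prevalence = 1200 / 1800)
  raw <- fitted(fits2$clinical$glm)
  expect_equal(unname(fits2$clinical$predicted_risk), unname(raw),
               tolerance = 1e-10)
})

test_that("predicted_risk is monotone and validates covariates", {
  set.seed(15)
  n <- 400
  clin <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 10),
                     bmi = rnorm(n, 24, 3))
  y <- rbinom(n, 1, plogis(-5 + 0.08 * clin$age))
  fits <- fit_risk_models(y, clin, rnorm(n), prevalence = 0.1)
  nd <- data.frame(sex = 0, age = c(40, 60), bmi = 24)
  r <- predicted_risk(fits$clinical, nd)
  expect_true(all(r > 0 & r < 1))
  expect_gt(r[2], r[1])  # age has a positive coefficient here
  expect_error(predicted_risk(fits$clinical, data.frame(sex = 0, age = 50)),
               class = "cgs_validation_error")
})
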