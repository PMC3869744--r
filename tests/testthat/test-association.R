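# Association testing: logistic/linear fits, permutation correction,
# direction consistency, heterogeneity, interaction, t-test

test_that("logistic fit on a collapsed 2x2 design equals the cross-product OR", {
  # exposed cases 20, unexposed cases 10; exposed controls 10, unexposed 20
  y <- c(rep(1, 30), rep(0, 30))
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  f <- fit_logistic_additive(y, x)
  expect_equal(f$or_, (20 * 20) / (10 * 10), tolerance = 1e-6)
  expect_error(fit_logistic_additive(y, rep(1, 60)),
               class = "cgs_validation_error")
  expect_error(fit_logistic_additive(rep(1, 10), rnorm(10)),
               class = "cgs_validation_error")
})

test_that("logistic MLE matches a brute-force likelihood maximiser on a toy", {
  y <- c(0, 0, 1, 0, 1, 1)
  x <- c(0, 1, 1, 2, 2, 2)
  f <- fit_logistic_additive(y, x)
  best <- logistic_grid_oracle(y, x)
  expect_equal(f$beta, best[2], tolerance = 1e-3)
  # the implementation's likelihood is no worse than the grid's
  expect_lte(neg_loglik_logistic(coef(glm(y ~ x, family = binomial()))[1],
                                 f$beta, y, x),
             neg_loglik_logistic(best[1], best[2], y, x) + 1e-6)
})

test_that("linear trait fit matches the closed-form normal equations", {
  y <- c(1.1, 1.9, 3.2, 3.8)
  x <- c(1, 2, 3, 4)
  f <- fit_linear_trait(y, x)
  b_closed <- cov(x, y) / var(x)
  expect_equal(f$beta, b_closed)
  # trait identical to dosage -> slope one, SE zero
  f2 <- suppressWarnings(fit_linear_trait(x, x + 0))  # exact fit: se 0
  expect_equal(f2$beta, 1)
  expect_lt(f2$se, 1e-10)
  # orthogonal construction -> slope zero
  x3 <- c(-1, 1, -1, 1); y3 <- c(-1, -1, 1, 1)
  expect_equal(fit_linear_trait(y3, x3)$beta, 0)
  expect_error(fit_linear_trait(y, cbind(x)[, 1], covariates = data.frame(z = x)),
               class = "cgs_fit_error")
})

test_that("binomial direction probability matches pmf summation for all n <= 20", {
  expect_equal(binomial_direction_test(12, 14), 106 / 16384)
  expect_equal(binomial_direction_test(12, 14), 6.5e-3, tolerance = 1e-2)
  expect_equal(binomial_direction_test(0, 14), 1)
  expect_equal(binomial_direction_test(14, 14), 0.5^14)
  for (n in 1:20) {
    for (k in 0:n) {
      direct <- sum(choose(n, k:n)) * 0.5^n
      expect_equal(binomial_direction_test(k, n), direct, tolerance = 1e-12)
    }
  }
  expect_error(binomial_direction_test(15, 14), class = "cgs_validation_error")
})

test_that("permutation correction is exact-seeded and matches exhaustive enumeration", {
  set.seed(2)
  n <- 8
  y <- rep(c(1L, 0L), each = 4)
  g <- matrix(sample(0:2, n * 3, replace = TRUE), n, 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  g[, 1] <- c(2, 2, 2, 1, 0, 0, 1, 0)  # ensure variation and signal
  # independent statistic: plain glm Wald z, tolerant of separation
  stat_fun <- function(yy) {
    vapply(1:3, function(j) {
      co <- summary(suppressWarnings(glm(yy ~ g[, j],
                                         family = binomial())))$coefficients
      abs(co[2, 1] / co[2, 2])
    }, numeric(1))
  }
  res1 <- permutation_adjust(y, g, B = 400, seed = 99)
  res2 <- permutation_adjust(y, g, B = 400, seed = 99)
  expect_identical(res1, res2)

  exact <- perm_oracle(y, g, stat_fun)
  # Monte-Carlo p within 3 binomial SEs of the exhaustive value
  for (j in 1:3) {
    se <- sqrt(exact[j] * (1 - exact[j]) / 400) + 1 / 400
    expect_lt(abs(res1$p_perm_fw[j] - exact[j]), 3 * se + 0.01)
  }
  # family-wise p never below pointwise p
  expect_true(all(res1$p_perm_fw >= res1$p_perm_pointwise - 1e-12))
  expect_error(permutation_adjust(y, g, B = 0), class = "cgs_validation_error")
})

test_that("Cochran's Q and I2 follow the inverse-variance definitions", {
  h0 <- cochran_q_i2(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.05))
  expect_equal(h0$Q, 0)
  expect_equal(h0$i2, 0)
  expect_equal(h0$p, 1)
  # published identity: I2 = 0.7846 with df 1 implies Q = 4.643, p = 0.0312
  Q <- 1 / (1 - 0.7846)
  expect_equal(Q, 4.643, tolerance = 1e-3)
  p <- pchisq(Q, 1, lower.tail = FALSE)
  expect_equal(p, 0.0312, tolerance = 1e-3)
  # strata rebuilt from rounded published ORs/CIs give I2 near the
  # implied value (SE from the CI width on the log scale)
  b <- log(c(1.26, 1.17))
  se <- c((log(1.31) - log(1.21)) / (2 * 1.96),
          (log(1.24) - log(1.10)) / (2 * 1.96))
  h <- cochran_q_i2(b, se)
  expect_lt(abs(h$i2 - 0.7846), 0.05)
  expect_error(cochran_q_i2(0.2, 0.1), class = "cgs_validation_error")
})

test_that("interaction test is calibrated under the null and powered under signal", {
  # null: no product effect; rejection rate near 5% over replicates
  rej <- vapply(1:120, function(r) {
    set.seed(3000 + r)
    n <- 1500
    cgs <- rbinom(n, 16, 0.45)
    flag <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-1 + 0.2 * (cgs - 7)))
    interaction_test(y, cgs, flag)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 0.01)

  # strong interaction detected
  set.seed(77)
  n <- 4000
  cgs <- rbinom(n, 16, 0.45)
  flag <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.05 * (cgs - 7) + 0.3 * flag * (cgs - 7)))
  expect_lt(interaction_test(y, cgs, flag)$p, 0.001)
  expect_error(interaction_test(y, cgs, rep(1, n)),
               class = "cgs_validation_error")
})

test_that("score t-test is the classical pooled-variance Student's t", {
  same <- t_test_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  tt <- t_test_scores(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_closed <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_closed)
  tt_rev <- t_test_scores(b, a)
  expect_equal(tt_rev$t, -tt$t)
  expect_equal(tt_rev$p, tt$p)
  expect_error(t_test_scores(1, c(1, 2)), class = "cgs_validation_error")
})

test_that("association table mirrors the published layout and drops missing SNP-wise", {
  cfg <- simulation_config(n_case = 400, n_control = 400)
  ch <- simulate_cohort(cfg, seed = 5)
  panel <- study_snp_panel()
  tab <- association_table(ch$genotypes, panel, ch$phenotypes$status,
                           covariates = data.frame(sex = ch$phenotypes$sex,
                                                   age = ch$phenotypes$age,
                                                   bmi = ch$phenotypes$bmi))
  expect_equal(nrow(tab), 8)
  expect_true(all(c("chr", "snp", "gene", "risk_allele", "nonrisk_allele",
                    "freq_cases", "freq_controls", "or_", "ci_low",
                    "ci_high", "p") %in% names(tab)))
  expect_true(all(tab$ci_low < tab$or_ & tab$or_ < tab$ci_high))
})
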