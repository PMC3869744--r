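# Independent brute-force oracles used to verify the implementations.
# Each oracle is written from the definition, never by calling the
# function it checks.

# Exact HWE p-value by direct enumeration: exact multivariate
# hypergeometric probability of every genotype configuration with the
# observed allele margin, summing those whose probability does not exceed
# the observed configuration's.
hwe_oracle <- function(n_hom_r, n_het, n_hom_n) {
  n <- n_hom_r + n_het + n_hom_n
  n_r <- 2 * n_hom_r + n_het
  n_n <- 2 * n_hom_n + n_het
  if (min(n_r, n_n) == 0) return(1)
  hets <- seq(min(n_r, n_n) %% 2, min(n_r, n_n), by = 2)
  prob_of <- function(h) {
    hr <- (n_r - h) / 2
    hn <- (n_n - h) / 2
    exp(h * log(2) + lfactorial(n) - lfactorial(hr) - lfactorial(h) -
          lfactorial(hn) + lfactorial(n_r) + lfactorial(n_n) -
          lfactorial(2 * n))
  }
  probs <- vapply(hets, prob_of, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_het]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# AUC by explicit enumeration over all case-control pairs
auc_oracle <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(cases) * length(controls))
}

# negative log-likelihood of the two-parameter logistic model
neg_loglik_logistic <- function(b0, b1, y, x) {
  eta <- b0 + b1 * x
  -sum(y * eta - log1p(exp(eta)))
}

# brute-force likelihood maximiser: coarse grid then local refinement
logistic_grid_oracle <- function(y, x, lim = 6, steps = 121) {
  best <- c(0, 0); bestv <- Inf
  grid <- seq(-lim, lim, length.out = steps)
  for (b0 in grid) for (b1 in grid) {
    v <- neg_loglik_logistic(b0, b1, y, x)
    if (v < bestv) { bestv <- v; best <- c(b0, b1) }
  }
  for (r in c(0.2, 0.02, 0.002, 2e-4)) {
    g0 <- seq(best[1] - 10 * r, best[1] + 10 * r, by = r)
    g1 <- seq(best[2] - 10 * r, best[2] + 10 * r, by = r)
    for (b0 in g0) for (b1 in g1) {
      v <- neg_loglik_logistic(b0, b1, y, x)
      if (v < bestv) { bestv <- v; best <- c(b0, b1) }
    }
  }
  best
}

# exhaustive family-wise permutation p-values over every relabelling of
# the outcome vector (feasible for <= 8 subjects)
perm_oracle <- function(y, dosage_matrix, stat_fun) {
  z_obs <- stat_fun(y)
  n1 <- sum(y == 1)
  combs <- utils::combn(length(y), n1)
  maxes <- apply(combs, 2, function(idx) {
    yp <- integer(length(y)); yp[idx] <- 1L
    max(stat_fun(yp))
  })
  vapply(z_obs, function(z) mean(maxes >= z), numeric(1))
}

# quartile cut-points by exhaustive search over integer cut triples
# minimising the summed distance of cumulative proportions to 25/50/75%,
# ties broken toward the lexicographically smallest triple
quartile_oracle <- function(scores) {
  u <- sort(unique(scores))
  cum <- cumsum(tabulate(match(scores, u))) / length(scores)
  best <- NULL; bestv <- Inf
  for (i in seq_along(u)) for (j in i:length(u)) for (k in j:length(u)) {
    v <- abs(cum[i] - 0.25) + abs(cum[j] - 0.5) + abs(cum[k] - 0.75)
    if (v < bestv - 1e-12) { bestv <- v; best <- c(u[i], u[j], u[k]) }
  }
  q <- 1L + (scores > best[1]) + (scores > best[2]) + (scores > best[3])
  as.integer(q)
}

# small deterministic dosage matrix fixture
toy_dosage_matrix <- function(n = 12, m = 4, seed = 42, missing = 0) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("S%02d", 1:n), paste0("snp", 1:m)))
  g <- g + 0.0
  if (missing > 0) g[sample(length(g), missing)] <- NA_real_
  g
}
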