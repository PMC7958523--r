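test_that("observed-scale R2 matches the closed form on an HWE cohort", {
  # cases at allele frequency 0.325, controls at 0.11, HWE genotype
  # counts rounded to integers; oracle value computed independently from
  # r2 = P(1-P) * Delta^2 / Var(g) with population-variance denominators
  counts_case <- hwe_counts(792, 0.325)   # 361 347  84
  counts_ctrl <- hwe_counts(10000, 0.11)  # 7921 1958 121
  expect_equal(counts_case, c(361, 347, 84))
  expect_equal(counts_ctrl, c(7921, 1958, 121))
  ch <- cohort_from_counts(counts_case, counts_ctrl)
  fit <- fit_observed_r2(ch$dosages[, 1], ch$status)
  expect_equal(fit$r2_obs, 0.05563258034382192, tolerance = 1e-12)
  expect_equal(fit$n_used, 10792L)
  expect_false(fit$monomorphic)
})

test_that("perfect and degenerate fits behave as documented", {
  # status perfectly proportional to centered dosage (summary.lm notes
  # the perfect fit; the R2 itself is exact)
  expect_equal(
    suppressWarnings(fit_observed_r2(c(0, 0, 2, 2), c(0, 0, 1, 1))$r2_obs),
    1)
  # monomorphic dosage: R2 = 0 with a warning flag, not an error
  expect_warning(fit <- fit_observed_r2(rep(1, 6), c(1, 1, 1, 0, 0, 0)),
                 "monomorphic")
  expect_equal(fit$r2_obs, 0)
  expect_true(fit$monomorphic)
  # single-class status is a hard error
  expect_error(fit_observed_r2(c(0, 1, 2), c(1, 1, 1)), "cases and controls")
})

test_that("observed-scale R2 is invariant to affine dosage recoding", {
  set.seed(42)
  g <- sample(0:2, 500, TRUE, c(0.5, 0.4, 0.1))
  y <- rbinom(500, 1, plogis(-1 + 0.5 * g))
  r_raw <- fit_observed_r2(g, y)$r2_obs
  r_rec <- fit_observed_r2(g / 2, y)$r2_obs          # 0 / 0.5 / 1
  r_aff <- fit_observed_r2(3 * g - 1, y)$r2_obs
  expect_equal(r_rec, r_raw, tolerance = 1e-12)
  expect_equal(r_aff, r_raw, tolerance = 1e-12)
})

test_that("joint R2 reduces to the simple fit, drops duplicates, and is
           monotone in the predictor set", {
  set.seed(7)
  g1 <- sample(0:2, 400, TRUE, c(0.5, 0.4, 0.1))
  g2 <- sample(0:2, 400, TRUE, c(0.25, 0.5, 0.25))
  y <- rbinom(400, 1, plogis(-0.5 + 0.4 * g1 - 0.2 * g2))

  single <- fit_observed_r2(g1, y)$r2_obs
  expect_equal(fit_joint_observed_r2(cbind(v1 = g1), y)$r2_obs, single,
               tolerance = 1e-12)

  expect_warning(
    dupfit <- fit_joint_observed_r2(cbind(v1 = g1, v1copy = g1), y),
    "duplicated"
  )
  expect_equal(dupfit$r2_obs, single, tolerance = 1e-12)
  expect_equal(dupfit$dropped, "v1copy")

  joint <- fit_joint_observed_r2(cbind(v1 = g1, v2 = g2), y)$r2_obs
  expect_gte(joint, max(single, fit_observed_r2(g2, y)$r2_obs) - 1e-12)

  # non-duplicate exact collinearity is an error naming the culprit
  expect_error(
    suppressWarnings(
      fit_joint_observed_r2(cbind(v1 = g1, v2 = g2, v3 = g1 + g2), y)),
    "rank deficient"
  )
})

test_that("joint R2 of independent small-effect variants is near-additive", {
  set.seed(11)
  n <- 40000
  g1 <- sample(0:2, n, TRUE, c(0.49, 0.42, 0.09))
  g2 <- sample(0:2, n, TRUE, c(0.36, 0.48, 0.16))
  y <- rbinom(n, 1, plogis(-1 + 0.15 * g1 + 0.2 * g2))
  a <- fit_observed_r2(g1, y)$r2_obs
  b <- fit_observed_r2(g2, y)$r2_obs
  j <- fit_joint_observed_r2(cbind(v1 = g1, v2 = g2), y)$r2_obs
  expect_lt(abs(j - (a + b)), 0.05 * (a + b))
})

test_that("logistic slope reproduces the exact log odds ratio of a
           multiplicative-odds genotype table", {
  # genotype-class counts built so case:control odds double per allele:
  # odds 0.25, 0.5, 1 for g = 0, 1, 2  =>  slope is exactly log 2
  g <- rep(0:2, c(500, 300, 200))
  y <- c(rep(1:0, c(100, 400)), rep(1:0, c(100, 200)),
         rep(1:0, c(100, 100)))
  fit <- fit_logistic(g, y)
  expect_equal(fit$beta, log(2), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 100L)
  expect_gt(fit$se_beta, 0)

  # independent check: the fitted slope maximizes the Bernoulli
  # log-likelihood over a parameter grid around the reported optimum
  loglik <- function(int, slope) {
    eta <- int + slope * g
    sum(y * eta - log1p(exp(eta)))
  }
  best <- loglik(fit$intercept, fit$beta)
  grid <- expand.grid(int = fit$intercept + seq(-0.2, 0.2, length.out = 21),
                      slope = fit$beta + seq(-0.2, 0.2, length.out = 21))
  ll <- mapply(loglik, grid$int, grid$slope)
  expect_true(all(ll <= best + 1e-8))
})

test_that("logistic regression recovers a null effect and detects
           separation", {
  set.seed(5)
  g <- sample(0:2, 5000, TRUE, c(0.5, 0.4, 0.1))
  y <- rbinom(5000, 1, 0.3)
  fit <- fit_logistic(g, y)
  expect_lt(abs(fit$beta) / fit$se_beta, 4)

  expect_error(
    fit_logistic(c(2, 2, 2, 0, 0, 0), c(1, 1, 1, 0, 0, 0)),
    "separation"
  )
})

test_that("logistic estimates are calibrated: true slope within 3 SE", {
  set.seed(2024)
  hits <- replicate(200, {
    n <- 20000
    g <- sample(0:2, n, TRUE, c(0.49, 0.42, 0.09))
    y <- rbinom(n, 1, plogis(-2 + 0.4 * g))
    fit <- fit_logistic(g, y)
    abs(fit$beta - 0.4) <= 3 * fit$se_beta
  })
  expect_gte(mean(hits), 0.99)
})

test_that("covariate adjustment leaves a genuine dosage effect visible", {
  set.seed(9)
  n <- 4000
  g <- sample(0:2, n, TRUE, c(0.36, 0.48, 0.16))
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g + 0.8 * x))
  fit <- fit_logistic(g, y, covariates = cbind(pc1 = x))
  expect_equal(length(fit$covariate_betas), 1L)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se_beta)
})

test_that("control allele frequency counts control alleles only", {
  expect_equal(control_allele_freq(c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(control_allele_freq(c(2, 2, 2), c(1, 0, 0)), 1)
  expect_equal(control_allele_freq(c(2, 0, 1, 1, 2), c(1, 0, 0, 0, 0)), 0.5)
  expect_equal(control_allele_freq(c(2, 0, 1, NA), c(1, 0, 0, 0)), 0.25)
  expect_error(control_allele_freq(c(1, 2), c(1, 1)), "no controls")
})
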