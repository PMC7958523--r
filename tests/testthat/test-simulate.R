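# frozen quadrature-oracle values for the strong-variant scenario
# (p = 0.11, K = 63e-5, allele-based per-allele OR = 4.99): liability
# shift solved by an independent root find over the exact three-genotype
# model before the build
ORACLE_A <- 0.4875585501819959
ORACLE_CASE_DIST <- c(0.3709160093531787, 0.4960481179814178,
                      0.1330358726654034)
ORACLE_CTRL_DIST <- c(0.7923655131874157, 0.1956107244420702,
                      0.01202376237051422)
ORACLE_CASE_FREQ <- 0.3810599316561123

test_that("odds-ratio-to-liability-shift conversion has exact null and
           round-trip behaviour", {
  expect_equal(or_to_liability_effect(1, p = 0.2, K = 0.01), 0)

  for (a in c(-0.4, 0.1, 0.6)) {
    or <- liability_effect_to_or(a, p = 0.25, K = 0.005)
    expect_equal(or_to_liability_effect(or, p = 0.25, K = 0.005), a,
                 tolerance = 1e-8)
  }

  expect_error(or_to_liability_effect(1e9, p = 0.5, K = 0.01),
               "too extreme")
})

test_that("the strong-variant liability shift matches the quadrature
           oracle", {
  a <- or_to_liability_effect(4.99, p = 0.11, K = 63e-5)
  expect_equal(a, ORACLE_A, tolerance = 1e-8)
  expect_equal(liability_variance_fraction(a, 0.11), 0.04447425034134012,
               tolerance = 1e-7)
})

test_that("case and control genotype distributions are normalized,
           HWE-null, and match the oracle under strong effects", {
  null <- case_control_genotype_dists(p = 0.3, K = 0.01, a = 0,
                                      model = "liability")
  expect_equal(null$case, null$hwe, tolerance = 1e-12)
  expect_equal(null$control, null$hwe, tolerance = 1e-12)

  d <- case_control_genotype_dists(p = 0.11, K = 63e-5, a = ORACLE_A,
                                   model = "liability")
  expect_equal(sum(d$case), 1, tolerance = 1e-12)
  expect_equal(sum(d$control), 1, tolerance = 1e-12)
  expect_equal(d$case, ORACLE_CASE_DIST, tolerance = 1e-8)
  expect_equal(d$control, ORACLE_CTRL_DIST, tolerance = 1e-8)
  expect_equal((d$case[2] + 2 * d$case[3]) / 2, ORACLE_CASE_FREQ,
               tolerance = 1e-8)

  # logistic model: conditional distributions follow the same structure
  dl <- case_control_genotype_dists(p = 0.3, K = 0.05, or_allele = 2,
                                    model = "logistic")
  expect_equal(sum(dl$case), 1, tolerance = 1e-12)
  expect_equal(sum(dl$control), 1, tolerance = 1e-12)
  expect_true(all(diff(dl$risk) > 0))
})

test_that("simulated genotype frequencies match the conditional
           distributions (goodness of fit over 20 seeds)", {
  d <- case_control_genotype_dists(p = 0.11, K = 63e-5, a = ORACLE_A,
                                   model = "liability")
  rejections <- 0L
  for (s in 1:20) {
    sp <- sim_spec(data.frame(variant_id = "v1", p = 0.11, a = ORACLE_A),
                   K = 63e-5, n_cases = 50000, n_controls = 1, seed = s)
    g <- simulate_cohort(sp)
    counts <- tabulate(g$dosages[g$status == 1L, 1] + 1L, nbins = 3L)
    pval <- suppressWarnings(chisq.test(counts, p = d$case)$p.value)
    if (pval < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("cohort simulation honours quotas, seeds and determinism", {
  spec <- sim_spec(data.frame(variant_id = "v1", p = 0.2, a = 0.3),
                   K = 1.25e-5, n_cases = 1, n_controls = 1, seed = 9)
  tiny <- simulate_cohort(spec)
  expect_equal(length(tiny$status), 2L)
  expect_equal(sum(tiny$status), 1L)

  spec2 <- sim_spec(data.frame(variant_id = c("v1", "v2"),
                               p = c(0.11, 0.4), a = c(0.49, 0.1)),
                    K = 63e-5, n_cases = 300, n_controls = 700, seed = 21)
  c1 <- simulate_cohort(spec2)
  c2 <- simulate_cohort(spec2)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$status, c2$status)

  c3 <- simulate_cohort(sim_spec(spec2$variants, spec2$K, 300, 700,
                                 seed = 22))
  expect_false(identical(c1$dosages, c3$dosages))
})

test_that("a null-effect spec yields a null logistic slope at large n", {
  spec <- sim_spec(data.frame(variant_id = "v1", p = 0.3, a = 0),
                   K = 63e-5, n_cases = 5000, n_controls = 5000, seed = 4)
  ch <- simulate_cohort(spec)
  fit <- fit_logistic(ch$dosages[, 1], ch$status)
  expect_lt(abs(fit$beta) / fit$se_beta, 4)
})

test_that("spec validation rejects invalid parameters", {
  v <- data.frame(variant_id = "v1", p = 0.3, a = 0.2)
  expect_error(sim_spec(v, K = 0, n_cases = 10, n_controls = 10), "'K'")
  expect_error(sim_spec(v, K = 0.01, n_cases = 0, n_controls = 10),
               "n_cases")
  bad <- data.frame(variant_id = "v1", p = 1.2, a = 0.2)
  expect_error(sim_spec(bad, K = 0.01, n_cases = 1, n_controls = 1),
               "frequencies")
  huge <- data.frame(variant_id = "v1", p = 0.5, a = 2)
  expect_error(sim_spec(huge, K = 0.01, n_cases = 1, n_controls = 1),
               "genetic variance")
  noeff <- data.frame(variant_id = "v1", p = 0.5)
  expect_error(sim_spec(noeff, K = 0.01, n_cases = 1, n_controls = 1),
               "'a' or an 'or_allele'")
})
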