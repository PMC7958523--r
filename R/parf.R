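#' Population attributable risk fraction for one variant
#'
#' The population attributable risk fraction (PARF) is the proportion of
#' cases that would be prevented if the risk allele were removed from the
#' population. For a variant with risk-allele frequency `p` in controls
#' and per-allele log odds ratio `beta`, under Hardy-Weinberg genotype
#' frequencies and multiplicative per-allele odds,
#' \deqn{PARF = 1 - \frac{1}{(1-p)^2 + 2p(1-p)e^{\beta} + p^2 e^{2\beta}}}
#'
#' The point estimate may be negative for protective effect estimates
#' (`beta < 0`); no truncation at zero is applied. PARFs of several
#' variants are not additive: removing one risk factor changes the PARFs
#' of the others.
#'
#' @param p Risk-allele frequency in controls, in `[0, 1]` (vectorized).
#' @param beta Per-allele log odds ratio (vectorized).
#' @return The attributable fraction(s), always `< 1`.
#' @examples
#' parf_point(0.806, log(1.48))  # ~0.48
#' parf_point(0.11, log(4.99))   # ~0.52
#' @export
parf_point <- function(p, beta) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(beta))) stop("beta must be finite", call. = FALSE)
  1 - 1 / ((1 - p)^2 + 2 * p * (1 - p) * exp(beta) + p^2 * exp(2 * beta))
}

#' Parametric-bootstrap confidence interval for PARF
#'
#' Percentile confidence interval from a parametric bootstrap: each
#' replicate draws `beta* ~ Normal(beta, se_beta)` and, when
#' `resample_freq = TRUE`, an allele frequency
#' `p* = Binomial(2 n_ctrl, p_ctrl) / (2 n_ctrl)`, then evaluates
#' [parf_point()] at the drawn values. The default resamples `beta` only;
#' frequency resampling additionally propagates the sampling uncertainty
#' of the control allele frequency and requires `n_ctrl`.
#'
#' Draw order under the seed is documented and stable: all `n_boot`
#' normal draws for `beta*` first, then (if enabled) all binomial draws
#' for `p*`. Results are deterministic under a fixed seed.
#'
#' @param p_ctrl Risk-allele frequency in controls.
#' @param beta Per-allele log odds ratio.
#' @param se_beta Standard error of `beta` (`>= 0`; zero yields a
#'   degenerate interval equal to the point estimate, with a warning).
#' @param n_ctrl Number of control subjects behind `p_ctrl`; required when
#'   `resample_freq = TRUE`.
#' @param n_boot Number of bootstrap replicates (default 10,000; fewer
#'   than 100 triggers a warning).
#' @param seed Integer RNG seed, recorded in the result.
#' @param level Confidence level (default 0.95).
#' @param resample_freq Also resample the allele frequency?
#' @return A list of class `"parf_result"`: `parf`, `ci_lower`,
#'   `ci_upper`, `n_boot`, `seed`, `level`, `resample_freq`, and
#'   `outside_ci`, a flag raised in the (rare, but legitimate for a
#'   percentile bootstrap) event that the point estimate falls outside
#'   its own interval.
#' @export
parf_bootstrap_ci <- function(p_ctrl, beta, se_beta, n_ctrl = NULL,
                              n_boot = 10000L, seed = 1L, level = 0.95,
                              resample_freq = FALSE) {
  check_prob(p_ctrl, "p_ctrl", open = FALSE)
  stopifnot(is.finite(beta), is.finite(se_beta), se_beta >= 0,
            level > 0, level < 1, n_boot >= 1)
  if (resample_freq && (is.null(n_ctrl) || is.na(n_ctrl))) {
    stop("'n_ctrl' is required when resample_freq = TRUE", call. = FALSE)
  }
  if (n_boot < 100L) {
    warning("n_boot < 100: percentile interval will be unstable",
            call. = FALSE)
  }
  if (se_beta == 0 && !resample_freq) {
    warning("se_beta = 0: confidence interval is degenerate", call. = FALSE)
  }
  point <- parf_point(p_ctrl, beta)
  draws <- with_seed(seed, {
    beta_star <- rnorm(n_boot, mean = beta, sd = se_beta)
    p_star <- if (resample_freq) {
      rbinom(n_boot, size = 2L * as.integer(n_ctrl), prob = p_ctrl) /
        (2 * as.integer(n_ctrl))
    } else {
      rep(p_ctrl, n_boot)
    }
    parf_point(p_star, beta_star)
  })
  ci <- quantile(draws, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  outside <- point < ci[1] || point > ci[2]
  if (outside) {
    warning("point estimate lies outside its percentile interval",
            call. = FALSE)
  }
  structure(list(parf = point, ci_lower = ci[1], ci_upper = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 level = level, resample_freq = resample_freq,
                 outside_ci = outside),
            class = "parf_result")
}

#' @export
print.parf_result <- function(x, ...) {
  cat(sprintf("PARF = %.1f%% (%.0f%% CI %.1f%% to %.1f%%; %d replicates)\n",
              100 * x$parf, 100 * x$level, 100 * x$ci_lower,
              100 * x$ci_upper, x$n_boot))
  invisible(x)
}

#' PARF table over a variant association table
#'
#' Computes [parf_bootstrap_ci()] for every variant in an association
#' table. Each variant gets its own RNG substream via
#' [child_seed()]`(seed, variant_id)`, so the table is reproducible and
#' its values are invariant to row order. PARFs are reported per variant
#' and are deliberately never summed.
#'
#' @param assoc A validated [assoc_table()].
#' @param n_boot,seed,level,resample_freq Passed to [parf_bootstrap_ci()];
#'   `seed` is the master seed from which per-variant seeds are derived.
#' @return A `data.frame` with columns `variant_id, parf, ci_lower,
#'   ci_upper, n_boot, seed`, one row per variant, in input order.
#' @export
parf_table <- function(assoc, n_boot = 10000L, seed = 1L, level = 0.95,
                       resample_freq = FALSE) {
  assoc <- validate_assoc_table(assoc)
  rows <- lapply(seq_len(nrow(assoc)), function(i) {
    s <- child_seed(seed, assoc$variant_id[i])
    r <- parf_bootstrap_ci(
      p_ctrl = assoc$p_ctrl[i], beta = assoc$beta[i],
      se_beta = assoc$se_beta[i], n_ctrl = assoc$n_ctrl[i],
      n_boot = n_boot, seed = s, level = level,
      resample_freq = resample_freq
    )
    data.frame(variant_id = assoc$variant_id[i], parf = r$parf,
               ci_lower = r$ci_lower, ci_upper = r$ci_upper,
               n_boot = r$n_boot, seed = r$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
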