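#' Specification of a synthetic ascertained case-control cohort
#'
#' Describes a population governed by a liability-threshold (or logistic)
#' disease model with independent biallelic variants (linkage
#' equilibrium), plus ascertainment quotas for a case-control study drawn
#' from it. Per-variant effects are given either as `a`, the per-allele
#' liability shift in residual-standard-deviation units, or as
#' `or_allele`, a per-allele odds ratio; odds ratios are converted to
#' liability shifts by [or_to_liability_effect()] when the liability model
#' is used.
#'
#' @param variants A `data.frame` with columns `variant_id`, `p`
#'   (risk-allele frequency in the population, in (0,1)) and one of `a`
#'   or `or_allele`.
#' @param K Population prevalence, in (0, 1).
#' @param n_cases,n_controls Ascertainment quotas, `>= 1`.
#' @param model `"liability"` (default) or `"logistic"`.
#' @param seed Integer RNG seed.
#' @return A list of class `"sim_spec"`.
#' @seealso [simulate_cohort()], [case_control_genotype_dists()]
#' @export
sim_spec <- function(variants, K, n_cases, n_controls,
                     model = c("liability", "logistic"), seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L,
            all(c("variant_id", "p") %in% names(variants)))
  if (!any(c("a", "or_allele") %in% names(variants))) {
    stop("'variants' needs an 'a' or an 'or_allele' column", call. = FALSE)
  }
  check_prob(K, "K")
  stopifnot(n_cases >= 1, n_controls >= 1)
  if (any(variants$p <= 0 | variants$p >= 1)) {
    stop("variant frequencies must lie in (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant_id in sim_spec", call. = FALSE)
  }
  spec <- structure(list(variants = variants, K = K,
                         n_cases = as.integer(n_cases),
                         n_controls = as.integer(n_controls),
                         model = model, seed = as.integer(seed)),
                    class = "sim_spec")
  if (model == "liability") {
    a <- resolve_liability_effects(spec)
    vg <- sum(a^2 * 2 * variants$p * (1 - variants$p))
    if (vg >= 1) {
      stop(sprintf(paste0("total genetic variance of listed variants ",
                          "(%.3f residual-variance units) must be < 1"), vg),
           call. = FALSE)
    }
  }
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(paste0("sim_spec: %d variant(s), %s model, K = %g per ",
                     "100,000,\n  quotas %d cases / %d controls, seed %d\n"),
              nrow(x$variants), x$model, 1e5 * x$K, x$n_cases,
              x$n_controls, x$seed))
  invisible(x)
}

# per-variant liability shifts, converting ORs where needed (marginal
# single-variant conversion, residual SD 1)
resolve_liability_effects <- function(spec) {
  v <- spec$variants
  if ("a" %in% names(v) && !all(is.na(v$a))) {
    a <- as.numeric(v$a)
    if (anyNA(a)) stop("column 'a' has missing entries", call. = FALSE)
    return(a)
  }
  vapply(seq_len(nrow(v)), function(i) {
    or_to_liability_effect(v$or_allele[i], v$p[i], spec$K)
  }, numeric(1))
}

# threshold of the single-variant liability model a*g + e, e ~ N(0, sd^2),
# re-centered so the HWE-weighted marginal prevalence equals K
liability_threshold <- function(a, p, K, sd_resid = 1) {
  f <- hwe_freqs(p)
  uniroot(function(T) {
    sum(f * pnorm(T - a * (0:2), sd = sd_resid, lower.tail = FALSE)) - K
  }, interval = sd_resid * qnorm(K, lower.tail = FALSE) + c(-1, 1) *
    (2 * abs(a) + 1), extendInt = "yes",
  tol = .Machine$double.eps^0.75)$root
}

#' Implied per-allele odds ratio of a liability shift
#'
#' Forward map from a per-allele liability shift `a` (residual-SD units)
#' to the per-allele odds ratio implied by the ascertained case-control
#' allele distributions: genotypes at Hardy-Weinberg frequencies, disease
#' when `a*g + e` exceeds the threshold re-centered so the marginal
#' prevalence is `K`, and the odds ratio computed from the case and
#' control risk-allele frequencies.
#'
#' @param a Per-allele liability shift.
#' @param p Risk-allele frequency in the population.
#' @param K Population prevalence.
#' @param sd_resid Residual liability standard deviation (default 1).
#' @return The implied per-allele (allele-based) odds ratio.
#' @export
liability_effect_to_or <- function(a, p, K, sd_resid = 1) {
  d <- case_control_genotype_dists(p, K, a = a, model = "liability",
                                   sd_resid = sd_resid)
  fc <- allele_freq_from_dist(d$case)
  ft <- allele_freq_from_dist(d$control)
  (fc / (1 - fc)) / (ft / (1 - ft))
}

#' Liability shift matching a requested per-allele odds ratio
#'
#' Numerically inverts [liability_effect_to_or()]: finds the per-allele
#' liability shift `a` whose implied case-control allele distributions
#' under threshold ascertainment yield the requested odds ratio, by a
#' bracketed monotone root find (tolerance 1e-10 on `a`). The bracket is
#' capped where the variant's genetic variance would reach the residual
#' variance; odds ratios too extreme to be representable within that
#' constraint are an error.
#'
#' @param or_allele Requested per-allele odds ratio, `> 0`.
#' @param p Risk-allele frequency in the population.
#' @param K Population prevalence.
#' @param sd_resid Residual liability standard deviation (default 1).
#' @param tol Root-find tolerance on `a`.
#' @return The per-allele liability shift `a` (0 when `or_allele = 1`).
#' @export
or_to_liability_effect <- function(or_allele, p, K, sd_resid = 1,
                                   tol = 1e-10) {
  stopifnot(is.finite(or_allele), or_allele > 0)
  check_prob(p, "p"); check_prob(K, "K")
  if (or_allele == 1) return(0)
  a_max <- 0.999 * sd_resid / sqrt(2 * p * (1 - p))
  obj <- function(a) log(liability_effect_to_or(a, p, K, sd_resid)) -
    log(or_allele)
  if (obj(-a_max) * obj(a_max) > 0) {
    stop(sprintf(paste0("odds ratio %.3g is too extreme: no liability ",
                        "shift within the variance constraint |a| < %.3g ",
                        "attains it"), or_allele, a_max), call. = FALSE)
  }
  uniroot(obj, interval = c(-a_max, a_max), tol = tol)$root
}

#' Genotype distributions among cases and controls
#'
#' Exact genotype probabilities conditional on disease status under the
#' generative model: `P(G = g | case)` is proportional to
#' `P(case | g) * HWE(g)`, and analogously for controls. For the
#' liability model `P(case | g)` is the upper-tail normal probability
#' beyond the re-centered threshold; for the logistic model it is
#' `plogis(alpha + log(or_allele) g)` with the intercept solved so the
#' marginal prevalence is `K`. These conditional distributions are what
#' make exact ascertained sampling possible at very low prevalence:
#' drawing cases directly from `P(G | case)` sidesteps the ~`1/K`
#' population draws per case that rejection sampling would need.
#'
#' @param p Risk-allele frequency in the population.
#' @param K Population prevalence.
#' @param a Per-allele liability shift (liability model).
#' @param or_allele Per-allele odds ratio (logistic model, or converted
#'   for the liability model when `a` is not given).
#' @param model `"liability"` or `"logistic"`.
#' @param sd_resid Residual liability SD (liability model).
#' @return A list: `case` and `control` (probabilities over genotypes
#'   0, 1, 2, each summing to 1), `risk` (`P(case | g)`), `hwe`, and the
#'   model nuisance parameter (`threshold` or `intercept`).
#' @export
case_control_genotype_dists <- function(p, K, a = NULL, or_allele = NULL,
                                        model = c("liability", "logistic"),
                                        sd_resid = 1) {
  model <- match.arg(model)
  check_prob(p, "p"); check_prob(K, "K")
  f <- hwe_freqs(p)
  if (model == "liability") {
    if (is.null(a)) {
      if (is.null(or_allele)) stop("supply 'a' or 'or_allele'", call. = FALSE)
      a <- or_to_liability_effect(or_allele, p, K, sd_resid)
    }
    Tt <- liability_threshold(a, p, K, sd_resid)
    risk <- pnorm(Tt - a * (0:2), sd = sd_resid, lower.tail = FALSE)
    nuisance <- c(threshold = Tt)
  } else {
    if (is.null(or_allele)) stop("'or_allele' is required for the logistic model",
                                 call. = FALSE)
    b <- log(or_allele)
    alpha <- uniroot(function(al) sum(f * plogis(al + b * (0:2))) - K,
                     interval = qlogis(K) + c(-1, 1) * (2 * abs(b) + 1),
                     extendInt = "yes", tol = .Machine$double.eps^0.75)$root
    risk <- plogis(alpha + b * (0:2))
    nuisance <- c(intercept = alpha)
  }
  case <- f * risk
  control <- f * (1 - risk)
  list(case = unname(case / sum(case)),
       control = unname(control / sum(control)),
       risk = unname(risk), hwe = unname(f), model = model,
       nuisance = nuisance)
}

#' Simulate an ascertained case-control cohort
#'
#' Draws `n_cases` genotype vectors from the case-conditional genotype
#' distributions and `n_controls` from the control-conditional ones, per
#' variant, with variants independent (linkage equilibrium). Sampling is
#' exact under the model and never instantiates the source population, so
#' cohorts at prevalences of ~1 per 100,000 are generated in
#' milliseconds. Deterministic under the spec's seed: an identical
#' [sim_spec()] yields a bit-identical cohort.
#'
#' Under the liability model with several variants, each variant's
#' conditional distribution is computed with its residual standard
#' deviation inflated to absorb the genetic variance of the remaining
#' variants (a normal approximation of the polygenic background), so the
#' per-variant marginals stay consistent with the joint additive model.
#'
#' @param spec A [sim_spec()].
#' @return A [cohort()] with cases first (`case_0001`, ...), then
#'   controls.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  v <- spec$variants
  k <- nrow(v)
  if (spec$model == "liability") {
    a <- resolve_liability_effects(spec)
    vg <- a^2 * 2 * v$p * (1 - v$p)
  }
  dists <- lapply(seq_len(k), function(j) {
    if (spec$model == "liability") {
      case_control_genotype_dists(
        p = v$p[j], K = spec$K, a = a[j], model = "liability",
        sd_resid = sqrt(1 + sum(vg[-j]))
      )
    } else {
      case_control_genotype_dists(
        p = v$p[j], K = spec$K, or_allele = v$or_allele[j],
        model = "logistic"
      )
    }
  })
  n1 <- spec$n_cases; n0 <- spec$n_controls
  d <- with_seed(spec$seed, {
    m <- matrix(NA_real_, nrow = n1 + n0, ncol = k)
    for (j in seq_len(k)) {
      m[seq_len(n1), j] <- sample(0:2, n1, replace = TRUE,
                                  prob = dists[[j]]$case)
      m[n1 + seq_len(n0), j] <- sample(0:2, n0, replace = TRUE,
                                       prob = dists[[j]]$control)
    }
    m
  })
  cohort(
    dosages = d,
    status = rep(c(1L, 0L), c(n1, n0)),
    subject_ids = c(sprintf("case_%05d", seq_len(n1)),
                    sprintf("control_%05d", seq_len(n0))),
    variant_ids = as.character(v$variant_id)
  )
}

#' Liability-variance fraction of one variant
#'
#' The fraction of total liability variance explained by a variant with
#' per-allele liability shift `a` (residual-SD units) and allele
#' frequency `p`: `Vg / (1 + Vg)` with `Vg = a^2 * 2p(1-p)`. This is the
#' generating truth against which pipeline estimates of liability-scale
#' R2 are compared in parameter-recovery tests.
#'
#' @param a Per-allele liability shift in residual-SD units.
#' @param p Risk-allele frequency.
#' @return The variance fraction, in `[0, 1)`.
#' @export
liability_variance_fraction <- function(a, p) {
  vg <- a^2 * 2 * p * (1 - p)
  vg / (1 + vg)
}
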