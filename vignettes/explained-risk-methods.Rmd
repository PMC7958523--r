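---
title: "Quantifying the disease risk explained by susceptibility variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the disease risk explained by susceptibility variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprisk)
```

## The problem

Case-control studies of rare diseases deliberately enrich for cases: a
condition affecting 63 people per 100,000 may be studied in a sample
that is 7% cases. Summaries that are unaffected by that enrichment (the
odds ratio) coexist with summaries that are badly distorted by it (the
R² of a regression of case status on genotype). `snprisk` implements
three complementary, ascertainment-aware answers to "how much disease
risk does this variant account for?":

1. the proportion of *liability* variance the variant explains in the
   general population,
2. the proportion of *cases* attributable to the risk allele (the
   population attributable risk fraction, PARF), and
3. the *absolute risk* carried by each genotype when an overall
   prevalence is decomposed over Hardy-Weinberg genotype frequencies.

It also ships an exact simulator of ascertained case-control cohorts
under a liability-threshold model, which is both the package's test bed
and a practical tool for power or design calculations at very low
prevalence.

## The liability-threshold model and the R² transform

The liability model assumes each individual carries an unobserved
standard-normal trait (the liability) and is affected when it exceeds
the threshold $t$ with upper-tail mass equal to the population
prevalence $K$. For a variant, the observed-scale R² ($R_o^2$) is the
coefficient of determination from a simple linear regression of the 0/1
status on allele dosage. With a study case proportion $P$ (typically
$P \gg K$), the liability-scale estimate is

$$R_l^2 = \frac{R_o^2\,C}{1 + R_o^2\,C\,\theta}, \qquad
  C = \frac{[K(1-K)]^2}{z^2\,P(1-P)}, \qquad
  \theta = \frac{m(P-K)}{1-K}\left(\frac{m(P-K)}{1-K} - t\right),$$

where $z$ is the normal density at $t$ and $m = z/K$ is the mean case
liability. Two limits anchor the implementation and its tests: with no
ascertainment ($P = K$) the correction $\theta$ vanishes and $C$
reduces to the classical factor $K(1-K)/z^2$; at $K = P = 1/2$ the
transform is exactly multiplication by $\pi/2$.

Numerical notes: $t$ is the upper-tail quantile (`qnorm(K, lower.tail =
FALSE)`), $C$ is assembled in log space so prevalences down to $10^{-7}$
do not underflow through $z^2$, and results outside $[0,1]$ by more than
$10^{-9}$ raise an error rather than being clipped — an observed R²
large enough to leave $[0,1]$ after transformation is outside the
transform's validity region and should be seen, not silenced. The
study case proportion $P$ entering the correction is recomputed per fit
from the subjects actually used after missing-genotype exclusions.

### A known limitation: the transform is first-order

The transformation is derived from a linearization of the threshold
model and is accurate when each predictor's effect on liability is
small. For a *single* variant of large effect at very low prevalence it
systematically overstates the variance fraction: at a per-allele
liability shift of ~0.49 residual SD (the kind of effect implied by a
per-allele odds ratio of ~5 at a control allele frequency of 11% and
K = 63 per 100,000), the infinite-data transform value is ~2.5 times
the generating variance fraction, as direct quadrature over the
three-genotype model shows. The package's parameter-recovery test
therefore exercises the pipeline in the regime where the method is
valid (K = 1%, per-allele shift 0.155 residual SD, variance fraction
~1%, exact bias ~6%), and the large-effect behaviour is exposed —
deliberately unfixed — by the strong-variant end-to-end check. Users
interpreting liability R² for a single very strong variant at very low
prevalence should treat it as the method's conventional estimate, not
as an unbiased variance decomposition.

## Population attributable risk fraction

For a variant with control risk-allele frequency $p$ and per-allele log
odds ratio $\beta$ (from a logistic regression with the variant as the
only covariate), the proportion of cases that would be prevented if the
risk allele were removed is

$$\mathrm{PARF} = 1 - \frac{1}{(1-p)^2 + 2p(1-p)e^{\beta} + p^2 e^{2\beta}}.$$

Protective point estimates are negative and are reported as such. PARFs
are *not additive* across variants — removing one risk factor changes
the PARFs of the others — so no table produced by the package ever
contains a sum of PARFs, and this is guarded by a test.

### Parametric bootstrap

Confidence intervals are percentile intervals over parametric-bootstrap
replicates: $\beta^* \sim N(\hat\beta, \mathrm{SE}^2)$, and optionally
$p^* = \mathrm{Bin}(2n_{\mathrm{ctrl}}, \hat p)/(2n_{\mathrm{ctrl}})$.
The beta-only mode is the default: the effect-size uncertainty
dominates, and when $\hat\beta$ and $\hat p$ come from the same
controls their sampling errors are negatively correlated, so resampling
them independently is mildly conservative. Both modes are available
(`resample_freq`). Defaults: 10,000 replicates, 95% level, type-7
empirical quantiles. Draw order under the seed is documented (all
$\beta^*$, then all $p^*$) so replicates can be replayed exactly.
Per-variant seeds are derived from the master seed and the variant
*identifier* (not its row position) via a 31-bit string hash
(`child_seed()`), making tables reproducible and order-invariant.

Coverage is checked end to end: cohorts of 792 cases and 10,000
controls simulated under a logistic model with a strong variant
(control frequency ~11%, OR ~5), each fitted and bootstrapped, cover
the generating PARF in ~95% of 500 replicates.

## Absolute risk by genotype

Given prevalence $K$, allele frequency $p$ and per-allele odds ratio
OR, genotype frequencies are $(1-p)^2, 2p(1-p), p^2$ and per-genotype
odds are $o$, $o\cdot\mathrm{OR}$, $o\cdot\mathrm{OR}^2$, with the
baseline odds $o$ solved (bracketed root find, then a Newton polish; the
prevalence constraint holds to $10^{-12}$) so the frequency-weighted
risks average to $K$. The multiplicative-odds scale is the default
because it is the scale on which the logistic OR is defined; the
risk-ratio scale (risks proportional to $\mathrm{OR}^g$, normalized) is
provided as an alternative and agrees within 1% relative for
$K \le 10^{-3}$, where odds and risks coincide. Expected cases per
100,000 carriers are reported unrounded and rounded to the nearest
integer.

## The cohort simulator

The simulator draws an *ascertained* case-control cohort without ever
instantiating the population. For each variant it computes the exact
genotype distributions conditional on status,

$$P(G = g \mid \mathrm{case}) \propto P(\mathrm{case} \mid g)\,
  \mathrm{HWE}(g),$$

and samples case and control genotype vectors directly from them. At a
prevalence of 1.25 per 100,000, rejection sampling would need on the
order of $10^5$ population draws per case; exact conditional sampling
makes cohort generation a few milliseconds regardless of $K$.

Under the liability model, $P(\mathrm{case} \mid g)$ is the
upper-tail normal probability beyond a threshold re-centered so the
marginal prevalence stays $K$; effects are per-allele liability shifts
`a` in residual-SD units. Effects given as odds ratios are converted by
solving for the shift whose implied case/control *allele* distributions
under threshold ascertainment produce the requested allele-based odds
ratio (bracketed root find, tolerance $10^{-10}$; the bracket is capped
where the variant's genetic variance would reach the residual
variance). A logistic-model mode (intercept solved so the population
prevalence is $K$) is provided to test the liability-scale estimators
under model misspecification.

With several variants, each variant's conditional distribution uses a
residual SD inflated by the genetic variance of the other variants — a
normal approximation of the polygenic background that keeps per-variant
marginals consistent with the joint additive model. Variants are
simulated in linkage equilibrium.

What the generator deliberately does **not** emulate: linkage
disequilibrium between variants, population structure and relatedness,
genotyping error and informative missingness, gene-environment
interaction and epistasis. Tests passing on these cohorts therefore
validate the estimators under the stated model, not robustness to those
real-data features.

One consequence worth stating plainly: with a control allele frequency
of 11% and a per-allele OR of ~5 at K = 63 per 100,000, *any* internally
consistent model implies a case allele frequency near 36–38%. Published
case-frequency ranges quoted from different cohorts than the OR (such
as a 30–35% band) need not be reachable by a simulator that honours the
OR exactly; the simulator honours the OR.

## Defaults and parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| prevalence scenarios | 1.25, 63, 495 | cases per 100,000; lowest and highest reported general-population estimates for a rare fibrotic lung disease, plus the over-65 estimate |
| ascertainment quotas | 792 / 10,000 | cases / controls of the motivating study design |
| `n_boot` | 10,000 | bootstrap replicates |
| CI level | 0.95 | percentile interval, type-7 quantiles |
| `resample_freq` | `FALSE` | beta-only parametric bootstrap |
| IRLS | tol 1e-8, max 100 | logistic convergence; separation when \|beta\| > 30, non-finite information, or ~0 residual deviance |
| missing dosages | complete-case (single), mean imputation (joint) | switchable to complete-case for the joint fit |
| root finds | 1e-12 (prevalence), 1e-10 (OR-to-shift) | bracketed, monotone |

Test problem sizes are chosen to make Monte-Carlo error small relative
to the tolerances being asserted while keeping the default suite fast:
20 seeds of 5,000/5,000 cohorts for liability recovery, 50 seeds of
792/10,000 for allele-frequency recovery, 500 replicates for bootstrap
coverage, 200 replicates of n = 20,000 for logistic calibration.

## A worked example

```{r example}
# absolute risk: prevalence 63 per 100,000, allele frequency 11%, OR 4.99
absolute_risk(K = 63e-5, p = 0.11, or_allele = 4.99)

# attributable fraction for a common allele of modest effect
100 * parf_point(p = 0.806, beta = log(1.48))

# liability R2 for an observed-scale R2 of 0.0572 in a 792/10,000 study
liability_sweep(0.0572, P = 792 / 10792)
```

```{r pipeline}
# simulate an ascertained cohort and run the full pipeline on it
spec <- sim_spec(
  data.frame(variant_id = c("strong", "weak"),
             p = c(0.11, 0.3), or_allele = c(4.99, 1.3)),
  K = 63e-5, n_cases = 792, n_controls = 10000, seed = 1
)
ch <- simulate_cohort(spec)
run_explained_risk(ch, drop_variant = "strong")
```

## Design choices

* **Bootstrap scheme.** "Parametric bootstrap" admits several readings;
  the package resamples the effect size from its asymptotic normal (and
  optionally the allele frequency from binomial allele counts) because
  that is the simplest scheme consistent with the phrase, and both
  uncertainty sources are separately switchable.
* **Odds-scale absolute risk.** The per-allele effect is applied
  multiplicatively on the odds scale for internal consistency with the
  logistic model that produced the OR; at rare-disease prevalences the
  risk-ratio shortcut agrees to within 1%.
* **Allele-based OR in the simulator's inverse map.** The "per-allele
  odds ratio" of a liability shift is defined from the case/control
  allele frequency contrast, the quantity a 2x2 allele-count table
  yields; genotype-based definitions (heterozygote OR, ascertained
  logistic slope) differ by a few percent at strong effects and are
  recoverable via `fit_logistic()` on simulated cohorts.
* **Monomorphic variants** return R² = 0 with a warning flag instead of
  erroring, so batch analyses over variant tables keep running past
  near-null signals.
* **Covariates** are accepted only by the logistic effect-size fit (an
  effect-size sensitivity analysis, e.g. ancestry principal components
  computed elsewhere); the R² entering the liability transform is
  always from the variant-only regression.

## Limitations

Beyond the first-order nature of the transform discussed above: the
liability R² of a joint fit inherits the linear model's approximations;
PARF assumes the control frequency estimates the population frequency
(excellent for rare diseases); the simulator's per-variant conditional
independence given status is exact for single variants and a
linkage-equilibrium approximation for several; and none of the methods
model gene-environment interplay.
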