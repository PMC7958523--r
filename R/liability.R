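#' Liability-scale context for one prevalence scenario
#'
#' Precomputes the scalars needed to move an observed-scale R2 from an
#' ascertained case-control analysis onto the liability scale. Under the
#' liability-threshold model, each individual carries an unobserved
#' standard-normal liability and is affected when it exceeds the threshold
#' `t` chosen so that the upper-tail mass equals the population prevalence
#' `K`. Case enrichment in the study (case proportion `P` above `K`)
#' enters through two constants:
#'
#' \deqn{C = \frac{[K(1-K)]^2}{z^2 \, P(1-P)}, \qquad
#'       \theta = \frac{m(P-K)}{1-K}\left(\frac{m(P-K)}{1-K} - t\right)}
#'
#' where `z` is the standard-normal density at `t` and `m = z/K` is the
#' mean liability of cases. With no ascertainment (`P = K`) `theta = 0`
#' and `C` reduces to the classical factor `K(1-K)/z^2`.
#'
#' `C` is evaluated in log space so that prevalences as small as 1e-7 do
#' not underflow through `z^2`.
#'
#' @param K Population prevalence, in (0, 1).
#' @param P Proportion of cases in the study, in (0, 1).
#' @return A list of class `"liability_context"`: `K`, `P`, `t`, `z`, `m`,
#'   `C`, `theta`.
#' @seealso [liability_r2()], [liability_sweep()]
#' @examples
#' liability_context(K = 63e-5, P = 792 / 10792)
#' @export
liability_context <- function(K, P) {
  check_prob(K, "K"); check_prob(P, "P")
  t <- qnorm(K, lower.tail = FALSE)
  z <- dnorm(t)
  m <- z / K
  logC <- 2 * (log(K) + log1p(-K)) - 2 * dnorm(t, log = TRUE) -
    log(P) - log1p(-P)
  q <- m * (P - K) / (1 - K)
  theta <- q * (q - t)
  structure(list(K = K, P = P, t = t, z = z, m = m, C = exp(logC),
                 theta = theta),
            class = "liability_context")
}

#' @export
print.liability_context <- function(x, ...) {
  cat(sprintf(paste0("liability context: K = %.6g, P = %.6g\n",
                     "  t = %.6f, z = %.6g, m = %.6f\n",
                     "  C = %.6f, theta = %.6f\n"),
              x$K, x$P, x$t, x$z, x$m, x$C, x$theta))
  invisible(x)
}

#' Transform observed-scale R2 to the liability scale
#'
#' Applies the ascertainment-corrected transformation
#' \deqn{R^2_{liab} = \frac{R^2_o \, C}{1 + R^2_o \, C \, \theta}}
#' with `C` and `theta` from [liability_context()]. The transform is
#' strictly increasing in `r2_obs` wherever the denominator stays
#' positive; a non-positive denominator (possible only for extreme inputs
#' outside the transform's validity region) is an error, as is a result
#' outside `[0, 1]` by more than 1e-9. Results within 1e-9 of the
#' boundary are clamped.
#'
#' @param r2_obs Observed-scale R2 in `[0, 1]`, or an `"observed_fit"`.
#' @param ctx A [liability_context()].
#' @return The liability-scale R2, a numeric scalar in `[0, 1]`.
#' @examples
#' ctx <- liability_context(K = 63e-5, P = 792 / 10792)
#' liability_r2(0.0572, ctx)
#' @export
liability_r2 <- function(r2_obs, ctx) {
  if (inherits(r2_obs, "observed_fit")) r2_obs <- r2_obs$r2_obs
  stopifnot(inherits(ctx, "liability_context"))
  check_prob(r2_obs, "r2_obs", open = FALSE)
  denom <- 1 + r2_obs * ctx$C * ctx$theta
  if (denom <= 0) {
    stop(sprintf(paste0(
      "liability transform outside its validity region: ",
      "1 + r2_obs*C*theta = %.4g <= 0 (r2_obs = %.4g, C = %.4g, ",
      "theta = %.4g)"), denom, r2_obs, ctx$C, ctx$theta), call. = FALSE)
  }
  val <- r2_obs * ctx$C / denom
  if (val < -1e-9 || val > 1 + 1e-9) {
    stop(sprintf("liability R2 = %.6g falls outside [0, 1]", val),
         call. = FALSE)
  }
  min(max(val, 0), 1)
}

#' Liability-scale R2 across prevalence scenarios
#'
#' Evaluates [liability_r2()] for one observed-scale R2 under a list of
#' population prevalence scenarios, expressed per 100,000 as on user
#' surfaces. The default scenarios are 1.25 and 63 per 100,000 (the lowest
#' and highest reported general-population prevalence estimates for a rare
#' fibrotic lung disease) and 495 per 100,000 (prevalence in people over
#' 65 years of age).
#'
#' @param r2_obs Observed-scale R2 in `[0, 1]`, or an `"observed_fit"`.
#' @param P Proportion of cases in the study.
#' @param K_per_100k Numeric vector of prevalences per 100,000 people.
#' @return A `data.frame` with columns `K_per_100k`, `K`, `liability_r2`,
#'   one row per scenario, in the order given.
#' @export
liability_sweep <- function(r2_obs, P, K_per_100k = c(1.25, 63, 495)) {
  if (inherits(r2_obs, "observed_fit")) r2_obs <- r2_obs$r2_obs
  stopifnot(is.numeric(K_per_100k), length(K_per_100k) >= 1L)
  K <- K_per_100k / 1e5
  data.frame(
    K_per_100k = K_per_100k,
    K = K,
    liability_r2 = vapply(K, function(k) {
      liability_r2(r2_obs, liability_context(k, P))
    }, numeric(1))
  )
}
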