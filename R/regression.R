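#' Observed-scale R2 from regression of case status on dosage
#'
#' Fits a simple linear regression of the 0/1 disease indicator on
#' risk-allele dosage over complete pairs and returns the coefficient of
#' determination (equivalently the squared sample correlation). This is
#' the observed-scale R2 that [liability_r2()] transforms to the liability
#' scale.
#'
#' A monomorphic (zero-variance) dosage yields `r2_obs = 0` with a warning
#' and a flag rather than an error, so batch runs over variant tables do
#' not abort on near-null variants.
#'
#' @param dosage Numeric vector of risk-allele counts (`NA` allowed).
#' @param status Binary vector (1 = case); both classes must be present
#'   among complete pairs.
#' @return A list of class `"observed_fit"`: `r2_obs`, `n_used`,
#'   `monomorphic`.
#' @examples
#' fit_observed_r2(c(0, 1, 2, 0, 1), c(0, 0, 1, 0, 1))
#' @export
fit_observed_r2 <- function(dosage, status) {
  stopifnot(length(dosage) == length(status))
  ok <- !is.na(dosage) & !is.na(status)
  d <- as.numeric(dosage[ok]); y <- as.numeric(status[ok])
  if (!all(y %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (!any(y == 1) || !any(y == 0)) {
    stop("both cases and controls are required", call. = FALSE)
  }
  if (length(unique(d)) < 2L) {
    warning("monomorphic dosage: observed-scale R2 set to 0", call. = FALSE)
    return(structure(list(r2_obs = 0, n_used = length(d), monomorphic = TRUE),
                     class = "observed_fit"))
  }
  fit <- lm(y ~ d)
  structure(list(r2_obs = summary(fit)$r.squared, n_used = length(d),
                 monomorphic = FALSE),
            class = "observed_fit")
}

#' @export
print.observed_fit <- function(x, ...) {
  cat(sprintf("observed-scale R2 = %.6g (n = %d%s)\n", x$r2_obs, x$n_used,
              if (isTRUE(x$monomorphic)) ", monomorphic" else ""))
  invisible(x)
}

#' Joint observed-scale R2 for several variants
#'
#' Multiple-regression coefficient of determination of case status on all
#' dosage columns jointly. Zero-variance columns are dropped with a
#' warning; remaining exact collinearity is an error naming the offending
#' columns. Missing dosages are mean-imputed per column by default
#' (complete-case analysis across many variants would discard most
#' subjects), switchable to complete-case.
#'
#' @param dosages Subjects x variants numeric matrix.
#' @param status Binary vector (1 = case).
#' @param missing Either `"mean"` (impute the column mean, default) or
#'   `"complete"` (drop subjects with any missing dosage).
#' @return An `"observed_fit"` with an extra `dropped` element naming the
#'   degenerate columns removed.
#' @export
fit_joint_observed_r2 <- function(dosages, status,
                                  missing = c("mean", "complete")) {
  missing <- match.arg(missing)
  X <- as.matrix(dosages)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- sprintf("var%d", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(status))
  y <- as.numeric(status)
  if (!all(y %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (missing == "complete") {
    keep <- complete.cases(X)
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  } else {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  if (!any(y == 1) || !any(y == 0)) {
    stop("both cases and controls are required", call. = FALSE)
  }
  sds <- apply(X, 2, function(v) var(v))
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (ncol(X) == 0L) {
    return(structure(list(r2_obs = 0, n_used = length(y), monomorphic = TRUE,
                          dropped = dropped), class = "observed_fit"))
  }
  # exact duplicates carry no information beyond an identical copy: drop
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("dropping duplicated column(s): ",
            paste(colnames(X)[dup], collapse = ", "), call. = FALSE)
    dropped <- c(dropped, colnames(X)[dup])
    X <- X[, !dup, drop = FALSE]
  }
  qx <- qr(cbind(`(Intercept)` = 1, X))
  if (qx$rank < ncol(X) + 1L) {
    bad <- colnames(cbind(`(Intercept)` = 1, X))[
      qx$pivot[seq(qx$rank + 1L, ncol(X) + 1L)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = dat)
  structure(list(r2_obs = summary(fit)$r.squared, n_used = length(y),
                 monomorphic = FALSE, dropped = dropped),
            class = "observed_fit")
}

#' Per-allele log odds ratio by logistic regression
#'
#' Maximum-likelihood logistic regression of case status on risk-allele
#' dosage, optionally adjusted for covariates (e.g. genetic principal
#' components supplied by the caller). Fitting is by iteratively
#' reweighted least squares with convergence tolerance `tol` and at most
#' `max_iter` iterations; the standard error comes from the inverse
#' observed information. Complete or quasi-complete separation (diverging
#' `|beta| > 30` or a non-finite information matrix) is reported as an
#' error.
#'
#' @param dosage Numeric vector of risk-allele counts (`NA` allowed;
#'   complete cases are used).
#' @param status Binary vector (1 = case).
#' @param covariates Optional numeric matrix of adjustment covariates.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A list of class `"logistic_fit"`: `beta`, `se_beta`,
#'   `converged`, `n_iter`, `intercept`, `covariate_betas`, `n_used`.
#' @export
fit_logistic <- function(dosage, status, covariates = NULL,
                         max_iter = 100L, tol = 1e-8) {
  stopifnot(length(dosage) == length(status))
  dat <- data.frame(y = as.numeric(status), g = as.numeric(dosage))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- sprintf("cov_%d", seq_len(ncol(covariates)))
    }
    dat <- cbind(dat, as.data.frame(covariates))
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (!any(dat$y == 1) || !any(dat$y == 0)) {
    stop("both cases and controls are required", call. = FALSE)
  }
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial(),
        control = glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(coef(fit)["g"])
  info_ok <- all(is.finite(vcov(fit)))
  se <- if (info_ok) unname(sqrt(vcov(fit)["g", "g"])) else NaN
  # a residual deviance of ~0 on a binary response means the classes are
  # perfectly separated even if the coefficients stopped short of the
  # divergence threshold
  if (!is.finite(beta) || abs(beta) > 30 || !is.finite(se) ||
      fit$deviance < 1e-7) {
    stop(sprintf(paste0(
      "complete or quasi-complete separation detected ",
      "(beta = %.3g, se = %.3g): the per-allele log odds ratio is not ",
      "identifiable from these data"), beta, se), call. = FALSE)
  }
  if (!fit$converged) {
    stop(sprintf("logistic fit did not converge in %d IRLS iterations",
                 fit$iter), call. = FALSE)
  }
  cb <- coef(fit)[setdiff(names(coef(fit)), c("(Intercept)", "g"))]
  structure(list(beta = beta, se_beta = se, converged = fit$converged,
                 n_iter = fit$iter, intercept = unname(coef(fit)[1]),
                 covariate_betas = if (length(cb)) cb,
                 n_used = nrow(dat)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("per-allele log OR = %.4f (SE %.4f, OR %.3f, n = %d, %d iter)\n",
              x$beta, x$se_beta, exp(x$beta), x$n_used, x$n_iter))
  invisible(x)
}

#' Risk-allele frequency in controls
#'
#' @param dosage Numeric vector of risk-allele counts (`NA` allowed).
#' @param status Binary vector (1 = case).
#' @return Control risk-allele frequency: the sum of non-missing control
#'   dosages divided by twice the number of non-missing controls.
#' @export
control_allele_freq <- function(dosage, status) {
  stopifnot(length(dosage) == length(status))
  ctrl <- status == 0 & !is.na(dosage)
  if (!any(ctrl)) {
    stop("no controls with non-missing dosage", call. = FALSE)
  }
  sum(dosage[ctrl]) / (2 * sum(ctrl))
}
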