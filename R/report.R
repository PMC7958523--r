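#' Explained liability per variant and jointly, across prevalences
#'
#' For each requested variant, fits the observed-scale R2 of case status
#' on dosage ([fit_observed_r2()]) and transforms it to the liability
#' scale under each prevalence scenario; optionally adds a joint row
#' using all variants together ([fit_joint_observed_r2()]) and a
#' leave-one-out row dropping a named variant (e.g. the dominant signal,
#' to show how much the remaining variants explain). The study case
#' proportion `P` entering the ascertainment correction is taken per fit
#' as cases / subjects actually used after missingness.
#'
#' Terms are ordered by explained proportion (observed-scale R2)
#' descending; the liability transform is monotone in R2, so the order is
#' the same on either scale.
#'
#' @param cohort A validated [cohort()].
#' @param variant_ids Variants to analyse (default: all in the cohort).
#' @param K_per_100k Prevalence scenarios per 100,000 people.
#' @param joint Add the all-variants joint row? (only when >1 variant)
#' @param drop_variant Optional variant ID; adds an `all_minus_<id>` row
#'   fitting all requested variants except this one.
#' @return A `data.frame` with columns `term`, `K_per_100k`, `r2_obs`,
#'   `n_used`, `liability_r2`.
#' @export
run_explained_risk <- function(cohort, variant_ids = NULL,
                               K_per_100k = c(1.25, 63, 495),
                               joint = TRUE, drop_variant = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(variant_ids)) variant_ids <- cohort$variant_ids
  unknown <- setdiff(variant_ids, cohort$variant_ids)
  if (length(unknown)) {
    stop("unknown variant id(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(cohort$variant_ids, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(drop_variant) && !drop_variant %in% variant_ids) {
    stop("drop_variant '", drop_variant, "' is not among the requested ",
         "variants", call. = FALSE)
  }
  res <- list()
  for (vid in variant_ids) {
    d <- cohort$dosages[, vid]
    used <- !is.na(d)
    fit <- fit_observed_r2(d, cohort$status)
    # complete-case fits can drop subjects; P is recomputed on those used
    P <- sum(cohort$status[used] == 1L) / sum(used)
    sw <- liability_sweep(fit$r2_obs, P = P, K_per_100k = K_per_100k)
    res[[length(res) + 1L]] <- data.frame(
      term = vid, K_per_100k = sw$K_per_100k, r2_obs = fit$r2_obs,
      n_used = fit$n_used, liability_r2 = sw$liability_r2,
      stringsAsFactors = FALSE)
  }
  if (isTRUE(joint) && length(variant_ids) > 1L) {
    fitj <- fit_joint_observed_r2(
      cohort$dosages[, variant_ids, drop = FALSE], cohort$status)
    Pj <- sum(cohort$status == 1L) / fitj$n_used
    swj <- liability_sweep(fitj$r2_obs, P = Pj, K_per_100k = K_per_100k)
    res[[length(res) + 1L]] <- data.frame(
      term = sprintf("all_%d_variants", length(variant_ids)),
      K_per_100k = swj$K_per_100k, r2_obs = fitj$r2_obs,
      n_used = fitj$n_used, liability_r2 = swj$liability_r2,
      stringsAsFactors = FALSE)
  }
  if (!is.null(drop_variant) && length(variant_ids) > 1L) {
    keep <- setdiff(variant_ids, drop_variant)
    fitd <- fit_joint_observed_r2(
      cohort$dosages[, keep, drop = FALSE], cohort$status)
    Pd <- sum(cohort$status == 1L) / fitd$n_used
    swd <- liability_sweep(fitd$r2_obs, P = Pd, K_per_100k = K_per_100k)
    res[[length(res) + 1L]] <- data.frame(
      term = paste0("all_minus_", drop_variant),
      K_per_100k = swd$K_per_100k, r2_obs = fitd$r2_obs,
      n_used = fitd$n_used, liability_r2 = swd$liability_r2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  ord <- order(-out$r2_obs, out$term, out$K_per_100k)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an analysis configuration file
#'
#' YAML configuration with optional blocks `cohort` (`path`), `assoc`
#' (`path`), `prevalences_per_100k`, `bootstrap` (`n_boot`, `seed`,
#' `resample_freq`), `simulate` (`variants`, `K_per_100k`, `n_cases`,
#' `n_controls`, `model`, `seed`), and `drop_variant`.
#'
#' @param path Path to a YAML file.
#' @return The configuration as a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

sim_spec_from_config <- function(sim) {
  stopifnot(!is.null(sim$variants))
  variants <- do.call(rbind, lapply(sim$variants, function(v) {
    data.frame(variant_id = v$variant_id, p = v$p,
               a = if (!is.null(v$a)) v$a else NA_real_,
               or_allele = if (!is.null(v$or_allele)) v$or_allele
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(variants$a))) variants$a <- NULL
  if (!is.null(variants$or_allele) && all(is.na(variants$or_allele))) {
    variants$or_allele <- NULL
  }
  sim_spec(variants = variants, K = sim$K_per_100k / 1e5,
           n_cases = sim$n_cases, n_controls = sim$n_controls,
           model = if (!is.null(sim$model)) sim$model else "liability",
           seed = if (!is.null(sim$seed)) sim$seed else 1L)
}

#' Run the full explained-risk pipeline and write its outputs
#'
#' Orchestrates cohort input (read from TSV, or simulated from the
#' config's `simulate` block), per-variant and joint explained-liability
#' estimation, per-variant logistic fits feeding the attributable-risk
#' table with bootstrap confidence intervals, the genotype-specific
#' absolute-risk table, and a JSON manifest recording inputs, seeds,
#' parameters and package version. Re-running with the same configuration
#' and seed reproduces every output byte for byte.
#'
#' When no association table is supplied, one is derived from the cohort
#' itself: per-variant logistic regression for the log odds ratio and its
#' standard error, and the control allele frequency with its control
#' count.
#'
#' @param config A configuration list or the path to a YAML file
#'   ([read_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of output file paths
#'   (`explained_risk`, `parf`, `absolute_risk`, `assoc`, `manifest`,
#'   and `cohort` when simulated).
#' @export
run_full_report <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  K_per_100k <- config$prevalences_per_100k
  if (is.null(K_per_100k)) K_per_100k <- c(1.25, 63, 495)
  K_per_100k <- as.numeric(unlist(K_per_100k))

  if (!is.null(config$cohort$path)) {
    ch <- read_cohort_tsv(config$cohort$path)
  } else if (!is.null(config$simulate)) {
    spec <- sim_spec_from_config(config$simulate)
    ch <- simulate_cohort(spec)
    paths$cohort <- file.path(out_dir, "cohort.tsv")
    write_cohort_tsv(ch, paths$cohort)
  } else {
    stop("config must provide either cohort$path or a simulate block",
         call. = FALSE)
  }

  er <- run_explained_risk(ch, K_per_100k = K_per_100k,
                           joint = TRUE,
                           drop_variant = config$drop_variant)
  paths$explained_risk <- file.path(out_dir, "explained_risk.tsv")
  write.table(er, paths$explained_risk, sep = "\t", quote = FALSE,
              row.names = FALSE)

  if (!is.null(config$assoc$path)) {
    assoc <- read_assoc_table(config$assoc$path)
  } else {
    n_ctrl_all <- sum(ch$status == 0L)
    rows <- lapply(ch$variant_ids, function(vid) {
      d <- ch$dosages[, vid]
      lf <- fit_logistic(d, ch$status)
      data.frame(variant_id = vid,
                 p_ctrl = control_allele_freq(d, ch$status),
                 beta = lf$beta, se_beta = lf$se_beta,
                 n_ctrl = sum(ch$status == 0L & !is.na(d)),
                 stringsAsFactors = FALSE)
    })
    assoc <- validate_assoc_table(do.call(rbind, rows))
    paths$assoc <- file.path(out_dir, "assoc.tsv")
    write_assoc_table(assoc, paths$assoc)
  }

  bt <- config$bootstrap
  pt <- parf_table(
    assoc,
    n_boot = if (!is.null(bt$n_boot)) bt$n_boot else 10000L,
    seed = if (!is.null(bt$seed)) bt$seed else 1L,
    resample_freq = isTRUE(bt$resample_freq)
  )
  # PARFs are not additive across variants: the table carries per-variant
  # rows only, never a sum
  paths$parf <- file.path(out_dir, "parf.tsv")
  write.table(pt, paths$parf, sep = "\t", quote = FALSE, row.names = FALSE)

  rt <- risk_table(assoc, K_per_100k = K_per_100k)
  paths$absolute_risk <- file.path(out_dir, "absolute_risk.tsv")
  write.table(rt, paths$absolute_risk, sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    package = "snprisk",
    version = as.character(packageVersion("snprisk")),
    config = config,
    prevalences_per_100k = K_per_100k,
    seeds = list(
      bootstrap = if (!is.null(bt$seed)) bt$seed else 1L,
      simulate = if (!is.null(config$simulate$seed)) config$simulate$seed
    ),
    outputs = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
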