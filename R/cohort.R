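#' Construct an individual-level case-control cohort
#'
#' Bundles a subjects-by-variants matrix of risk-allele dosages (0, 1 or 2
#' copies; `NA` marks a missing genotype), a binary case/control status
#' vector, and optional numeric covariates. Missing dosages are kept
#' explicit and are handled per analysis (complete-case for single-variant
#' fits, imputation for the joint fit); they are never silently zero-filled.
#'
#' @param dosages Numeric matrix, subjects x variants, entries in
#'   `{0, 1, 2}` or `NA`.
#' @param status Binary vector (1 = case, 0 = control), one per subject;
#'   both classes must be present.
#' @param covariates Optional numeric matrix, subjects x q.
#' @param subject_ids,variant_ids Optional identifier vectors; defaults are
#'   derived from dimnames or generated.
#' @return A list of class `"cohort"` with elements `dosages`, `status`,
#'   `covariates`, `subject_ids`, `variant_ids`.
#' @seealso [read_cohort_tsv()], [simulate_cohort()]
#' @export
cohort <- function(dosages, status, covariates = NULL,
                   subject_ids = NULL, variant_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(dosages)
    if (is.null(subject_ids)) subject_ids <- sprintf("S%05d", seq_len(n))
  }
  if (is.null(variant_ids)) {
    variant_ids <- colnames(dosages)
    if (is.null(variant_ids)) {
      variant_ids <- sprintf("var%d", seq_len(ncol(dosages)))
    }
  }
  rownames(dosages) <- subject_ids
  colnames(dosages) <- variant_ids
  x <- structure(
    list(dosages = dosages, status = as.integer(status),
         covariates = if (!is.null(covariates)) as.matrix(covariates),
         subject_ids = as.character(subject_ids),
         variant_ids = as.character(variant_ids)),
    class = "cohort"
  )
  validate_cohort(x)
}

#' Validate a cohort object
#'
#' @param x A `"cohort"` object.
#' @return `x`, unchanged, after checking that dosages are in `{0, 1, 2}`
#'   or missing, status is binary with both classes present, and matrix
#'   dimensions agree with the identifier lists.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  d <- x$dosages
  if (nrow(d) != length(x$status)) {
    stop("status length does not match the number of subjects", call. = FALSE)
  }
  if (nrow(d) != length(x$subject_ids) || ncol(d) != length(x$variant_ids)) {
    stop("dosage matrix dimensions inconsistent with id lists", call. = FALSE)
  }
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyNA(x$status) || !all(x$status %in% c(0L, 1L))) {
    stop("status must be 0/1 with no missing values", call. = FALSE)
  }
  if (!any(x$status == 1L) || !any(x$status == 0L)) {
    stop("cohort must contain at least one case and one control",
         call. = FALSE)
  }
  if (!is.null(x$covariates) && nrow(x$covariates) != nrow(d)) {
    stop("covariate rows do not match subjects", call. = FALSE)
  }
  if (anyDuplicated(x$variant_ids)) {
    stop("duplicate variant_ids in cohort", call. = FALSE)
  }
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("case-control cohort: %d cases, %d controls, %d variant(s)\n",
              sum(x$status == 1L), sum(x$status == 0L), ncol(x$dosages)))
  nmiss <- sum(is.na(x$dosages))
  if (nmiss) cat(sprintf("  missing dosages: %d\n", nmiss))
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %d\n", ncol(x$covariates)))
  }
  invisible(x)
}

#' Read a cohort from TSV
#'
#' Expects a header row `subject_id, status, <variant ids...>` with
#' optional trailing covariate columns named `cov_*`; missing dosages are
#' encoded `NA`.
#'
#' @param path Path to the TSV file.
#' @return A validated [cohort()].
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!all(c("subject_id", "status") %in% names(x))) {
    stop("cohort TSV must have 'subject_id' and 'status' columns",
         call. = FALSE)
  }
  covcols <- grep("^cov_", names(x), value = TRUE)
  varcols <- setdiff(names(x), c("subject_id", "status", covcols))
  if (!length(varcols)) stop("cohort TSV has no variant columns", call. = FALSE)
  cohort(
    dosages = as.matrix(x[varcols]),
    status = x$status,
    covariates = if (length(covcols)) as.matrix(x[covcols]),
    subject_ids = x$subject_id,
    variant_ids = varcols
  )
}

#' Write a cohort to TSV
#'
#' @param x A validated [cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(x, path) {
  x <- validate_cohort(x)
  out <- data.frame(subject_id = x$subject_ids, status = x$status,
                    x$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read risk-allele dosages from a VCF file
#'
#' Extracts per-subject risk-allele counts from the GT field of a VCF.
#' The caller names the risk allele for each variant; dosage is the number
#' of alleles in the genotype matching it. Multiallelic records are
#' rejected; missing genotypes become `NA`. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file.
#' @param risk_alleles Named character vector mapping variant IDs (VCF
#'   `ID` column) to the risk allele sequence (must equal REF or ALT).
#' @return A subjects x variants numeric matrix of dosages.
#' @export
read_dosages_vcf <- function(path, risk_alleles) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the 'vcfR' package is required for VCF input", call. = FALSE)
  }
  if (is.null(names(risk_alleles)) || any(!nzchar(names(risk_alleles)))) {
    stop("'risk_alleles' must be a named character vector", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {            # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  ids <- fix[, "ID"]
  keep <- match(names(risk_alleles), ids)
  if (anyNA(keep)) {
    stop("variants not found in VCF: ",
         paste(names(risk_alleles)[is.na(keep)], collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- matrix(NA_real_, nrow = ncol(gt), ncol = length(keep),
                dimnames = list(colnames(gt), names(risk_alleles)))
  for (j in seq_along(keep)) {
    i <- keep[j]
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multiallelic record rejected: ", ids[i], call. = FALSE)
    }
    alleles <- c(ref, alt)
    risk_idx <- match(risk_alleles[j], alleles)
    if (is.na(risk_idx)) {
      stop(sprintf("risk allele '%s' is neither REF nor ALT for %s",
                   risk_alleles[j], ids[i]), call. = FALSE)
    }
    codes <- strsplit(gt[i, ], "[/|]")
    out[, j] <- vapply(codes, function(a) {
      if (length(a) == 0L || any(a == "." | is.na(a))) return(NA_real_)
      sum(as.integer(a) == (risk_idx - 1L))
    }, numeric(1))
  }
  out
}
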