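#' Construct a variant association table
#'
#' A variant association table holds per-variant summary statistics: the
#' risk-allele frequency in controls, the per-risk-allele log odds ratio
#' (natural log), its standard error, and optionally the number of control
#' subjects behind the frequency estimate (required only when the
#' attributable-risk bootstrap resamples the allele frequency).
#'
#' Risk-allele orientation is the caller's responsibility: `beta` must be
#' the log odds ratio *per copy of the risk allele* whose control frequency
#' is `p_ctrl`. No strand or allele harmonization is performed.
#'
#' @param variant_id Character vector of unique, nonempty identifiers.
#' @param p_ctrl Risk-allele frequency in controls, in `[0, 1]`.
#' @param beta Per-allele log odds ratio.
#' @param se_beta Standard error of `beta`, `>= 0`.
#' @param n_ctrl Optional integer count of control subjects used to
#'   estimate `p_ctrl` (`NA` where unknown).
#' @return A `data.frame` of class `"assoc_table"` with one row per variant.
#' @seealso [read_assoc_table()], [validate_assoc_table()], [parf_table()]
#' @examples
#' assoc_table("rs35705950", p_ctrl = 0.11, beta = log(4.99), se_beta = 0.1)
#' @export
assoc_table <- function(variant_id, p_ctrl, beta, se_beta,
                        n_ctrl = NA_integer_) {
  x <- data.frame(
    variant_id = as.character(variant_id),
    p_ctrl = as.numeric(p_ctrl),
    beta = as.numeric(beta),
    se_beta = as.numeric(se_beta),
    n_ctrl = as.integer(n_ctrl),
    stringsAsFactors = FALSE
  )
  validate_assoc_table(x)
}

#' Validate a variant association table
#'
#' Checks the invariants of an association table: nonempty, unique and
#' nonempty variant identifiers, control allele frequencies in `[0, 1]`,
#' finite effect sizes and non-negative standard errors. Validation is
#' idempotent: validating an already valid table returns it unchanged.
#'
#' @param x A `data.frame` with columns `variant_id`, `p_ctrl`, `beta`,
#'   `se_beta` and optionally `n_ctrl`.
#' @return `x`, classed as `"assoc_table"`.
#' @export
validate_assoc_table <- function(x) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("association table must be a data.frame with at least one row",
         call. = FALSE)
  }
  required <- c("variant_id", "p_ctrl", "beta", "se_beta")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("association table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"n_ctrl" %in% names(x)) x$n_ctrl <- NA_integer_
  id <- as.character(x$variant_id)
  if (anyNA(id) || any(!nzchar(id))) {
    stop("variant_id must be nonempty", call. = FALSE)
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate variant_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x$p_ctrl) || any(x$p_ctrl < 0 | x$p_ctrl > 1)) {
    stop("p_ctrl must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(x$beta) || any(!is.finite(x$beta))) {
    stop("beta must be finite", call. = FALSE)
  }
  if (anyNA(x$se_beta) || any(!is.finite(x$se_beta) | x$se_beta < 0)) {
    stop("se_beta must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.na(x$n_ctrl) & x$n_ctrl < 1)) {
    stop("n_ctrl must be >= 1 where present", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- unique(c("assoc_table", class(x)))
  x
}

#' Read a variant association table from TSV
#'
#' Expects a tab-delimited UTF-8 file with a header row and columns
#' `variant_id, p_ctrl, beta, se_beta` and optionally `n_ctrl`;
#' decimal point is `'.'`.
#'
#' @param path Path to the TSV file.
#' @return A validated [assoc_table()].
#' @export
read_assoc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = NA, check.names = FALSE)
  validate_assoc_table(x)
}

#' Write a variant association table to TSV
#'
#' @param x A validated [assoc_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc_table <- function(x, path) {
  x <- validate_assoc_table(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
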