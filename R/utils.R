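# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Derive a per-variant child seed from a master seed
#'
#' Deterministic derivation of an RNG substream seed from a master seed and
#' a variant identifier, so that per-variant bootstrap results are
#' reproducible and invariant to the ordering of variants in a table.
#' Uses a 31-bit polynomial string hash of the identifier mixed with the
#' master seed; all arithmetic is exact in double precision.
#'
#' @param master Integer master seed.
#' @param id Character scalar, e.g. a variant identifier.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' child_seed(1L, "rs35705950")
#' @export
child_seed <- function(master, id) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(id), length(id) == 1L, nzchar(id))
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(master) %% 2147483647 + h * 65539) %% 2147483647)
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    stop(sprintf("'%s' must lie in %s; got %g", name,
                 if (open) "(0, 1)" else "[0, 1]", x), call. = FALSE)
  }
  invisible(x)
}

hwe_freqs <- function(p) c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)

allele_freq_from_dist <- function(d) unname((d[2] + 2 * d[3]) / 2)
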