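# shared fixtures, built in code

# deterministic cohort with known genotype counts per class:
# counts_case / counts_ctrl are length-3 vectors of subjects with 0/1/2
# risk alleles
cohort_from_counts <- function(counts_case, counts_ctrl, variant_id = "v1") {
  d <- c(rep(0:2, counts_case), rep(0:2, counts_ctrl))
  y <- rep(c(1L, 0L), c(sum(counts_case), sum(counts_ctrl)))
  cohort(dosages = matrix(d, ncol = 1,
                          dimnames = list(NULL, variant_id)),
         status = y)
}

# HWE-shaped integer counts for n subjects at allele frequency p
hwe_counts <- function(n, p) {
  cc <- round(n * c((1 - p)^2, 2 * p * (1 - p), p^2))
  cc[1] <- n - sum(cc[2:3])
  cc
}

# three-variant synthetic assoc table used across tests
toy_assoc <- function() {
  assoc_table(
    variant_id = c("strong", "common_weak", "protective"),
    p_ctrl = c(0.11, 0.806, 0.45),
    beta = c(log(4.99), log(1.48), log(0.99)),
    se_beta = c(0.08, 0.06, 0.07),
    n_ctrl = c(10000L, 10000L, 10000L)
  )
}
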