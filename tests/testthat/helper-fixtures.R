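# small builders shared across test files

toy_table <- function(a1, a2, pops, motif = 2L) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  genotype_table(a1, a2, paste0("i", seq_len(nrow(a1))), pops,
                 locus_set(paste0("L", seq_len(ncol(a1))), motif),
                 validate = FALSE)
}

# diploid genotypes drawn from given allele frequencies (sizes = names)
sample_pop <- function(n, freqs, n_loci = 1L) {
  sizes <- as.integer(names(freqs))
  a1 <- matrix(sample(sizes, n * n_loci, TRUE, freqs), n, n_loci)
  a2 <- matrix(sample(sizes, n * n_loci, TRUE, freqs), n, n_loci)
  list(a1 = a1, a2 = a2)
}

# one shared study fixture per test session (deterministic)
study_fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_study_fixture(1L)
    cache
  }
})

# Levene exact p for a 2-allele genotype count matrix, computed directly
# (independent of the package implementation)
levene_p_2alleles <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  m1 <- 2 * n11 + n12; m2 <- 2 * n22 + n12
  hs <- seq(m1 %% 2, min(m1, m2), by = 2)
  lp <- vapply(hs, function(h)
    lfactorial(n) + h * log(2) + lfactorial(m1) + lfactorial(m2) -
      lfactorial((m1 - h) / 2) - lfactorial(h) - lfactorial((m2 - h) / 2) -
      lfactorial(2 * n), numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  sum(pr[lp <= lp[hs == n12] + 1e-9])
}
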