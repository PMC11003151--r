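# shared fixtures, built once per test run

# full-size bundle and pipeline run under the default study conditions
test_bundle <- local({
  env <- new.env()
  function() {
    if (is.null(env$b))
      env$b <- simulate_bundle(synthetic_config(seed = 1))
    env$b
  }
})

test_report <- local({
  env <- new.env()
  function() {
    if (is.null(env$r))
      env$r <- suppressWarnings(run_pipeline(test_bundle(), seed = 1))
    env$r
  }
})

# reduced bundle for structural tests that do not need the full design
small_config <- function(seed = 7) {
  synthetic_config(
    seed = seed, chrom_lengths = c(chr1 = 1200000, chr2 = 800000),
    n_chains = 10, n_specific_extra_erna = 10, n_specific_extra_gene = 10,
    n_other_gene = 20, n_ncrna = 7, n_repeats = 100, n_gwas_outside = 20,
    n_qtl = 5, n_snp_true = 8, n_snp_null = 12)
}

small_bundle <- local({
  env <- new.env()
  function() {
    if (is.null(env$b)) env$b <- simulate_bundle(small_config())
    env$b
  }
})

tiny_layout <- function(lens = c(chrA = 100000, chrB = 50000))
  genome_layout(lens)

# base-level coverage of an interval table, for set-equality oracles
covered_bases <- function(x) {
  if (nrow(x) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(x)), function(i)
    paste0(x$chrom[i], ":", seq(x$start[i], x$end[i] - 1))))
}

# independent two-sided Fisher oracle: exhaustive enumeration of tables
# with the observed margins via the factorial formula
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) - lfactorial(k) -
    lfactorial(r1 - k) - lfactorial(c1 - k) - lfactorial(r2 - c1 + k)
  p <- exp(logp)
  min(1, sum(p[p <= p[k == a] * (1 + 1e-7)]))
}
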