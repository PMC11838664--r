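# Shared fixtures, built once per test run. Kept deliberately small; the
# heavier end-to-end fixtures live in test-acceptance.R.

# tiny genotype panel with LD
fix_panel <- function() {
  if (is.null(.fix$panel))
    .fix$panel <- simulate_genotypes(2000, 400, n_blocks = 8, r = 0.8,
                                     maf_range = c(0.1, 0.5), seed = 101)
  .fix$panel
}

# moderate cohort with a planted gradient, used by gwas/ldsc tests
fix_cohort <- function() {
  if (is.null(.fix$cohort)) {
    tr <- truth_record(h2 = 0.5, rg_fact = 0.6, seed = 102)
    co <- simulate_item_phenotypes(fix_panel(), tr, seed = 102)
    .fix$cohort <- simulate_disorder(co, seed = 103)
  }
  .fix$cohort
}

# desk-scale LD score table for direct summary-statistic draws
fix_ld <- function(m = 2000, seed = 104) {
  with_seed_ <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  with_seed_(seed,
             ld_score_table(sprintf("rs%06d", seq_len(m)), runif(m, 1, 6), M = m))
}

.fix <- new.env(parent = emptyenv())

# basic valid sumstats data.frame
fix_ss_df <- function(n = 50, seed = 105) {
  set.seed(seed)
  data.frame(SNP = sprintf("rs%03d", seq_len(n)), CHR = rep(1L, n),
             BP = seq_len(n) * 1000L, A1 = rep("A", n), A2 = rep("G", n),
             FRQ = runif(n, 0.1, 0.9), N = rep(1000, n), Z = rnorm(n))
}
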