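test_that("LD scores: window-0, perfect proxies, and bias correction", {
  panel <- simulate_genotypes(500, 20, n_blocks = 20, r = 0,
                              maf_range = c(0.2, 0.5), seed = 31)
  # window 0: self only, unadjusted
  ld0 <- compute_ld_scores(panel, window = 0, adjusted = FALSE)
  expect_equal(ld0$l2, rep(1, 20))
  expect_equal(ld0$M, 20)
  # duplicated variant: unadjusted l = 2 for the pair
  panel2 <- panel
  panel2$dosage[, 2] <- panel2$dosage[, 1]
  ld2 <- compute_ld_scores(panel2, window = 5, adjusted = FALSE)
  expect_gte(ld2$l2[1], 2)
  expect_gte(ld2$l2[2], 2)
  # independent variants: unadjusted inflated by ~window/n, adjusted ~ 1
  panel3 <- simulate_genotypes(400, 300, n_blocks = 300, r = 0,
                               maf_range = c(0.2, 0.5), seed = 32)
  ldu <- compute_ld_scores(panel3, window = 20, adjusted = FALSE)
  lda <- compute_ld_scores(panel3, window = 20, adjusted = TRUE)
  expect_gt(mean(ldu$l2), 1 + 0.5 * 40 / 400)
  expect_lt(abs(mean(lda$l2) - 1), 0.02)
  # monomorphic variants excluded
  panel4 <- panel
  panel4$dosage[, 7] <- 2
  expect_message(ld4 <- compute_ld_scores(panel4, window = 0), "monomorphic")
  expect_equal(ld4$M, 19)
})

test_that("univariate fit recovers planted h2 and intercept", {
  ld <- fix_ld(2000)
  # h2 = 0.3, intercept 1
  h <- a <- numeric(10)
  for (r in 1:10) {
    ss <- simulate_sumstats_direct(ld, traits = list(list(h2 = 0.3, N = 50000)),
                                   seed = 400 + r)
    f <- fit_ldsc_univariate(ss[[1]], ld, n_blocks = 200)
    h[r] <- f$h2; a[r] <- f$intercept
  }
  expect_lt(abs(mean(h) - 0.3), 2 * sd(h) / sqrt(10) + 0.005)
  expect_lt(abs(mean(a) - 1), 2 * sd(a) / sqrt(10) + 0.05)
  # null h2
  ss0 <- simulate_sumstats_direct(ld, traits = list(list(h2 = 0, N = 50000)),
                                  seed = 401)
  f0 <- fit_ldsc_univariate(ss0[[1]], ld, n_blocks = 200)
  expect_lt(abs(f0$h2), 2 * f0$h2_se)
  # confounding inflation lands in the intercept, not the slope
  ssa <- simulate_sumstats_direct(ld, traits = list(list(h2 = 0, N = 50000, a = 1.2)),
                                  seed = 402)
  fa <- fit_ldsc_univariate(ssa[[1]], ld, n_blocks = 200)
  expect_lt(abs(fa$h2), 3 * fa$h2_se)
  expect_lt(abs(fa$intercept - 1.2), 3 * fa$intercept_se)
  # error paths
  expect_error(multivariate_ldsc(list(ss0[[1]]), ld_score_table("rs1", 2), 10),
               "fewer than 200")
})

test_that("bivariate fit: self-consistency, rg recovery, overlap isolation", {
  ld <- fix_ld(2000)
  ss <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = 0.5, N = 30000), list(h2 = 0.5, N = 30000)),
    rg_matrix = matrix(c(1, 0.5, 0.5, 1), 2), seed = 41)
  # identical trait twice recovers the univariate fit
  same <- fit_ldsc_bivariate(ss[[1]], ss[[1]], ld, n_blocks = 100)
  uni <- fit_ldsc_univariate(ss[[1]], ld, n_blocks = 100)
  expect_equal(same$gcov, uni$h2, tolerance = 1e-10)
  expect_equal(same$cross_intercept, uni$intercept, tolerance = 1e-10)
  expect_equal(same$rg, 1, tolerance = 1e-10)
  # planted rg recovered within 2 jackknife SEs
  biv <- fit_ldsc_bivariate(ss[[1]], ss[[2]], ld, n_blocks = 200)
  expect_lt(abs(biv$rg - 0.5), 2 * biv$rg_se)
  # complete overlap, rg 0: slope ~ 0, cross-intercept absorbs it
  ov <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = 0.3, N = 50000), list(h2 = 0.3, N = 50000)),
    rg_matrix = diag(2), overlap = list(N_s = 50000, pheno_corr = 0.5),
    seed = 42)
  fov <- fit_ldsc_bivariate(ov[[1]], ov[[2]], ld, n_blocks = 200)
  expect_lt(abs(fov$gcov), 3 * fov$gcov_se)
})

test_that("multivariate fit assembles a coherent joint structure", {
  ld <- fix_ld(2000)
  rgm <- matrix(c(1, .8, .2, .8, 1, .5, .2, .5, 1), 3)
  ss <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = .4, N = 40000), list(h2 = .4, N = 40000),
                      list(h2 = .4, N = 40000)),
    rg_matrix = rgm, seed = 43)
  st <- multivariate_ldsc(ss, ld, n_blocks = 200)
  # each off-diagonal R element within 2 joint-jackknife SEs of truth
  std <- standardize_S(st)
  seR <- sqrt(diag(std$V_R))
  for (pair in list(c(2, 1), c(3, 1), c(3, 2))) {
    pos <- pair[1] * (pair[1] - 1) / 2 + pair[2]
    expect_lt(abs(st$R[pair[1], pair[2]] - rgm[pair[1], pair[2]]),
              3 * seR[pos])
  }
  # duplicated trait: estimation errors perfectly correlated in V
  st2 <- multivariate_ldsc(list(ss[[1]], ss[[1]]), ld, n_blocks = 100)
  Vc <- cov2cor(st2$V_S)
  expect_equal(Vc[1, 2], 1, tolerance = 1e-8)
  expect_equal(Vc[1, 3], 1, tolerance = 1e-8)
  # k = 1 reduces exactly to the univariate fit
  st1 <- multivariate_ldsc(list(ss[[1]]), ld, n_blocks = 150)
  u1 <- fit_ldsc_univariate(ss[[1]], ld, n_blocks = 150)
  expect_identical(st1$h2[[1]], u1$h2)
  expect_identical(st1$intercepts[1, 1], u1$intercept)
})

test_that("liability conversion and its closed form", {
  expect_equal(liability_factor(0.5, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(liability_convert(0, sample_prev = 0.3, pop_prev = 0.1), 0)
  expect_error(liability_factor(0, 0.5))
  # struct conversion: binary scaled, continuous untouched, V consistent
  ld <- fix_ld(1500)
  ss <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = .3, N = 30000, binary = TRUE, P = 0.5, K = 0.2),
                      list(h2 = .3, N = 30000)),
    rg_matrix = matrix(c(1, .5, .5, 1), 2), seed = 44)
  st <- multivariate_ldsc(ss, ld, n_blocks = 100)
  cv <- liability_convert(st)
  cf <- liability_factor(0.5, 0.2)
  expect_equal(cv$S[1, 1], st$S[1, 1] * cf)
  expect_equal(cv$S[2, 2], st$S[2, 2])           # continuous: factor 1
  expect_equal(cv$S[1, 2], st$S[1, 2] * sqrt(cf)) # mixed pair: sqrt(c) only
  expect_equal(cv$V_S[1, 1], st$V_S[1, 1] * cf^2)
  expect_equal(cv$V_S[3, 3], st$V_S[3, 3])
  # rg invariant under scale conversion
  expect_equal(cv$S[1, 2] / sqrt(cv$S[1, 1] * cv$S[2, 2]),
               st$S[1, 2] / sqrt(st$S[1, 1] * st$S[2, 2]))
})

test_that("standardize_S: exactness, arithmetic, delta vs jackknife V_R", {
  # already a correlation matrix: R = S
  st <- list(S = matrix(c(1, .4, .4, 1), 2), V_S = diag(4) [1:3, 1:3] * 0.01)
  std <- standardize_S(st)
  expect_equal(std$R, st$S)
  # arithmetic case
  st2 <- list(S = matrix(c(4, 3, 3, 9), 2), V_S = diag(3) * 0.01)
  expect_equal(standardize_S(st2)$R[1, 2], 0.5)
  expect_error(standardize_S(list(S = matrix(c(-1, 0, 0, 1), 2),
                                  V_S = diag(3))), "non-positive")
  # delta-method V_R close to directly jackknifed V_R
  ld <- fix_ld(2000)
  ss <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = .4, N = 40000), list(h2 = .4, N = 40000)),
    rg_matrix = matrix(c(1, .6, .6, 1), 2), seed = 45)
  stD <- multivariate_ldsc(ss, ld, n_blocks = 200, R_method = "delta")
  stJ <- multivariate_ldsc(ss, ld, n_blocks = 200, R_method = "jackknife")
  expect_equal(stD$V_R[2, 2], stJ$V_R[2, 2], tolerance = 0.15)
})

test_that("smooth_to_psd clips eigenvalues and reports the change", {
  V <- diag(c(1, 2, 3))
  Vp <- smooth_to_psd(V)
  expect_equal(unclass(Vp), unclass(V), ignore_attr = TRUE)
  expect_equal(attr(Vp, "max_change"), 0)
  # 2x2 with eigenvalues (1, -0.01)
  Q <- cbind(c(1, 1), c(1, -1)) / sqrt(2)
  V2 <- Q %*% diag(c(1, -0.01)) %*% t(Q)
  V2p <- smooth_to_psd(V2, eps = 0)
  expect_gte(min(eigen(V2p)$values), -1e-15)
  expect_lte(attr(V2p, "max_change"), 0.01 + 1e-12)
  # zero matrix unchanged
  expect_equal(unclass(smooth_to_psd(matrix(0, 2, 2))), matrix(0, 2, 2),
               ignore_attr = TRUE)
})

test_that("struct round-trips through its directory serialization", {
  ld <- fix_ld(1200)
  ss <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = .4, N = 20000), list(h2 = .4, N = 20000)),
    rg_matrix = matrix(c(1, .5, .5, 1), 2), seed = 46)
  st <- multivariate_ldsc(ss, ld, n_blocks = 50)
  d <- withr::local_tempdir()
  write_struct(st, d)
  st2 <- read_struct(d)
  expect_equal(st2$S, st$S, tolerance = 1e-12)
  expect_equal(st2$R, st$R, tolerance = 1e-12)
  expect_equal(st2$V_S, unname(st$V_S), tolerance = 1e-12)
  expect_equal(st2$h2, st$h2, tolerance = 1e-12)
  expect_equal(st2$scale, "observed")
})
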