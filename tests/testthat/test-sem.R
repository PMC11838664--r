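# build an exact model-implied correlation structure for recovery tests
make_exact_struct <- function(spec, lambda, psi, theta_resid, v_diag = 1e-6) {
  S <- lambda %*% psi %*% t(lambda) + diag(theta_resid)
  k <- nrow(S)
  traits <- spec$indicators
  dimnames(S) <- list(traits, traits)
  nc <- k * (k + 1) / 2
  structure(list(traits = traits, S = S, R = S, intercepts = diag(k),
                 V_S = diag(v_diag, nc), V_R = diag(v_diag, nc),
                 h2 = diag(S), h2_se = rep(0.01, k), n_blocks = 200,
                 n_var = 2000, scale = "observed", R_method = "delta",
                 vech = vech_index(k), trait_meta = vector("list", k),
                 jackknife = NULL),
            class = "genetic_cov_struct")
}

paper_pattern_theta <- function(spec, seed = 60) {
  set.seed(seed)
  L <- spec$lambda_fixed
  # gradient of loadings: low factor fades and high factor rises with rank
  wl <- which(spec$lambda_free, arr.ind = TRUE)
  k <- length(spec$cut_names)
  for (r in seq_len(nrow(wl))) {
    a <- wl[r, 1]; f <- wl[r, 2]
    if (a > k) { L[a, f] <- 1; next }  # external single-indicator latent
    w <- (a - 1) / (k - 1)
    L[a, f] <- 0.9 * (if (f == 1) 1 - w else w) + 0.05
  }
  psi <- diag(ncol(L))
  psi[1, 2] <- psi[2, 1] <- 0.6
  nf <- spec$n_factors
  if (ncol(L) > nf) {  # external trait correlations
    for (e in (nf + 1):ncol(L)) {
      psi[1, e] <- psi[e, 1] <- 0.45
      psi[2, e] <- psi[e, 2] <- 0.72
    }
  }
  comm <- diag(L %*% psi %*% t(L))
  theta <- ifelse(spec$theta_free, pmax(1 - comm, 0.1), 0)
  list(L = L, psi = psi, theta = theta)
}

test_that("model specs reproduce the anchor patterns and parameter counts", {
  # 12 cuts, 1 factor: q = 24, df = 78 - 24 = 54
  s1 <- build_severity_factor_model(12, 1)
  expect_equal(s1$q, 24)
  expect_equal(s1$df, 54)
  expect_true(all(s1$lambda_free[, 1]))
  # 2 factors + external: low 1-11, high 2-12, external correlates with both
  s2 <- build_severity_factor_model(12, 2, external_traits = "MDD")
  expect_equal(unname(which(s2$lambda_free[, 1])), 1:11)
  expect_equal(unname(which(s2$lambda_free[, 2])), 2:12)
  expect_true(s2$lambda_free[13, 3])   # free scale loading of the external
  expect_false(s2$theta_free[13])      # zero residual: single indicator
  expect_equal(sum(s2$psi_free), 3)
  # 3 factors: low 1-5, mid 2-10, high 8-12
  s3 <- build_severity_factor_model(12, 3)
  expect_equal(unname(which(s3$lambda_free[, 1])), 1:5)
  expect_equal(unname(which(s3$lambda_free[, 2])), 2:10)
  expect_equal(unname(which(s3$lambda_free[, 3])), 8:12)
  expect_error(build_severity_factor_model(3, 3), "k_cuts")
})

test_that("exact recovery: S built from known theta is recovered to 1e-6", {
  spec <- build_severity_factor_model(12, 2, external_traits = "MDD")
  tp <- paper_pattern_theta(spec)
  st <- make_exact_struct(spec, tp$L, tp$psi, tp$theta)
  fit <- sem_fit_dwls(spec, st)
  expect_true(fit$converged)
  expect_lt(fit$F_min, 1e-10)
  expect_equal(unname(fit$lambda[spec$lambda_free]),
               unname(tp$L[spec$lambda_free]), tolerance = 1e-6)
  expect_equal(fit$psi[1, 2], 0.6, tolerance = 1e-6)
  expect_equal(unname(fit$theta_resid[spec$theta_free]),
               unname(tp$theta[spec$theta_free]), tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-8)
  expect_equal(fit$CFI, 1)
  expect_lt(fit$SRMR, 1e-6)
})

test_that("saturated model fits exactly with df 0", {
  # 3 indicators, 1 factor: q = 6 = p*, saturated
  spec <- build_severity_factor_model(3, 1)
  expect_equal(spec$df, 0)
  psi <- matrix(1, 1, 1)
  L <- matrix(c(0.8, 0.7, 0.6), 3, 1)
  st <- make_exact_struct(spec, L, psi, 1 - c(0.64, 0.49, 0.36))
  fit <- sem_fit_dwls(spec, st)
  expect_lt(max(abs(fit$s - vech(fit$lambda %*% fit$psi %*% t(fit$lambda) +
                                   diag(fit$theta_resid)))), 1e-6)
  expect_equal(fit$chisq, 0)
  expect_equal(fit$df, 0)
})

test_that("fit statistics: independence truth gives chisq 0; dual oracle", {
  # identity R: the independence model is true
  spec <- build_severity_factor_model(4, 1)
  st <- make_exact_struct(spec, matrix(0.7, 4, 1), matrix(1, 1, 1),
                          rep(1 - 0.49, 4), v_diag = 1e-4)
  st$R <- st$S <- diag(4); dimnames(st$S) <- dimnames(st$R) <- list(st$traits, st$traits)
  fit <- suppressWarnings(sem_fit_dwls(spec, st))
  expect_equal(fit$chisq_independence, 0, tolerance = 1e-8)
  # chi-square equals an independent evaluation of the same quadratic form
  ld <- fix_ld(1500)
  rgm <- outer(1:4, 1:4, function(i, j) 0.9^abs(i - j))
  ss <- simulate_sumstats_direct(
    ld, traits = lapply(1:4, function(i) list(h2 = .4, N = 30000,
                                     trait_id = paste0("cut", i))),
    rg_matrix = rgm, seed = 61)
  stx <- multivariate_ldsc(ss, ld, n_blocks = 100)
  fitx <- suppressWarnings(sem_fit_dwls(spec, stx))
  e <- fitx$s - vech(fitx$lambda %*% fitx$psi %*% t(fitx$lambda) +
                       diag(fitx$theta_resid))
  V <- fitx$V
  Vs <- smooth_to_psd(V, eps = 1e-12 * max(diag(V)))
  Vi <- solve(Vs)
  J <- gtaccc:::.sem_jacobian(fitx$estimates$est, spec)
  U <- Vi - Vi %*% J %*% solve(t(J) %*% Vi %*% J, t(J) %*% Vi)
  expect_equal(fitx$chisq, drop(t(e) %*% U %*% e), tolerance = 1e-8)
})

test_that("indicator reordering permutes estimates, not fit statistics", {
  spec <- build_severity_factor_model(6, 2)
  tp <- paper_pattern_theta(spec, seed = 62)
  st <- make_exact_struct(spec, tp$L, tp$psi, tp$theta, v_diag = 1e-4)
  # add structured noise so the fit is not exact
  set.seed(63)
  nz <- vech_index(6)
  noise <- rnorm(nrow(nz), 0, 0.01) * (nz$row != nz$col)
  st$S <- st$R <- unvech(vech(st$S) + noise)
  dimnames(st$S) <- dimnames(st$R) <- list(st$traits, st$traits)
  fit <- sem_fit_dwls(spec, st)
  p <- c(3, 1, 2, 6, 5, 4)
  st2 <- st
  st2$traits <- st$traits[p]
  perm_s <- st$S[p, p]; dimnames(perm_s) <- list(st2$traits, st2$traits)
  st2$S <- st2$R <- perm_s
  idx <- vech_index(6)
  pos <- vech_pos(p[idx$row], p[idx$col], 6)
  st2$V_S <- st2$V_R <- st$V_S[pos, pos]
  # same spec (indicator names select the right rows from the permuted struct)
  fit2 <- sem_fit_dwls(spec, st2)
  expect_equal(fit2$chisq, fit$chisq, tolerance = 1e-6)
  expect_equal(fit2$SRMR, fit$SRMR, tolerance = 1e-8)
  expect_equal(fit2$AIC, fit$AIC, tolerance = 1e-6)
  expect_equal(fit2$estimates$est, fit$estimates$est, tolerance = 1e-4)
})

test_that("nested specs have non-increasing minimized fit function", {
  ld <- fix_ld(1500)
  k <- 8
  rgm <- outer(1:k, 1:k, function(i, j) 0.92^abs(i - j))
  ss <- simulate_sumstats_direct(
    ld, traits = lapply(1:k, function(i) list(h2 = .4, N = 40000,
                                              trait_id = paste0("cut", i))),
    rg_matrix = rgm, seed = 64)
  st <- multivariate_ldsc(ss, ld, n_blocks = 100)
  f1 <- suppressWarnings(sem_fit_dwls(build_severity_factor_model(k, 1), st))
  f2 <- suppressWarnings(sem_fit_dwls(build_severity_factor_model(k, 2), st))
  expect_lte(f2$F_min, f1$F_min + 1e-8)
})

test_that("sem fits serialize to JSON", {
  spec <- build_severity_factor_model(4, 1)
  st <- make_exact_struct(spec, matrix(0.7, 4, 1), matrix(1, 1, 1),
                          rep(0.51, 4))
  fit <- sem_fit_dwls(spec, st)
  p <- withr::local_tempfile(fileext = ".json")
  write_sem_fit(fit, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$AIC, fit$AIC)
  expect_equal(j$estimates$est, fit$estimates$est)
})
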