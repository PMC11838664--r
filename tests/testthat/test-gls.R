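# independent brute-force evaluation of the GLS formulas, used as the
# dual-implementation oracle
gls_brute <- function(y, X, V) {
  Vi <- solve(V)
  covb <- solve(t(X) %*% Vi %*% X)
  list(beta = drop(covb %*% t(X) %*% Vi %*% y), covb = covb)
}

test_that("gls_fit matches the closed-form worked example exactly", {
  d <- list(y = c(0.5, 0.7, 0.9), X = cbind(intercept = 1, x = c(-1, 0, 1)),
            V = diag(0.01, 3))
  f <- gls_fit(d)
  expect_equal(f$coefficients$est, c(0.7, 0.2), tolerance = 1e-12)
  expect_equal(f$coefficients$se[2], sqrt(0.005), tolerance = 1e-12)
  expect_equal(f$residuals, rep(0, 3), tolerance = 1e-12)
})

test_that("gls_fit equals OLS under V = s2 I and brute force under dense V", {
  set.seed(51)
  for (r in 1:20) {
    n <- sample(4:12, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- rnorm(n)
    s2 <- runif(1, 0.1, 3)
    f <- gls_fit(list(y = y, X = X, V = diag(s2, n)))
    expect_equal(f$coefficients$est, unname(coef(lm(y ~ 0 + X))),
                 tolerance = 1e-12)
    # dense PD V: brute-force formula evaluation to 1e-12
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) + diag(n)
    f2 <- gls_fit(list(y = y, X = X, V = V))
    ref <- gls_brute(y, X, V)
    expect_equal(f2$coefficients$est, ref$beta, tolerance = 1e-12)
    expect_equal(unname(f2$vcov), unname(ref$covb), tolerance = 1e-12)
  }
})

test_that("gls_fit invariances: reordering and V rescaling", {
  set.seed(52)
  n <- 8
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  A <- matrix(rnorm(n * n), n); V <- crossprod(A) + diag(n)
  f <- gls_fit(list(y = y, X = X, V = V))
  p <- sample(n)
  fp <- gls_fit(list(y = y[p], X = X[p, ], V = V[p, p]))
  expect_equal(fp$coefficients$est, f$coefficients$est, tolerance = 1e-10)
  expect_equal(fp$coefficients$se, f$coefficients$se, tolerance = 1e-10)
  # scaling V by c > 0: same beta, SEs scale by sqrt(c)
  fc <- gls_fit(list(y = y, X = X, V = 4 * V))
  expect_equal(fc$coefficients$est, f$coefficients$est, tolerance = 1e-10)
  expect_equal(fc$coefficients$se, 2 * f$coefficients$se, tolerance = 1e-10)
  expect_error(gls_fit(list(y = y, X = cbind(1, 1)[rep(1, n), ], V = V)),
               "rank deficient")
})

test_that("build_gls_inputs selects the right elements in both modes", {
  ld <- fix_ld(1500)
  k <- 5
  rgm <- outer(1:k, 1:k, function(i, j) 0.9^abs(i - j))
  tr <- lapply(1:k, function(i)
    list(h2 = 0.4, N = 30000, trait_id = if (i < k) paste0("cut", i) else "dis"))
  ss <- simulate_sumstats_direct(ld, traits = tr, rg_matrix = rgm, seed = 53)
  st <- multivariate_ldsc(ss, ld, n_blocks = 100)
  z <- c(-1, -0.3, 0.4, 1.2)
  d <- build_gls_inputs(st, z, mode = "external", external = "dis")
  expect_equal(d$y, unname(st$R[1:4, 5]))
  expect_equal(dim(d$X), c(4, 2))
  expect_equal(dim(d$V), c(4, 4))
  # quadratic: 3 columns, centered
  dq <- build_gls_inputs(st, z, mode = "external", external = "dis",
                         quadratic = TRUE)
  expect_equal(dim(dq$X), c(4, 3))
  expect_equal(mean(dq$X[, 2]), 0, tolerance = 1e-12)
  # decay mode: k-1 outcomes against severity distance
  dd <- build_gls_inputs(st, z, mode = "decay", cuts = 1:4)
  expect_equal(length(dd$y), 3)
  expect_equal(dd$y, unname(st$R[2:4, 1]))
  expect_equal(dd$X[, 2], z[2:4] - z[1])
  # V_y rows match the selected elements: compare against direct lookup
  pos <- vech_pos(2:4, rep(1, 3), 5)
  expect_equal(dd$V, st$V_R[pos, pos])
  expect_error(build_gls_inputs(st, z, external = "nope"), "not in struct")
  expect_error(build_gls_inputs(st, z[1:2], external = "dis"), "length")
  expect_error(build_gls_inputs(st, -1, external = "dis", cuts = 1),
               "need >= 2 elements")
})

test_that("trend and decay round-trips on planted correlation structures", {
  ld <- fix_ld(2000)
  k <- 7
  # planted rising rg with the external trait; cuts near-collinear
  z <- seq(-1.2, 1.8, length.out = k - 1)
  rg_ext <- 0.55 + 0.1 * z
  rgm <- outer(1:k, 1:k, function(i, j) 0.98^abs(i - j))
  rgm[k, 1:(k - 1)] <- rgm[1:(k - 1), k] <- rg_ext
  stopifnot(min(eigen(rgm)$values) > 0)
  tr <- lapply(1:k, function(i)
    list(h2 = 0.5, N = 60000,
         trait_id = if (i < k) paste0("cut", i) else "dis"))
  sig <- 0
  for (r in 1:5) {
    ss <- simulate_sumstats_direct(ld, traits = tr, rg_matrix = rgm,
                                   seed = 540 + r)
    st <- multivariate_ldsc(ss, ld, n_blocks = 200)
    f <- severity_trend_test(st, z, external = "dis")
    if (f$coefficients$est[2] > 0 && f$coefficients$p[2] < 0.05) sig <- sig + 1
  }
  expect_gte(sig, 4)  # planted positive trend detected
  # decay: correlations fall off with distance from cut 1
  rgm2 <- outer(1:k, 1:k, function(i, j) pmax(1 - 0.06 * abs(i - j), 0))
  zc <- seq(-1.5, 1.5, length.out = k)
  ss2 <- simulate_sumstats_direct(
    ld, traits = lapply(1:k, function(i) list(h2 = 0.5, N = 60000,
                                     trait_id = paste0("cut", i))),
    rg_matrix = rgm2, seed = 55)
  st2 <- multivariate_ldsc(ss2, ld, n_blocks = 200)
  fd <- decay_test(st2, zc)
  expect_lt(fd$coefficients$est[2], 0)
  # constant y with V = I: slope exactly 0
  f0 <- gls_fit(list(y = rep(0.4, 5), X = cbind(1, 1:5), V = diag(5)))
  expect_equal(f0$coefficients$est[2], 0, tolerance = 1e-14)
})

test_that("GLS SEs differ from WLS SEs when estimation errors correlate", {
  ld <- fix_ld(1500)
  rgm <- matrix(c(1, .9, .5, .9, 1, .6, .5, .6, 1), 3)
  ss <- simulate_sumstats_direct(
    ld, traits = list(list(h2 = .4, N = 30000, trait_id = "cut1"),
                      list(h2 = .4, N = 30000, trait_id = "cut2"),
                      list(h2 = .4, N = 30000, trait_id = "dis")),
    rg_matrix = rgm, overlap = list(N_s = 30000, pheno_corr = 0.4), seed = 56)
  st <- multivariate_ldsc(ss, ld, n_blocks = 100)
  d <- build_gls_inputs(st, c(-0.5, 0.5), mode = "external", external = "dis")
  f_gls <- gls_fit(d)
  d_wls <- d; d_wls$V <- diag(diag(d$V))
  f_wls <- gls_fit(d_wls)
  expect_false(isTRUE(all.equal(f_gls$coefficients$se, f_wls$coefficients$se)))
})

test_that("gls fits serialize to JSON", {
  f <- gls_fit(list(y = c(0.5, 0.7, 0.9), X = cbind(a = 1, b = c(-1, 0, 1)),
                    V = diag(0.01, 3)))
  p <- withr::local_tempfile(fileext = ".json")
  write_gls_fit(f, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$coefficients$est, f$coefficients$est)
})
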