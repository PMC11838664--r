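# LD score regression: LD score estimation, univariate / bivariate /
# multivariate fits with a joint block jackknife, liability conversion,
# standardization, and PSD smoothing.

#' Construct an LD score table
#'
#' @param snp variant ids.
#' @param l2 LD scores (finite, >= 1 with the unadjusted estimator).
#' @param M number of variants in the regression denominator.
#' @return data.frame of class `ld_score_table` with attribute-style field
#'   `M` stored as a column-independent list element.
#' @export
ld_score_table <- function(snp, l2, M = length(l2)) {
  stopifnot(length(snp) == length(l2), all(is.finite(l2)), M > 0)
  structure(list(snp = as.character(snp), l2 = as.numeric(l2), M = M),
            class = "ld_score_table")
}

#' Estimate LD scores from a genotype panel
#'
#' `l_j` is the sum of squared sample dosage correlations between variant
#' `j` and every variant within `window` positions (self term included).
#' The adjusted estimator subtracts the small-sample bias of each r^2:
#' `r2_adj = r2 - (1 - r2) / (n - 2)`, so independent variants contribute
#' ~0 rather than ~1/n each.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param window number of flanking variants on each side (0 = self only).
#' @param adjusted apply the small-sample bias correction (default TRUE).
#' @return an [ld_score_table()]; monomorphic variants are excluded with a
#'   message.
#' @export
compute_ld_scores <- function(panel, window = 50, adjusted = TRUE) {
  stopifnot(inherits(panel, "geno_panel"), window >= 0)
  X <- panel$dosage
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(pmax(colMeans(X^2) - mu^2, 0) * n / (n - 1))
  keep <- sds > 0
  if (any(!keep))
    message(sprintf("compute_ld_scores: %d monomorphic variants excluded",
                    sum(!keep)))
  kcols <- which(keep)
  m <- length(kcols)
  l2 <- rep(1, m)  # self term (r2 = 1; adjusted self term is also 1)
  if (window > 0 && m > 1) {
    # banded crossprod in overlapping column chunks (BLAS-friendly);
    # columns standardized chunk-wise to avoid a full scaled copy
    chunk <- max(2L * window, 256L)
    for (s0 in seq(1L, m, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, m)
      e1 <- min(s1 + window, m)
      cols <- kcols[s0:e1]
      Xc <- sweep(X[, cols, drop = FALSE], 2, mu[cols])
      Xc <- sweep(Xc, 2, sds[cols], `/`)
      Rc <- crossprod(Xc) / (n - 1)
      r2 <- Rc^2
      if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
      nloc <- e1 - s0 + 1L
      for (jj in seq_len(s1 - s0 + 1L)) {
        lo <- jj + 1L
        hi <- min(jj + window, nloc)
        if (lo > hi) next
        contrib <- r2[jj, lo:hi]
        l2[s0 + jj - 1L] <- l2[s0 + jj - 1L] + sum(contrib)
        tgt <- (s0 + lo - 1L):(s0 + hi - 1L)
        l2[tgt] <- l2[tgt] + contrib
      }
    }
  }
  ld_score_table(panel$snp$SNP[keep], l2, M = m)
}

# weighted regression of y on (1, x): full-sample and delete-one-block
# estimates from per-block sufficient statistics.
.wreg_blocks <- function(y, x, w, block) {
  sw <- rowsum(w, block); swx <- rowsum(w * x, block)
  swy <- rowsum(w * y, block); swxx <- rowsum(w * x^2, block)
  swxy <- rowsum(w * x * y, block)
  B <- cbind(sw, swx, swy, swxx, swxy)
  tot <- colSums(B)
  solve2 <- function(s) {
    # s = (sw, swx, swy, swxx, swxy); returns (intercept, slope)
    det <- s[1] * s[4] - s[2]^2
    c((s[4] * s[3] - s[2] * s[5]) / det, (s[1] * s[5] - s[2] * s[3]) / det)
  }
  est <- solve2(tot)
  del <- t(apply(B, 1, function(b) solve2(tot - b)))
  list(est = est, del = del)  # columns: intercept, slope
}

# two-pass heteroskedasticity weights, one trait
.univ_weights <- function(z2, x, l2, blocks) {
  p1 <- .wreg_blocks(z2, x, 1 / pmax(l2, 1), blocks)
  a0 <- max(p1$est[1], 0)
  h0x <- pmin(pmax(p1$est[2], 0) * x, 2)  # N h2 l/M contribution, clamped
  v <- pmax(h0x + a0, 0.05)
  list(v = v, w = 1 / (pmax(l2, 1) * v^2))
}

# one LDSC regression cell (i = j gives the heritability cell)
.ldsc_cell <- function(zi, zj, xij, l2, blocks, vi, vj) {
  y <- zi * zj
  if (identical(vi, vj) && identical(zi, zj)) {
    w <- 1 / (pmax(l2, 1) * vi^2)
  } else {
    p1 <- .wreg_blocks(y, xij, 1 / pmax(l2, 1), blocks)
    c12 <- p1$est[2] * xij + p1$est[1]
    w <- 1 / (pmax(l2, 1) * pmax(vi * vj + c12^2, 0.05))
  }
  .wreg_blocks(y, xij, w, blocks)
}

#' Multivariate LD score regression with a joint block jackknife
#'
#' Every cell of the k x k genetic covariance matrix `S` (diagonal:
#' observed-scale heritabilities; off-diagonal: genetic covariances) is
#' estimated as a weighted regression of `z_i z_j` on
#' `sqrt(N_i N_j) l / M` with a free intercept, on the *same* variant set
#' and the *same* partition into contiguous variant blocks. The joint
#' delete-one-block estimates of all `vech(S)` elements give the sampling
#' covariance matrix `V_S`, capturing dependencies of estimation errors
#' across cells (the quantity GLS and SEM weighting require). `R` and
#' `V_R` are produced either by delta-method standardization of (`S`,
#' `V_S`) or by jackknifing the standardized elements directly.
#'
#' @param traits list of [sumstats] (k >= 1); aligned internally via
#'   [align_traits()] when k >= 2.
#' @param ld an [ld_score_table()].
#' @param n_blocks number of contiguous jackknife blocks (default 200,
#'   capped at half the variant count).
#' @param R_method `"delta"` (default; first-order delta method from
#'   `V_S`) or `"jackknife"` (delete-one-block standardized elements).
#' @return object of class `genetic_cov_struct`: list with `traits`
#'   (ids), `S`, `R`, `intercepts`, `V_S`, `V_R`, `h2`, `h2_se`,
#'   `n_blocks`, `scale`, `trait_meta`, and `vech` (the index table
#'   documenting element order in `V_S`/`V_R`).
#' @export
multivariate_ldsc <- function(traits, ld, n_blocks = 200,
                              R_method = c("delta", "jackknife")) {
  R_method <- match.arg(R_method)
  stopifnot(length(traits) >= 1, inherits(ld, "ld_score_table"))
  if (length(traits) >= 2) traits <- align_traits(traits)
  k <- length(traits)
  ids <- traits[[1]]$data$SNP
  mm <- match(ids, ld$snp)
  keep <- !is.na(mm)
  if (sum(keep) < 200) stop("fewer than 200 variants shared with the LD score table")
  ord <- order(traits[[1]]$data$CHR[keep], traits[[1]]$data$BP[keep])
  sel <- which(keep)[ord]
  l2 <- ld$l2[mm[keep]][ord]
  M <- ld$M
  nv <- length(sel)
  n_blocks <- min(n_blocks, floor(nv / 2))
  if (n_blocks < 2) stop("need at least 2 jackknife blocks")
  blocks <- sort(rep_len(seq_len(n_blocks), nv))
  Z <- vapply(traits, function(s) s$data$Z[sel], numeric(nv))
  Nmat <- vapply(traits, function(s) s$data$N[sel], numeric(nv))
  if (any(!is.finite(l2)) || var(l2) == 0)
    stop("LD scores constant across variants: slope unidentified")

  wts <- lapply(seq_len(k), function(t)
    .univ_weights(Z[, t]^2, Nmat[, t] * l2 / M, l2, blocks))
  idx <- vech_index(k)
  nc <- nrow(idx)
  S <- matrix(NA_real_, k, k); A <- matrix(NA_real_, k, k)
  D_int <- matrix(NA_real_, n_blocks, nc)
  D_slope <- matrix(NA_real_, n_blocks, nc)
  for (c in seq_len(nc)) {
    i <- idx$row[c]; j <- idx$col[c]
    xij <- sqrt(Nmat[, i] * Nmat[, j]) * l2 / M
    fit <- .ldsc_cell(Z[, i], Z[, j], xij, l2, blocks, wts[[i]]$v, wts[[j]]$v)
    S[i, j] <- S[j, i] <- fit$est[2]
    A[i, j] <- A[j, i] <- fit$est[1]
    D_slope[, c] <- fit$del[, 2]
    D_int[, c] <- fit$del[, 1]
  }
  jack_cov <- function(D) {
    Dc <- sweep(D, 2, colMeans(D))
    crossprod(Dc) * (n_blocks - 1) / n_blocks
  }
  V_S <- jack_cov(D_slope)
  h2 <- diag(S)
  h2_se <- sqrt(diag(V_S)[vech_pos(seq_len(k), seq_len(k), k)])
  int_se <- sqrt(diag(jack_cov(D_int)))
  tids <- vapply(traits, function(s) s$meta$trait_id, "")
  dimnames(S) <- dimnames(A) <- list(tids, tids)
  struct <- structure(list(
    traits = tids, S = S, R = NULL, intercepts = A, V_S = V_S, V_R = NULL,
    h2 = stats::setNames(h2, tids), h2_se = stats::setNames(h2_se, tids),
    intercept_se = unvech(int_se, k),
    mean_chi2 = stats::setNames(colMeans(Z^2), tids),
    n_blocks = n_blocks, n_var = nv, scale = "observed",
    R_method = R_method, vech = idx,
    trait_meta = lapply(traits, function(s) s$meta),
    jackknife = list(S = D_slope, intercept = D_int)),
    class = "genetic_cov_struct")
  if (all(h2 > 0)) {
    std <- standardize_S(struct)
    struct$R <- std$R
    struct$V_R <- if (R_method == "delta") std$V_R else .jackknife_R(struct)
  }
  struct
}

# V_R by delete-one-block standardization of the jackknifed S estimates
.jackknife_R <- function(struct) {
  k <- length(struct$traits)
  D <- struct$jackknife$S
  Dr <- t(apply(D, 1, function(v) {
    Sb <- unvech(v, k)
    d <- diag(Sb)
    if (any(d <= 0)) return(rep(NA_real_, ncol(D)))
    vech(Sb / sqrt(d %o% d))
  }))
  Dr <- Dr[stats::complete.cases(Dr), , drop = FALSE]
  nb <- nrow(Dr)
  Dc <- sweep(Dr, 2, colMeans(Dr))
  crossprod(Dc) * (nb - 1) / nb
}

#' @export
print.genetic_cov_struct <- function(x, ...) {
  cat(sprintf("<genetic_cov_struct: %d traits, %d variants, %d jackknife blocks, %s scale>\n",
              length(x$traits), x$n_var, x$n_blocks, x$scale))
  cat("h2:", sprintf("%.4f (%.4f)", x$h2, x$h2_se), "\n")
  invisible(x)
}

#' Univariate LD score regression
#'
#' Weighted regression of chi-square on `N l / M` with a free intercept;
#' two-pass heteroskedasticity weights
#' `1 / [max(l, 1) (N h2 l / M + a)^2]`; SEs by delete-one-block jackknife.
#'
#' @param s a [sumstats] object.
#' @param ld an [ld_score_table()].
#' @param n_blocks jackknife blocks (default 200).
#' @return list with `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `mean_chi2`, `n_var`, and the underlying `struct`.
#' @export
fit_ldsc_univariate <- function(s, ld, n_blocks = 200) {
  st <- multivariate_ldsc(list(s), ld, n_blocks = n_blocks)
  list(h2 = unname(st$h2[1]), h2_se = unname(st$h2_se[1]),
       intercept = st$intercepts[1, 1],
       intercept_se = st$intercept_se[1, 1],
       mean_chi2 = unname(st$mean_chi2[1]), n_var = st$n_var, struct = st)
}

#' Bivariate (cross-trait) LD score regression
#'
#' Weighted regression of `z_1 z_2` on `sqrt(N_1 N_2) l / M` with a free
#' cross-trait intercept absorbing sample overlap
#' (`rho N_s / sqrt(N_1 N_2)`). The genetic correlation and its SE are
#' jackknifed jointly with the heritabilities.
#'
#' @param s1,s2 [sumstats] objects.
#' @param ld an [ld_score_table()].
#' @param n_blocks jackknife blocks.
#' @return list with `gcov`, `gcov_se`, `cross_intercept`,
#'   `cross_intercept_se`, `rg`, `rg_se`, `h2` (length 2), and `struct`.
#' @export
fit_ldsc_bivariate <- function(s1, s2, ld, n_blocks = 200) {
  st <- multivariate_ldsc(list(s1, s2), ld, n_blocks = n_blocks)
  D <- st$jackknife$S
  rg_del <- D[, 2] / sqrt(pmax(D[, 1] * D[, 3], .Machine$double.eps))
  nb <- nrow(D)
  rg <- st$S[1, 2] / sqrt(st$S[1, 1] * st$S[2, 2])
  rg_se <- sqrt(sum((rg_del - mean(rg_del))^2) * (nb - 1) / nb)
  list(gcov = st$S[1, 2], gcov_se = sqrt(st$V_S[2, 2]),
       cross_intercept = st$intercepts[1, 2],
       cross_intercept_se = st$intercept_se[1, 2],
       rg = rg, rg_se = rg_se, h2 = st$h2, h2_se = st$h2_se, struct = st)
}

#' Restrict a genetic covariance structure to a subset of traits
#'
#' Subsets `S`, `R`, the intercept matrix and the joint sampling
#' covariances consistently (the relevant rows/columns of `V` are selected
#' by their half-vectorization positions). Useful for pooling or dropping
#' cuts whose heritability estimate is non-positive.
#'
#' @param struct a `genetic_cov_struct`.
#' @param traits character vector of trait ids (or integer indices).
#' @return a `genetic_cov_struct` over the selected traits.
#' @export
subset_struct <- function(struct, traits) {
  stopifnot(inherits(struct, "genetic_cov_struct"))
  sel <- if (is.numeric(traits)) as.integer(traits)
  else match(traits, struct$traits)
  if (anyNA(sel)) stop("unknown trait(s)")
  k0 <- length(struct$traits)
  idx <- vech_index(length(sel))
  pos <- vech_pos(sel[idx$row], sel[idx$col], k0)
  sub <- function(M) if (is.null(M)) NULL else M[sel, sel, drop = FALSE]
  out <- struct
  out$traits <- unname(struct$traits[sel])
  out["S"] <- list(sub(struct[["S"]])); out["R"] <- list(sub(struct[["R"]]))
  out$intercepts <- sub(struct$intercepts)
  out$intercept_se <- sub(struct$intercept_se)
  out$V_S <- struct$V_S[pos, pos, drop = FALSE]
  out["V_R"] <- list(if (is.null(struct[["V_R"]])) NULL else struct[["V_R"]][pos, pos, drop = FALSE])
  out$h2 <- struct$h2[sel]; out$h2_se <- struct$h2_se[sel]
  if (!is.null(struct$mean_chi2)) out$mean_chi2 <- struct$mean_chi2[sel]
  out$vech <- idx
  out$trait_meta <- struct$trait_meta[sel]
  if (!is.null(struct$jackknife))
    out$jackknife <- list(S = struct$jackknife$S[, pos, drop = FALSE],
                          intercept = struct$jackknife$intercept[, pos, drop = FALSE])
  if (is.null(out[["R"]]) && all(out$h2 > 0)) {
    std <- standardize_S(out)
    out$R <- std$R
    out$V_R <- std$V_R
  }
  out
}

#' Observed-to-liability scale conversion factor
#'
#' `c = K^2 (1-K)^2 / [P (1-P) phi(t)^2]` with `t` the `1-K` standard
#' normal quantile: the classical conversion for heritability of a binary
#' trait analysed by a linear model under case-control sampling.
#'
#' @param P sample prevalence in (0, 1).
#' @param K population prevalence in (0, 1).
#' @return scalar conversion factor.
#' @export
liability_factor <- function(P, K) {
  stopifnot(P > 0, P < 1, K > 0, K < 1)
  t <- qnorm(1 - K)
  K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(t)^2)
}

#' Convert a genetic covariance structure to the liability scale
#'
#' Each binary trait `t` gets factor `c_t = liability_factor(P_t, K_t)`;
#' continuous traits get factor 1. Covariance element `(i, j)` is scaled
#' by `sqrt(c_i c_j)` and each element of `V_S` by the product of the two
#' corresponding element factors. `R`/`V_R` are scale invariant and left
#' unchanged. Numeric input scales a heritability directly.
#'
#' @param x a `genetic_cov_struct` or numeric observed-scale h2.
#' @param sample_prev,pop_prev prevalences; for a struct, taken from trait
#'   metadata when omitted (pop_prev falls back to sample_prev, the
#'   convention for cuts of an unascertained population sample).
#' @return converted struct (with `scale = "liability"`) or numeric h2.
#' @export
liability_convert <- function(x, sample_prev = NULL, pop_prev = NULL) {
  if (is.numeric(x)) return(x * liability_factor(sample_prev, pop_prev))
  stopifnot(inherits(x, "genetic_cov_struct"))
  if (identical(x$scale, "liability")) return(x)
  k <- length(x$traits)
  cf <- vapply(seq_len(k), function(t) {
    m <- x$trait_meta[[t]]
    if (!isTRUE(m$binary)) return(1)
    P <- sample_prev %||% m$sample_prev
    K <- pop_prev %||% m$pop_prev %||% P
    if (is.na(K)) K <- P
    liability_factor(P, K)
  }, 0)
  sc <- sqrt(cf)
  x$S <- x$S * (sc %o% sc)
  x$h2 <- x$h2 * cf
  x$h2_se <- x$h2_se * cf
  elem <- sc[x$vech$row] * sc[x$vech$col]
  x$V_S <- x$V_S * (elem %o% elem)
  x$jackknife$S <- sweep(x$jackknife$S, 2, elem, `*`)
  x$scale <- "liability"
  x
}

#' Standardize a genetic covariance matrix
#'
#' `R = D^{-1/2} S D^{-1/2}` with `D = diag(S)`; `V_R` by the first-order
#' delta method (`V_R = J V_S J'` with `J` the Jacobian of the
#' standardization map).
#'
#' @param struct a `genetic_cov_struct` with positive diagonal, or a plain
#'   list with elements `S` and `V_S`.
#' @return list with `R` and `V_R`.
#' @export
standardize_S <- function(struct) {
  S <- struct$S; V_S <- struct$V_S
  d <- diag(S)
  if (any(d <= 0))
    stop("non-positive diagonal of S: increase effective N or pool cuts")
  k <- nrow(S)
  R <- S / sqrt(d %o% d)
  idx <- vech_index(k)
  nc <- nrow(idx)
  J <- matrix(0, nc, nc)
  for (c in seq_len(nc)) {
    i <- idx$row[c]; j <- idx$col[c]
    if (i == j) next  # diagonal of R is fixed at 1
    J[c, vech_pos(i, j, k)] <- 1 / sqrt(d[i] * d[j])
    J[c, vech_pos(i, i, k)] <- -R[i, j] / (2 * d[i])
    J[c, vech_pos(j, j, k)] <- -R[i, j] / (2 * d[j])
  }
  list(R = R, V_R = J %*% V_S %*% t(J))
}

#' Serialize / load a genetic covariance structure as a directory of TSVs
#'
#' Writes `S.tsv`, `R.tsv`, `intercepts.tsv`, `V_S.tsv`, `V_R.tsv` and a
#' `manifest.json` documenting the half-vectorization order (row-major
#' lower triangle, diagonal included) and trait metadata.
#'
#' @param struct a `genetic_cov_struct`.
#' @param dir target directory (created).
#' @return `dir` (write) or a `genetic_cov_struct` (read; the jackknife
#'   replicate table is not round-tripped).
#' @export
write_struct <- function(struct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, f) utils::write.table(M, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          col.names = FALSE)
  wm(struct$S, "S.tsv"); wm(struct$intercepts, "intercepts.tsv")
  wm(struct$V_S, "V_S.tsv")
  if (!is.null(struct[["R"]])) wm(struct[["R"]], "R.tsv")
  if (!is.null(struct[["V_R"]])) wm(struct[["V_R"]], "V_R.tsv")
  manifest <- list(traits = struct$traits, n_blocks = struct$n_blocks,
                   n_var = struct$n_var, scale = struct$scale,
                   R_method = struct$R_method,
                   vech_order = "row-major lower triangle, diagonal included",
                   h2 = struct$h2, h2_se = struct$h2_se,
                   trait_meta = struct$trait_meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_struct
#' @export
read_struct <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rm_ <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    as.matrix(utils::read.table(p, sep = "\t", header = FALSE))
  }
  k <- length(man$traits)
  S <- rm_("S.tsv"); dimnames(S) <- list(man$traits, man$traits)
  R <- rm_("R.tsv"); if (!is.null(R)) dimnames(R) <- dimnames(S)
  A <- rm_("intercepts.tsv"); dimnames(A) <- dimnames(S)
  tm <- man$trait_meta
  if (is.data.frame(tm)) tm <- lapply(seq_len(nrow(tm)), function(i) as.list(tm[i, ]))
  structure(list(traits = man$traits, S = S, R = R, intercepts = A,
                 V_S = unname(rm_("V_S.tsv")), V_R = unname(rm_("V_R.tsv")),
                 h2 = stats::setNames(as.numeric(man$h2), man$traits),
                 h2_se = stats::setNames(as.numeric(man$h2_se), man$traits),
                 intercept_se = NULL, n_blocks = man$n_blocks,
                 n_var = man$n_var, scale = man$scale,
                 R_method = man$R_method, vech = vech_index(k),
                 trait_meta = tm, jackknife = NULL),
            class = "genetic_cov_struct")
}
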