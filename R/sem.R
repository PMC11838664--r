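# Severity-factor structural equation models fitted to (S or R, V) by
# diagonally weighted least squares, with sandwich standard errors and
# residual-based fit statistics.

#' Build a severity-factor model specification
#'
#' Overlapping subsets of cut-point indicators load on 1-3 correlated
#' severity factors, anchored by the extreme cuts:
#' * 1 factor: all cuts load on one factor (the liability-threshold
#'   limit).
#' * 2 factors: a low factor spans cuts `1..k-1`, a high factor `2..k`
#'   (for 12 cuts: 1-11 and 2-12).
#' * 3 factors: low `1..ceil(5k/12)`, mid `2..round(10k/12)`, high
#'   `(k-ceil(5k/12)+1)..k` (for 12 cuts: 1-5, 2-10, 8-12); the fractions
#'   generalize the 12-cut anchor pattern proportionally.
#'
#' Factors are standardized (unit variance) with all pattern loadings
#' free; factor correlations are free. External traits enter as
#' unit-variance single-indicator latents with a free loading (their
#' genetic SD on the fitted metric; estimates 1 when fitting `R`) and
#' residual fixed at 0, free to correlate with every factor.
#'
#' @param k_cuts number of cut-point indicators (>= n_factors + 1).
#' @param n_factors 1, 2 or 3 severity factors.
#' @param external_traits character vector of external trait ids.
#' @param cut_names indicator ids of the cuts (default `cut1..cutk`).
#' @return object of class `factor_model_spec`: list with `indicators`,
#'   `factor_names`, `lambda_free` (logical mask), `lambda_fixed`
#'   (values of fixed entries), `theta_free`, `psi_free`, `q` (free
#'   parameters), `p_star` (distinct moments), `df`.
#' @export
build_severity_factor_model <- function(k_cuts, n_factors,
                                        external_traits = character(),
                                        cut_names = paste0("cut", seq_len(k_cuts))) {
  stopifnot(n_factors %in% 1:3, k_cuts >= n_factors + 1,
            length(cut_names) == k_cuts)
  ranges <- switch(n_factors,
    list(low = seq_len(k_cuts)),
    list(low = seq_len(k_cuts - 1), high = 2:k_cuts),
    {
      lo_end <- ceiling(5 * k_cuts / 12)
      mid_end <- round(10 * k_cuts / 12)
      hi_start <- k_cuts - lo_end + 1
      list(low = seq_len(lo_end), mid = 2:mid_end, high = hi_start:k_cuts)
    })
  n_ext <- length(external_traits)
  fac_names <- c(names(ranges), external_traits)
  m_tot <- n_factors + n_ext
  p_ind <- k_cuts + n_ext
  indicators <- c(cut_names, external_traits)
  lambda_free <- matrix(FALSE, p_ind, m_tot,
                        dimnames = list(indicators, fac_names))
  lambda_fixed <- matrix(0, p_ind, m_tot,
                         dimnames = list(indicators, fac_names))
  for (f in seq_len(n_factors)) lambda_free[ranges[[f]], f] <- TRUE
  # external traits: unit-variance latent, free loading (the loading is
  # the trait's genetic SD on the fitted metric; 1 on the correlation
  # metric), zero residual
  for (e in seq_len(n_ext))
    lambda_free[k_cuts + e, n_factors + e] <- TRUE
  if (any(rowSums(lambda_free) + rowSums(lambda_fixed != 0) == 0))
    stop("an indicator loads on no factor")
  theta_free <- c(rep(TRUE, k_cuts), rep(FALSE, n_ext))
  psi_free <- upper.tri(matrix(TRUE, m_tot, m_tot))
  q <- sum(lambda_free) + sum(psi_free) + sum(theta_free)
  p_star <- p_ind * (p_ind + 1) / 2
  if (q > p_star)
    stop(sprintf("model not identified: %d free parameters > %d moments", q, p_star))
  structure(list(indicators = indicators, cut_names = cut_names,
                 external = external_traits, n_factors = n_factors,
                 factor_names = fac_names, lambda_free = lambda_free,
                 lambda_fixed = lambda_fixed, theta_free = theta_free,
                 psi_free = psi_free, q = q, p_star = p_star,
                 df = p_star - q),
            class = "factor_model_spec")
}

# --- parameter packing -------------------------------------------------

.sem_unpack <- function(theta, spec) {
  p <- nrow(spec$lambda_free); m <- ncol(spec$lambda_free)
  nl <- sum(spec$lambda_free); np <- sum(spec$psi_free)
  L <- spec$lambda_fixed
  L[spec$lambda_free] <- theta[seq_len(nl)]
  P <- diag(m)
  P[spec$psi_free] <- theta[nl + seq_len(np)]
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  Th <- rep(0, p)
  Th[spec$theta_free] <- theta[nl + np + seq_len(sum(spec$theta_free))]
  list(L = L, P = P, Th = Th)
}

.sem_sigma <- function(theta, spec) {
  u <- .sem_unpack(theta, spec)
  vech(u$L %*% u$P %*% t(u$L) + diag(u$Th, nrow(u$L)))
}

# analytic Jacobian d vech(Sigma) / d theta, p* x q
.sem_jacobian <- function(theta, spec) {
  u <- .sem_unpack(theta, spec)
  p <- nrow(u$L); idx <- vech_index(p)
  LP <- u$L %*% u$P
  cols <- list()
  wl <- which(spec$lambda_free, arr.ind = TRUE)
  for (r in seq_len(nrow(wl))) {
    a <- wl[r, 1]; f <- wl[r, 2]
    dS <- matrix(0, p, p)
    dS[a, ] <- dS[a, ] + LP[, f]
    dS[, a] <- dS[, a] + LP[, f]
    cols[[length(cols) + 1]] <- dS[cbind(idx$row, idx$col)]
  }
  wp <- which(spec$psi_free, arr.ind = TRUE)
  for (r in seq_len(nrow(wp))) {
    f <- wp[r, 1]; g <- wp[r, 2]
    dS <- u$L[, f] %o% u$L[, g] + u$L[, g] %o% u$L[, f]
    cols[[length(cols) + 1]] <- dS[cbind(idx$row, idx$col)]
  }
  for (a in which(spec$theta_free))
    cols[[length(cols) + 1]] <- as.numeric(idx$row == a & idx$col == a)
  do.call(cbind, cols)
}

# permute/subset a struct's matrix + V to a given trait order
.sem_moments <- function(struct, spec, use_R) {
  Mat <- if (use_R) struct[["R"]] else struct[["S"]]
  Vm <- if (use_R) struct[["V_R"]] else struct[["V_S"]]
  if (is.null(Mat) || is.null(Vm)) stop("struct lacks the requested matrix")
  perm <- match(spec$indicators, struct$traits)
  if (anyNA(perm))
    stop("struct does not cover indicators: ",
         paste(spec$indicators[is.na(perm)], collapse = ", "))
  k <- length(struct$traits)
  idx <- vech_index(length(perm))
  pos <- vech_pos(perm[idx$row], perm[idx$col], k)
  list(s = vech(Mat[perm, perm, drop = FALSE]), V = Vm[pos, pos, drop = FALSE])
}

#' Fit a severity-factor model by diagonally weighted least squares
#'
#' Minimizes `F(theta) = (s - sigma(theta))' W^-1 (s - sigma(theta))` with
#' `W = diag(V)` (the Genomic-SEM convention: the full `V` enters only the
#' sandwich standard errors and the fit statistic, where it corrects for
#' the non-optimal weight matrix). Quasi-Newton optimization with analytic
#' Jacobian and jittered multi-starts. Negative residual variances
#' (Heywood cases) are flagged, not bounded away.
#'
#' @param spec a [build_severity_factor_model()] spec.
#' @param struct a `genetic_cov_struct` covering all indicators.
#' @param use_R fit the correlation matrix `R` with `V_R` instead of `S`
#'   with `V_S`. The default is FALSE: the directly jackknifed `V_S` is
#'   well calibrated, whereas the first-order delta-method `V_R` is badly
#'   conservative when all indicators share one GWAS sample (numerator
#'   and denominator errors cancel beyond first order), which deflates
#'   the chi-square and removes all power to compare factor structures.
#' @param n_starts total optimizer starts (1 deterministic + jitters).
#' @param seed seed for the jittered starts.
#' @return object of class `sem_fit`: list with `estimates` (data.frame),
#'   `lambda`, `psi`, `theta_resid`, `F_min`, `converged`, `iterations`,
#'   `heywood`, and fit indices `chisq`, `df`, `p`, `CFI`, `SRMR`, `AIC`.
#' @export
sem_fit_dwls <- function(spec, struct, use_R = FALSE, n_starts = 5, seed = 1) {
  stopifnot(inherits(spec, "factor_model_spec"),
            inherits(struct, "genetic_cov_struct"))
  mom <- .sem_moments(struct, spec, use_R)
  s <- mom$s; V <- mom$V
  wd <- diag(V)
  wd[wd <= 0] <- min(wd[wd > 0])
  wi <- 1 / wd
  obj <- function(th) {
    e <- s - .sem_sigma(th, spec)
    sum(wi * e^2)
  }
  grad <- function(th) {
    e <- s - .sem_sigma(th, spec)
    J <- .sem_jacobian(th, spec)
    -2 * drop(crossprod(J, wi * e))
  }
  nl <- sum(spec$lambda_free); np <- sum(spec$psi_free)
  nt <- sum(spec$theta_free)
  # starts on the scale of the fitted matrix: the canonical 0.7 / 0.51
  # pattern assumes unit-variance indicators, so scale each row's start by
  # its own observed diagonal (1 when fitting R, the observed-scale h2
  # when fitting S)
  p_ind <- nrow(spec$lambda_free)
  idx0 <- vech_index(p_ind)
  sdiag <- pmax(s[idx0$row == idx0$col], 1e-4)
  wl0 <- which(spec$lambda_free, arr.ind = TRUE)
  start0 <- c(0.7 * sqrt(sdiag[wl0[, 1]]), rep(0.5, np),
              (1 - 0.49) * sdiag[spec$theta_free])
  lower <- c(rep(-Inf, nl), rep(-0.999, np), rep(-Inf, nt))
  upper <- c(rep(Inf, nl), rep(0.999, np), rep(Inf, nt))
  jit <- 0.15 * c(sqrt(sdiag[wl0[, 1]]), rep(1, np), sdiag[spec$theta_free])
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1) start0 else start0 + rnorm(length(start0), 0, jit)
  }))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(st, obj, gradient = grad, lower = lower, upper = upper,
                    control = list(iter.max = 1000, eval.max = 2000,
                                   rel.tol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimizer failed from every start")
  th <- best$par
  converged <- best$convergence == 0 || best$objective < 1e-10
  J <- .sem_jacobian(th, spec)
  B <- crossprod(J, wi * J)
  Bi <- tryCatch(solve(B), error = function(e) {
    warning("singular information matrix; SEs use a pseudoinverse", call. = FALSE)
    ev <- eigen(B, symmetric = TRUE)
    pos <- ev$values > 1e-12 * max(ev$values)
    ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  })
  JW <- wi * J
  cov_th <- Bi %*% crossprod(JW, V %*% JW) %*% Bi
  se <- sqrt(pmax(diag(cov_th), 0))
  u <- .sem_unpack(th, spec)
  heywood <- any(u$Th[spec$theta_free] < 0)
  if (heywood) warning("Heywood case: negative residual variance", call. = FALSE)
  wl <- which(spec$lambda_free, arr.ind = TRUE)
  wp <- which(spec$psi_free, arr.ind = TRUE)
  est <- data.frame(
    type = c(rep("loading", nl), rep("factor_cor", np), rep("residual", nt)),
    lhs = c(spec$indicators[wl[, 1]], spec$factor_names[wp[, 1]],
            spec$indicators[spec$theta_free]),
    rhs = c(spec$factor_names[wl[, 2]], spec$factor_names[wp[, 2]],
            spec$indicators[spec$theta_free]),
    est = th, se = se, z = th / se, p = 2 * pnorm(-abs(th / se)),
    row.names = NULL)
  fi <- .sem_fit_indices(s, V, th, spec)
  structure(c(list(estimates = est, lambda = u$L, psi = u$P,
                   theta_resid = u$Th, F_min = best$objective,
                   converged = converged, iterations = best$iterations,
                   heywood = heywood, spec = spec, cov_theta = cov_th,
                   s = s, V = V), fi),
            class = "sem_fit")
}

# residual-based chi-square (full V), CFI against the independence model,
# SRMR over distinct standardized elements, AIC = chisq + 2q
.sem_fit_indices <- function(s, V, th, spec) {
  p <- nrow(spec$lambda_free)
  idx <- vech_index(p)
  e <- s - .sem_sigma(th, spec)
  J <- .sem_jacobian(th, spec)
  chisq_resid <- function(e, J) {
    Vs <- smooth_to_psd(V, eps = 1e-12 * max(diag(V)))
    Vi <- solve(Vs)
    A <- crossprod(J, Vi %*% J)
    # pseudoinverse only as a fallback for rank-deficient Jacobians
    # (e.g. zero loadings at a degenerate optimum)
    Ai <- tryCatch(solve(A), error = function(err) {
      ev <- eigen(A, symmetric = TRUE)
      pos <- ev$values > 1e-12 * max(ev$values, 0)
      ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    })
    U <- Vi - Vi %*% J %*% Ai %*% t(J) %*% Vi
    max(drop(t(e) %*% U %*% e), 0)
  }
  df <- spec$df
  chisq <- if (df == 0) 0 else chisq_resid(e, J)
  # independence model: free diagonal only (fits the diagonal exactly)
  J_ind <- vapply(seq_len(p), function(a) as.numeric(idx$row == a & idx$col == a),
                  numeric(length(s)))
  e_ind <- s
  e_ind[idx$row == idx$col] <- 0
  df_ind <- length(s) - p
  chisq_ind <- if (df_ind == 0) 0 else chisq_resid(e_ind, J_ind)
  denom <- chisq_ind - df_ind
  cfi <- if (denom <= 0) 1 else 1 - max(chisq - df, 0) / denom
  cfi <- min(max(cfi, 0), 1)
  sdiag <- s[idx$row == idx$col]
  e_std <- e / sqrt(sdiag[idx$row] * sdiag[idx$col])
  srmr <- sqrt(mean(e_std^2))
  list(chisq = chisq, df = df, p_chisq = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
       CFI = cfi, SRMR = srmr, AIC = chisq + 2 * spec$q,
       chisq_independence = chisq_ind, df_independence = df_ind)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit: %d indicators, %d severity factor(s); chisq(%d) = %.3f, CFI = %.3f, SRMR = %.4f, AIC = %.3f%s>\n",
              nrow(x$spec$lambda_free), x$spec$n_factors, x$df, x$chisq,
              x$CFI, x$SRMR, x$AIC,
              if (x$heywood) "; HEYWOOD" else ""))
  invisible(x)
}

#' Fit indices of a converged severity-factor model
#'
#' Residual-based model chi-square using the full sampling covariance
#' `V` (not just its diagonal), CFI against the diagonal-only
#' independence model, SRMR over the distinct standardized residuals, and
#' `AIC = chisq + 2q`.
#'
#' @param fit a [sem_fit_dwls()] result.
#' @return named list `chisq`, `df`, `p_chisq`, `CFI`, `SRMR`, `AIC`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  fit[c("chisq", "df", "p_chisq", "CFI", "SRMR", "AIC")]
}

#' Serialize a SEM fit to JSON
#'
#' @param fit a `sem_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sem_fit <- function(fit, path) {
  out <- list(indicators = fit$spec$indicators,
              factor_names = fit$spec$factor_names,
              n_factors = fit$spec$n_factors,
              estimates = fit$estimates, F_min = fit$F_min,
              converged = fit$converged, heywood = fit$heywood,
              chisq = fit$chisq, df = fit$df, p_chisq = fit$p_chisq,
              CFI = fit$CFI, SRMR = fit$SRMR, AIC = fit$AIC)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
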