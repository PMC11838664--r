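# Per-variant association scans producing summary statistics for LDSC.

#' Ordinary least squares association scan
#'
#' Regresses the phenotype on each variant's dosage (plus optional
#' covariates, residualized out of both sides), one variant at a time, via
#' vectorized sufficient statistics. Binary phenotypes are analysed on the
#' observed scale with a linear model — the standard input scale for LD
#' score regression, with liability conversion applied downstream.
#' Individuals with missing phenotype are dropped; the per-variant N
#' reflects the analysed sample. Monomorphic variants are skipped with a
#' warning. |Z| is capped at 1e6 (perfect association yields SE 0).
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param phenotype numeric vector, length = panel individuals; 0/1 coding
#'   for binary traits; `NA` allowed.
#' @param covariates optional full-rank numeric matrix of covariates
#'   (intercept added internally).
#' @param trait_id label carried into the output.
#' @param subset optional index vector restricting the analysed
#'   individuals (e.g. an ascertained case-control subset).
#' @param pop_prev population prevalence recorded in metadata for binary
#'   traits (defaults to the sample prevalence, appropriate for an
#'   unascertained population sample).
#' @return a [sumstats] object; binary traits carry their realized sample
#'   prevalence in metadata.
#' @export
assoc_scan <- function(panel, phenotype, covariates = NULL,
                       trait_id = "trait", subset = NULL, pop_prev = NULL) {
  res <- assoc_scan_multi(panel, matrix(phenotype, ncol = 1,
                                        dimnames = list(NULL, trait_id)),
                          covariates = covariates, subset = subset,
                          pop_prev = pop_prev)
  res[[1]]
}

#' Association scans of several phenotypes sharing one analysed sample
#'
#' Same model as [assoc_scan()], but the per-variant sufficient statistics
#' of the dosage matrix are computed once and the phenotype cross-products
#' in a single BLAS call — the efficient path for a family of binarized
#' phenotypes on one cohort.
#'
#' @inheritParams assoc_scan
#' @param phenotypes numeric matrix, one column per trait (column names
#'   become trait ids). Missingness must be column-wise identical (rows
#'   with any `NA` are dropped for all traits).
#' @return named list of [sumstats] objects.
#' @export
assoc_scan_multi <- function(panel, phenotypes, covariates = NULL,
                             subset = NULL, pop_prev = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  n_all <- nrow(panel$dosage)
  phenotypes <- as.matrix(phenotypes)
  stopifnot(nrow(phenotypes) == n_all)
  if (is.null(colnames(phenotypes)))
    colnames(phenotypes) <- paste0("trait", seq_len(ncol(phenotypes)))
  keep <- if (is.null(subset)) seq_len(n_all) else subset
  keep <- keep[rowSums(is.na(phenotypes[keep, , drop = FALSE])) == 0]
  Y <- phenotypes[keep, , drop = FALSE]
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  if (n < 3) stop("fewer than 3 non-missing individuals")
  if (any(apply(Y, 2, var) == 0)) stop("constant phenotype")
  full <- length(keep) == n_all && all(keep == seq_len(n_all))
  G <- if (full) panel$dosage else panel$dosage[keep, , drop = FALSE]
  if (!is.double(G)) storage.mode(G) <- "double"
  p_cov <- 0
  if (!is.null(covariates)) {
    Cm <- cbind(1, as.matrix(covariates)[keep, , drop = FALSE])
    qrC <- qr(Cm)
    if (qrC$rank < ncol(Cm)) stop("covariates are rank deficient")
    Y <- qr.resid(qrC, Y)
    G <- qr.resid(qrC, G)
    p_cov <- ncol(Cm) - 1
  }
  gs <- colSums(G)
  sxx <- colSums(G^2) - gs^2 / n
  mono <- sxx <= 0
  if (any(mono))
    warning(sprintf("%d monomorphic variants skipped", sum(mono)), call. = FALSE)
  frq <- gs / (2 * n)
  ys <- colSums(Y)
  syy <- colSums(Y^2) - ys^2 / n
  SXY <- crossprod(G, Y) - gs %o% (ys / n)
  df <- n - 2 - p_cov
  ok <- !mono
  out <- lapply(seq_len(ncol(Y)), function(t) {
    beta <- SXY[, t] / sxx
    sigma2 <- pmax(syy[t] - beta * SXY[, t], 0) / df
    se <- sqrt(sigma2 / sxx)
    z <- ifelse(se > 0, beta / se, sign(beta) * 1e6)
    z <- pmin(pmax(z, -1e6), 1e6)
    d <- data.frame(SNP = panel$snp$SNP[ok], CHR = panel$snp$CHR[ok],
                    BP = panel$snp$BP[ok], A1 = panel$snp$A1[ok],
                    A2 = panel$snp$A2[ok], FRQ = frq[ok], N = n,
                    Z = z[ok], P = 2 * pnorm(-abs(z[ok])))
    pheno <- phenotypes[keep, t]
    binary <- all(pheno %in% c(0, 1))
    sp <- if (binary) mean(pheno) else NA_real_
    sumstats(d, trait_id = colnames(Y)[t], binary = binary, sample_prev = sp,
             pop_prev = if (binary) (pop_prev %||% sp) else NA_real_)
  })
  names(out) <- colnames(Y)
  out
}
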