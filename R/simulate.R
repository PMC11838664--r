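# Simulation of genotype panels, item-level cohorts with a planted
# severity-gradient genetic architecture, ascertained disorder traits, and
# direct draws of GWAS summary statistics under the LD score regression
# model. Full ground truth is recorded so every downstream estimator can be
# tested by round-trip recovery.

#' Simulate a genotype panel with block-wise LD
#'
#' Two haplotypes per individual are generated by a first-order Markov
#' chain within each contiguous LD block: adjacent variants share a latent
#' uniform with probability `r`, so adjacent-variant allele correlation is
#' `r` when their allele frequencies are equal (slightly less otherwise).
#' Haplotypes are summed to 0/1/2 dosages. Variants in distinct blocks are
#' independent by construction.
#'
#' @param n_ind individuals.
#' @param n_var variants.
#' @param n_blocks number of contiguous LD blocks (equal sized up to
#'   rounding).
#' @param r within-block adjacent-variant allele correlation, in [0, 1).
#' @param maf_range range the allele frequency is drawn from, a subset of
#'   (0, 0.5]; a single value fixes the frequency. One frequency is drawn
#'   per LD block (equal within a block, so the planted adjacent-variant
#'   correlation is exactly `r`; the Pearson correlation of two Bernoulli
#'   variables with unequal frequencies cannot reach `r` in general).
#' @param seed integer seed; same seed gives a bit-identical panel.
#' @return object of class `geno_panel`: list with `dosage`
#'   (n_ind x n_var integer matrix), `snp` (data.frame SNP/CHR/BP/A1/A2),
#'   `maf` (target frequencies), `block` (block id per variant), `r`.
#' @export
simulate_genotypes <- function(n_ind, n_var, n_blocks = 1, r = 0,
                               maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(n_ind >= 1, n_var >= 1, n_blocks >= 1, n_blocks <= n_var)
  if (r < 0 || r >= 1) stop("r must lie in [0, 1)")
  if (length(maf_range) == 1) maf_range <- rep(maf_range, 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf_range must be within (0, 0.5]")
  with_seed(seed, {
    block <- sort(rep_len(seq_len(n_blocks), n_var))
    maf <- runif(n_blocks, maf_range[1], maf_range[2])[block]
    dosage <- matrix(0, n_ind, n_var)
    for (b in seq_len(n_blocks)) {
      vars <- which(block == b)
      u1 <- runif(n_ind); u2 <- runif(n_ind)
      for (jj in seq_along(vars)) {
        j <- vars[jj]
        if (jj > 1 && r > 0) {
          refresh1 <- runif(n_ind) >= r
          refresh2 <- runif(n_ind) >= r
          u1[refresh1] <- runif(sum(refresh1))
          u2[refresh2] <- runif(sum(refresh2))
        } else if (jj > 1) {
          u1 <- runif(n_ind); u2 <- runif(n_ind)
        }
        dosage[, j] <- (u1 < maf[j]) + (u2 < maf[j])
      }
    }
    # stored as double: every downstream consumer (GWAS cross-products,
    # LD scores, effect construction) needs double arithmetic, and the
    # repeated integer->double coercions dominate runtime at scale
    snp <- data.frame(SNP = sprintf("rs%06d", seq_len(n_var)),
                      CHR = 1L, BP = seq_len(n_var) * 1000L,
                      A1 = "A", A2 = "G", stringsAsFactors = FALSE)
    structure(list(dosage = dosage, snp = snp, maf = maf, block = block, r = r),
              class = "geno_panel")
  })
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel: %d individuals x %d variants, %d LD blocks, r = %.2f>\n",
              nrow(x$dosage), ncol(x$dosage), max(x$block), x$r))
  invisible(x)
}

#' Ground-truth record for the two-factor severity-gradient architecture
#'
#' Encodes the generative hypothesis being planted: two unit-variance
#' severity factors `F_low`, `F_high`, genetically correlated `rg_fact`,
#' with low-severity items loading mostly on `F_low` and high-severity
#' items mostly on `F_high`. `rg_fact = 1` collapses to the single
#' liability-threshold model.
#'
#' @param h2 heritability of each factor (variance fraction in [0, 1]).
#' @param rg_fact genetic correlation between the two factors, in [-1, 1].
#' @param n_items number of dichotomous items.
#' @param w per-item mixing weight in [0, 1] (weight on `F_high`);
#'   default linear in severity rank, `(j-1)/(n_items-1)`.
#' @param tau per-item endorsement threshold in latent-normal units;
#'   default spans endorsement rates from 0.65 down to 0.08, strictly
#'   increasing in severity rank.
#' @param item_communality squared item loading on the factor mixture
#'   (rest is i.i.d. unique noise), default 0.8.
#' @param common_env loading of an optional shared environmental factor on
#'   every item (adds phenotypic but not genetic covariance), default 0.
#' @param b_low,b_high disorder liability loadings on `F_low` / `F_high`.
#' @param K disorder population prevalence.
#' @param P_target ascertained sample prevalence (NULL = no ascertainment).
#' @param causal_fraction fraction of variants with nonzero effects.
#' @param seed integer seed recorded for reproducibility.
#' @return list of class `truth_record`.
#' @export
truth_record <- function(h2 = 0.5, rg_fact = 0.6, n_items = 12,
                         w = NULL, tau = NULL, item_communality = 0.8,
                         common_env = 0, b_low = 0, b_high = 0.8,
                         K = 0.15, P_target = NULL, causal_fraction = 1,
                         seed = NULL) {
  stopifnot(h2 >= 0, h2 <= 1, rg_fact >= -1, rg_fact <= 1, n_items >= 2,
            item_communality >= 0, item_communality + common_env^2 <= 1,
            causal_fraction > 0, causal_fraction <= 1)
  if (is.null(w)) w <- (seq_len(n_items) - 1) / (n_items - 1)
  if (is.null(tau)) tau <- qnorm(1 - seq(0.65, 0.08, length.out = n_items))
  stopifnot(length(w) == n_items, all(w >= 0 & w <= 1),
            length(tau) == n_items, all(diff(tau) > 0))
  if (b_low^2 + b_high^2 + 2 * b_low * b_high * rg_fact > 1)
    stop("disorder loadings imply liability variance > 1")
  stopifnot(K > 0, K < 1)
  if (!is.null(P_target)) stopifnot(P_target > 0, P_target < 1)
  structure(list(h2 = h2, rg_fact = rg_fact, n_items = n_items, w = w,
                 tau = tau, item_communality = item_communality,
                 common_env = common_env, b_low = b_low, b_high = b_high,
                 K = K, P_target = P_target,
                 causal_fraction = causal_fraction, seed = seed),
            class = "truth_record")
}

#' Simulate item-level phenotypes with a severity-gradient architecture
#'
#' Per-variant effect vectors for the two factors are drawn jointly with
#' correlation `rg_fact`; environmental factor components share the same
#' correlation, so the factor scores themselves correlate `rg_fact`. Item
#' `j`'s liability is `sqrt(c) * [(1-w_j) F_low + w_j F_high] / s_j +
#' sqrt(1-c-ce^2) * e_j + ce * C`, with `s_j` normalizing the mixture to
#' unit variance; the item is endorsed iff liability exceeds `tau_j`.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param truth a [truth_record()].
#' @param seed integer seed.
#' @return object of class `cohort`: list with `panel`, `F` (n x 2 factor
#'   scores), `items` (n x k 0/1), `score` (sum score), `disorder` (NULL
#'   until [simulate_disorder()]), `truth`.
#' @export
simulate_item_phenotypes <- function(panel, truth, seed = NULL) {
  stopifnot(inherits(panel, "geno_panel"), inherits(truth, "truth_record"))
  n <- nrow(panel$dosage); m <- ncol(panel$dosage)
  k <- truth$n_items
  with_seed(seed %||% truth$seed, {
    m_c <- max(1L, round(truth$causal_fraction * m))
    causal <- sort(sample.int(m, m_c))
    X <- panel$dosage
    mu <- colMeans(X)[causal]
    sdv <- sqrt(pmax(colMeans(X^2)[causal] - mu^2, 0) * n / (n - 1))
    rg <- truth$rg_fact
    E <- matrix(rnorm(m_c * 2), m_c, 2)
    b1 <- E[, 1]
    b2 <- rg * E[, 1] + sqrt(1 - rg^2) * E[, 2]
    sc <- sqrt(truth$h2 / m_c)
    B <- cbind(b1 * sc, b2 * sc)
    B[sdv == 0, ] <- 0  # monomorphic variants carry no effect
    Bs <- B / ifelse(sdv == 0, 1, sdv)
    # standardized-dosage effects without materializing a scaled copy
    Xc <- if (m_c == m) X else X[, causal, drop = FALSE]
    G <- Xc %*% Bs
    G <- sweep(G, 2, drop(mu %*% Bs))
    # realized-moment standardization: LD makes the sample variance and
    # correlation of X beta wobble across effect draws (by ~sqrt(2 h2^2
    # lbar / m)), so the genetic parts are rescaled to hit the planted
    # factor covariance h2 * [[1, rg], [rg, 1]] exactly; the environmental
    # parts are orthogonalized against them and scaled likewise
    exact_cov <- function(M, target) {
      M <- sweep(M, 2, colMeans(M))
      M %*% solve(chol(crossprod(M) / (nrow(M) - 1))) %*% chol(target)
    }
    Tmat <- matrix(c(1, rg, rg, 1), 2)
    if (abs(rg) == 1) {
      g1 <- G[, 1, drop = FALSE]
      g1 <- exact_cov(g1, matrix(1)) * sqrt(truth$h2)
      G <- cbind(g1, rg * g1)
      Ee <- matrix(rnorm(n), n, 1)
      Ee <- Ee - g1 %*% solve(crossprod(g1), crossprod(g1, Ee))
      Ee <- exact_cov(Ee, matrix(1)) * sqrt(1 - truth$h2)
      Ew <- cbind(Ee, rg * Ee)
    } else {
      if (truth$h2 > 0) G <- exact_cov(G, truth$h2 * Tmat)
      Ee <- matrix(rnorm(n * 2), n, 2)
      if (truth$h2 > 0)
        Ee <- Ee - G %*% solve(crossprod(G), crossprod(G, Ee))
      Ew <- exact_cov(Ee, (1 - truth$h2) * Tmat)
    }
    Fs <- G + Ew
    colnames(Fs) <- c("F_low", "F_high")
    cc <- truth$item_communality
    ce <- truth$common_env
    Cenv <- if (ce > 0) rnorm(n) else 0
    items <- matrix(0L, n, k,
                    dimnames = list(NULL, paste0("item", seq_len(k))))
    for (j in seq_len(k)) {
      w <- truth$w[j]
      s_j <- sqrt((1 - w)^2 + w^2 + 2 * w * (1 - w) * rg)
      if (s_j == 0) stop("mixture normalizer is zero (w, rg degenerate)")
      liab <- sqrt(cc) * ((1 - w) * Fs[, 1] + w * Fs[, 2]) / s_j +
        ce * Cenv + sqrt(1 - cc - ce^2) * rnorm(n)
      items[, j] <- as.integer(liab > truth$tau[j])
    }
    structure(list(panel = panel, F = Fs, items = items,
                   score = rowSums(items), disorder = NULL,
                   disorder_index = NULL, truth = truth),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d individuals, %d items, rg_fact = %.2f%s>\n",
              nrow(x$items), ncol(x$items), x$truth$rg_fact,
              if (!is.null(x$disorder))
                sprintf(", disorder prevalence %.3f", mean(x$disorder)) else ""))
  invisible(x)
}

#' Add an ascertained case-control disorder trait to a cohort
#'
#' Disorder liability is `b_low F_low + b_high F_high + unique`, scaled to
#' unit variance; case status is liability above the `1-K` normal quantile.
#' If `P_target` is given, the majority class is subsampled (without
#' replacement) to that sample prevalence, mimicking clinical
#' ascertainment; `disorder_index` records the retained individuals.
#'
#' @param cohort a [simulate_item_phenotypes()] cohort.
#' @param b_low,b_high,K,P_target override the cohort's truth record.
#' @param seed integer seed.
#' @return the cohort with `disorder` (0/1 for all individuals),
#'   `disorder_index` (ascertained subset, or all individuals), and
#'   realized prevalences recorded in `truth$K_realized`,
#'   `truth$P_realized`.
#' @export
simulate_disorder <- function(cohort, b_low = NULL, b_high = NULL, K = NULL,
                              P_target = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  tr <- cohort$truth
  b_low <- b_low %||% tr$b_low
  b_high <- b_high %||% tr$b_high
  K <- K %||% tr$K
  P_target <- P_target %||% tr$P_target
  rg <- tr$rg_fact
  v_shared <- b_low^2 + b_high^2 + 2 * b_low * b_high * rg
  if (v_shared > 1) stop("disorder loadings imply liability variance > 1")
  with_seed(seed, {
    n <- nrow(cohort$F)
    liab <- b_low * cohort$F[, 1] + b_high * cohort$F[, 2] +
      sqrt(1 - v_shared) * rnorm(n)
    status <- as.integer(liab > qnorm(1 - K))
    cohort$disorder <- status
    cohort$truth$K_realized <- mean(status)
    if (is.null(P_target)) {
      cohort$disorder_index <- seq_len(n)
      cohort$truth$P_realized <- mean(status)
    } else {
      idx <- downsample_balanced(status, target_prev = P_target,
                                 n_eff_floor = 0)
      cohort$disorder_index <- idx
      cohort$truth$P_realized <- mean(status[idx])
    }
    cohort
  })
}

#' Draw GWAS summary statistics directly from the LDSC model
#'
#' Inverts LD score regression as a generator: per variant `j`, the vector
#' of Z statistics across traits is multivariate normal with
#' `var(z_tj) = N_t h2_t l_j / M + a_t` and
#' `cov(z_tj, z_uj) = sqrt(N_t N_u) rg_tu sqrt(h2_t h2_u) l_j / M +
#' pheno_corr * N_s / sqrt(N_t N_u)`. Draws are independent across
#' variants — a deliberate simplification (no LD-induced Z correlation), so
#' jackknife SEs in this mode are slightly optimistic; the individual-level
#' path carries real LD.
#'
#' @param ld_scores an [ld_score_table()] (or numeric vector of LD scores).
#' @param M number of variants in the regression denominator (defaults to
#'   the table's M).
#' @param traits list of per-trait lists with elements `h2`, `N`, and
#'   optionally `a` (univariate intercept, default 1), `P`, `K`,
#'   `trait_id`, `binary`.
#' @param rg_matrix genetic correlation matrix across traits (unit
#'   diagonal, PSD).
#' @param overlap optional list `(N_s, pheno_corr)`: shared sample count
#'   and phenotypic correlation in the shared sample (scalar or matrix).
#' @param seed integer seed.
#' @return list of [sumstats] objects, one per trait.
#' @export
simulate_sumstats_direct <- function(ld_scores, M = NULL, traits, rg_matrix = NULL,
                                     overlap = NULL, seed = NULL) {
  if (inherits(ld_scores, "ld_score_table")) {
    l2 <- ld_scores$l2
    snp <- ld_scores$snp
    M <- M %||% ld_scores$M
  } else {
    l2 <- as.numeric(ld_scores)
    snp <- sprintf("rs%06d", seq_along(l2))
  }
  if (any(l2 <= 0)) stop("LD scores must be positive")
  M <- M %||% length(l2)
  k <- length(traits)
  if (is.null(rg_matrix)) rg_matrix <- diag(k)
  stopifnot(nrow(rg_matrix) == k, all(abs(diag(rg_matrix) - 1) < 1e-12),
            max(abs(rg_matrix - t(rg_matrix))) < 1e-12)
  h2 <- vapply(traits, function(t) t$h2, 0)
  N <- vapply(traits, function(t) t$N, 0)
  a <- vapply(traits, function(t) t$a %||% 1, 0)
  stopifnot(all(h2 >= 0 & h2 <= 1), all(N > 0))
  # per-variant covariance: l_j * A + C
  A <- (sqrt(N * h2) %o% sqrt(N * h2)) * rg_matrix / M
  C <- diag(a, k)
  if (!is.null(overlap) && k > 1) {
    Ns <- overlap$N_s
    pc <- overlap$pheno_corr
    if (length(pc) == 1) pc <- matrix(pc, k, k)
    cross <- pc * Ns / (sqrt(N) %o% sqrt(N))
    C[upper.tri(C)] <- cross[upper.tri(cross)]
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
  }
  la <- tryCatch(chol(A + diag(1e-12, k)), error = function(e)
    stop("per-variant covariance component (genetic) is not PSD"))
  lc <- tryCatch(chol(C + diag(1e-12, k)), error = function(e)
    stop("per-variant covariance component (intercept) is not PSD"))
  mv <- length(l2)
  with_seed(seed, {
    Z <- (matrix(rnorm(mv * k), mv, k) %*% la) * sqrt(l2) +
      matrix(rnorm(mv * k), mv, k) %*% lc
    frq <- runif(mv, 0.05, 0.5)
    lapply(seq_len(k), function(t) {
      df <- data.frame(SNP = snp, CHR = 1L, BP = seq_len(mv) * 1000L,
                       A1 = "A", A2 = "G", FRQ = frq, N = N[t], Z = Z[, t],
                       P = 2 * pnorm(-abs(Z[, t])))
      sumstats(df,
               trait_id = traits[[t]]$trait_id %||% paste0("trait", t),
               binary = isTRUE(traits[[t]]$binary),
               sample_prev = traits[[t]]$P %||% NA_real_,
               pop_prev = traits[[t]]$K %||% NA_real_)
    })
  })
}

#' Write a cohort to plain-text files
#'
#' Dosages as a dense integer table, phenotypes as a tab-separated table
#' (IID, items, sum score, disorder), ground truth as a JSON sidecar.
#'
#' @param cohort a cohort.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(cohort$panel$dosage),
                     file.path(dir, "dosage.tsv"), sep = "\t")
  utils::write.table(cohort$panel$snp, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(IID = seq_len(nrow(cohort$items)), cohort$items,
                   sumscore = cohort$score)
  if (!is.null(cohort$disorder)) ph$disorder <- cohort$disorder
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  tr$P_target <- tr$P_target %||% NA
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
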