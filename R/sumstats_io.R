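# GWAS summary-statistic container, text IO, and cross-trait allele
# harmonization.

SS_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "N", "Z", "P")

#' Construct a summary-statistics object
#'
#' The container used throughout the package: one row per variant with
#' effect-allele Z statistics, plus trait-level metadata (binary flag,
#' sample and population prevalence, effective N) needed for liability
#' conversion downstream. Rows violating the invariants (duplicate or
#' missing ids, non-ACGT alleles, frequency outside (0,1), non-positive N,
#' non-finite Z) are dropped with a message.
#'
#' @param data data.frame with columns SNP, CHR, BP, A1, A2, FRQ, N, Z, P
#'   (P recomputed from Z if absent).
#' @param trait_id character label.
#' @param binary logical; is the trait a 0/1 phenotype?
#' @param sample_prev,pop_prev case shares in the analysed sample and the
#'   population (binary traits only; `NA` otherwise).
#' @param n_eff sum of effective sample sizes; computed as
#'   `4 v (1-v) max(N)` for binary traits when not supplied.
#' @return object of class `sumstats`: list with `data` and `meta`.
#' @export
sumstats <- function(data, trait_id = "trait", binary = FALSE,
                     sample_prev = NA_real_, pop_prev = NA_real_,
                     n_eff = NA_real_) {
  data <- as.data.frame(data)
  if (is.null(data$P) && !is.null(data$Z)) data$P <- 2 * pnorm(-abs(data$Z))
  miss <- setdiff(SS_COLS, names(data))
  if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  data <- data[SS_COLS]
  n0 <- nrow(data)
  ok <- !is.na(data$SNP) & !duplicated(data$SNP) &
    data$A1 %in% c("A", "C", "G", "T") & data$A2 %in% c("A", "C", "G", "T") &
    is.finite(data$FRQ) & data$FRQ > 0 & data$FRQ < 1 &
    is.finite(data$N) & data$N > 0 & is.finite(data$Z)
  dropped <- n0 - sum(ok)
  if (dropped > 0)
    message(sprintf("sumstats '%s': dropped %d of %d invalid rows",
                    trait_id, dropped, n0))
  if (n0 > 0 && !any(ok)) stop("all rows invalid")
  data <- data[ok, , drop = FALSE]
  rownames(data) <- NULL
  data$Z <- data$Z + 0  # canonicalize -0
  if (binary && (is.na(sample_prev) || sample_prev <= 0 || sample_prev >= 1))
    stop("binary trait requires sample_prev in (0, 1)")
  if (binary && is.na(n_eff) && nrow(data))
    n_eff <- effective_n(sample_prev, max(data$N))
  structure(list(data = data,
                 meta = list(trait_id = trait_id, binary = binary,
                             sample_prev = sample_prev, pop_prev = pop_prev,
                             n_eff = n_eff, n_dropped = dropped)),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats '%s': %d variants%s>\n", x$meta$trait_id,
              nrow(x$data),
              if (isTRUE(x$meta$binary))
                sprintf(", binary (P=%.3g, K=%.3g)", x$meta$sample_prev,
                        x$meta$pop_prev) else ""))
  invisible(x)
}

# header aliases recognised by read_sumstats
.ss_aliases <- list(
  SNP = c("SNP", "ID", "RSID", "MARKERNAME", "VARIANT_ID"),
  CHR = c("CHR", "CHROM", "CHROMOSOME"),
  BP = c("BP", "POS", "POSITION"),
  A1 = c("A1", "EFFECT_ALLELE", "ALT", "EA"),
  A2 = c("A2", "OTHER_ALLELE", "REF", "OA", "NEA"),
  FRQ = c("FRQ", "FREQ", "EAF", "MAF", "A1FREQ"),
  N = c("N", "NEFF", "N_TOTAL"),
  Z = c("Z", "ZSCORE", "Z_STAT"),
  P = c("P", "PVAL", "PVALUE", "P_VALUE"),
  BETA = c("BETA", "B", "EFFECT", "LOG_ODDS"),
  SE = c("SE", "STDERR", "STD_ERR"))

#' Read summary statistics from a whitespace-delimited text file
#'
#' Header names are matched case-insensitively against common aliases
#' (overridable via `column_map`); `Z` is reconstructed as `BETA/SE` when
#' absent. Trait metadata is taken from a JSON sidecar `<path>.meta.json`
#' when present, overridden by the `meta` argument.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical names
#'   (SNP, CHR, BP, A1, A2, FRQ, N, Z, P, BETA, SE) to file header names.
#' @param meta optional named list overriding sidecar metadata
#'   (trait_id, binary, sample_prev, pop_prev, n_eff).
#' @return a [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = NULL, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(d) == 0 && ncol(d) == 0) stop("empty file: ", path)
  hdr <- toupper(names(d))
  pick <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      j <- match(toupper(column_map[[canon]]), hdr)
    } else {
      j <- match(.ss_aliases[[canon]], hdr)
      j <- j[!is.na(j)][1]
    }
    if (length(j) == 0 || is.na(j)) NULL else d[[j]]
  }
  out <- list()
  for (canon in c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "N", "Z", "P"))
    out[[canon]] <- pick(canon)
  if (is.null(out$Z)) {
    beta <- pick("BETA"); se <- pick("SE")
    if (is.null(beta) || is.null(se))
      stop("no Z column and no BETA/SE pair to reconstruct it from")
    out$Z <- beta / se
  }
  mandatory <- c("SNP", "A1", "A2", "FRQ", "N", "Z")
  miss <- mandatory[vapply(out[mandatory], is.null, logical(1))]
  if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  n <- length(out$SNP)
  out$CHR <- out$CHR %||% rep(NA_integer_, n)
  out$BP <- out$BP %||% rep(NA_integer_, n)
  out$P <- out$P %||% (2 * pnorm(-abs(out$Z)))
  df <- as.data.frame(out)[SS_COLS]
  df$A1 <- toupper(df$A1); df$A2 <- toupper(df$A2)
  sidecar <- paste0(path, ".meta.json")
  m <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  m[names(meta)] <- meta
  sumstats(df,
           trait_id = m$trait_id %||% sub("\\.[^.]*$", "", basename(path)),
           binary = isTRUE(m$binary),
           sample_prev = m$sample_prev %||% NA_real_,
           pop_prev = m$pop_prev %||% NA_real_,
           n_eff = m$n_eff %||% NA_real_)
}

#' Write summary statistics to a tab-separated file with JSON sidecar
#'
#' Fixed column order `SNP CHR BP A1 A2 FRQ N Z P`; metadata goes to
#' `<path>.meta.json`. `read_sumstats(write_sumstats(s, p))` reproduces `s`.
#'
#' @param s a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "sumstats"))
  d <- s$data
  d$Z <- d$Z + 0
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- s$meta[c("trait_id", "binary", "sample_prev", "pop_prev", "n_eff")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Restrict traits to shared variants and harmonize effect alleles
#'
#' Variant ids are intersected across traits (kept in the first trait's
#' order). For each other trait, a variant whose (A1, A2) is swapped
#' relative to the first trait has its Z negated and frequency reflected;
#' variants with incompatible allele pairs are dropped everywhere.
#' Strand-ambiguous pairs (A/T, C/G) are dropped when `drop_ambiguous`.
#'
#' @param ss_list list of two or more [sumstats] objects.
#' @param drop_ambiguous drop A/T and C/G variants (default FALSE; the
#'   simulator never produces real strand flips).
#' @return list of aligned sumstats, with attribute `drop_counts`
#'   (named: shared, incompatible, ambiguous).
#' @export
align_traits <- function(ss_list, drop_ambiguous = FALSE) {
  stopifnot(length(ss_list) >= 2, all(vapply(ss_list, inherits, TRUE, "sumstats")))
  ids <- Reduce(intersect, lapply(ss_list, function(s) s$data$SNP))
  if (!length(ids)) stop("no shared variants across traits")
  ids <- ss_list[[1]]$data$SNP[ss_list[[1]]$data$SNP %in% ids]
  mats <- lapply(ss_list, function(s) s$data[match(ids, s$data$SNP), , drop = FALSE])
  ref <- mats[[1]]
  incompatible <- rep(FALSE, length(ids))
  for (t in seq_along(mats)[-1]) {
    m <- mats[[t]]
    same <- m$A1 == ref$A1 & m$A2 == ref$A2
    swap <- m$A1 == ref$A2 & m$A2 == ref$A1
    incompatible <- incompatible | !(same | swap)
    m$Z[swap] <- -m$Z[swap]
    m$FRQ[swap] <- 1 - m$FRQ[swap]
    m$A1[swap] <- ref$A1[swap]
    m$A2[swap] <- ref$A2[swap]
    mats[[t]] <- m
  }
  ambiguous <- rep(FALSE, length(ids))
  if (drop_ambiguous) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    ambiguous <- comp[ref$A1] == ref$A2
  }
  keep <- !incompatible & !ambiguous
  if (!any(keep)) stop("no variants survive allele harmonization")
  out <- Map(function(s, m) {
    s$data <- m[keep, , drop = FALSE]
    rownames(s$data) <- NULL
    s
  }, ss_list, mats)
  attr(out, "drop_counts") <- c(shared = length(ids),
                                incompatible = sum(incompatible),
                                ambiguous = sum(ambiguous & !incompatible))
  out
}
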