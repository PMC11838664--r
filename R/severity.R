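# Severity construction: binarized phenotype families, latent-normal severity
# scores, prevalence balancing and effective sample sizes.

#' Binarize a continuous score at multiple severity cut points
#'
#' Scores at or above a cut are coded 1 ("case"), scores below the cut 0.
#' Each cut yields one binary phenotype; together they form a nested family
#' (the case set at a higher cut is a subset of the case set at any lower
#' cut). The realized below-cut prevalence of each cut, computed in the
#' non-missing sample, is mapped to the standard normal quantile scale to
#' give the cut's severity score.
#'
#' @param scores numeric vector; `NA` allowed and propagated.
#' @param cuts increasing numeric vector of cut points.
#' @return list with `bin`, an `n x length(cuts)` 0/1 matrix (`NA` where the
#'   score is missing), and `map`, a `severity_map` data.frame with columns
#'   `cut`, `n_case`, `n_control`, `prev_below`, `severity_z`.
#' @export
binarize_scores <- function(scores, cuts) {
  stopifnot(is.numeric(scores), is.numeric(cuts), length(cuts) >= 1)
  cuts <- sort(cuts)
  ok <- !is.na(scores)
  if (!any(ok)) stop("all scores are missing")
  bin <- vapply(cuts, function(cc) as.integer(scores >= cc), integer(length(scores)))
  bin <- matrix(bin, ncol = length(cuts),
                dimnames = list(NULL, paste0("cut", seq_along(cuts))))
  n_case <- colSums(bin[ok, , drop = FALSE])
  n_ctrl <- sum(ok) - n_case
  bad <- which(n_case == 0 | n_ctrl == 0)
  if (length(bad))
    stop(sprintf("cut %s leaves an empty %s class", cuts[bad[1]],
                 if (n_case[bad[1]] == 0) "case" else "control"))
  map <- severity_map(cuts, n_case, n_ctrl)
  list(bin = bin, map = map)
}

#' Construct a severity map from per-cut case/control counts
#'
#' @param cuts cut-point values (score units).
#' @param n_case,n_control integer counts per cut.
#' @return data.frame of class `severity_map`.
#' @export
severity_map <- function(cuts, n_case, n_control) {
  stopifnot(length(cuts) == length(n_case), length(cuts) == length(n_control),
            all(n_case > 0), all(n_control > 0))
  prev_below <- n_control / (n_case + n_control)
  map <- data.frame(cut = cuts, n_case = n_case, n_control = n_control,
                    prev_below = prev_below,
                    severity_z = severity_from_prevalence(prev_below))
  class(map) <- c("severity_map", "data.frame")
  map
}

#' Map below-cut prevalences to latent-normal severity scores
#'
#' The severity of a cut point is the standard-normal quantile of the share
#' of the sample falling below it: a cut that 97.5% of people fall below
#' sits 1.96 latent SD above the mean. Using prevalences rather than the raw
#' cut values makes severity robust to non-interval scaling of the score.
#'
#' @param prev_below vector of below-cut prevalences in (0, 1).
#' @return vector of severity z scores (strictly increasing whenever
#'   `prev_below` is).
#' @export
severity_from_prevalence <- function(prev_below) {
  if (any(!is.finite(prev_below)) || any(prev_below <= 0 | prev_below >= 1))
    stop("prevalences must lie strictly within (0, 1)")
  qnorm(prev_below)
}

#' Down-sample a binary phenotype to a target prevalence
#'
#' The minority class is kept intact; the majority class is randomly
#' subsampled (without replacement) until the target case share is reached.
#' Used to show that severity gradients in genetic correlation are not an
#' artifact of prevalence differences between cuts.
#'
#' @param y 0/1 vector (`NA` excluded).
#' @param target_prev target case share, default 0.5.
#' @param seed integer seed for the subsample; the global RNG is untouched.
#' @param n_eff_floor warn when the retained effective sample size
#'   `4 p (1-p) n` falls below this (default 15000): LD score regression on
#'   smaller samples is unstable.
#' @return sorted integer vector of retained indices.
#' @export
downsample_balanced <- function(y, target_prev = 0.5, seed = NULL,
                                n_eff_floor = 15000) {
  stopifnot(target_prev > 0, target_prev < 1)
  idx <- which(!is.na(y))
  cases <- idx[y[idx] == 1]
  ctrls <- idx[y[idx] == 0]
  if (!length(cases) || !length(ctrls)) stop("both classes must be non-empty")
  prev <- length(cases) / length(idx)
  if (prev == target_prev) {
    keep <- sort(idx)
  } else if (prev < target_prev) {
    n_keep <- round(length(cases) * (1 - target_prev) / target_prev)
    if (n_keep > length(ctrls)) stop("target prevalence unreachable by subsampling controls")
    keep <- sort(c(cases, with_seed(seed, sample(ctrls, n_keep))))
  } else {
    n_keep <- round(length(ctrls) * target_prev / (1 - target_prev))
    if (n_keep > length(cases)) stop("target prevalence unreachable by subsampling cases")
    keep <- sort(c(ctrls, with_seed(seed, sample(cases, n_keep))))
  }
  p <- mean(y[keep])
  n_eff <- effective_n(p, length(keep))
  if (n_eff < n_eff_floor)
    warning(sprintf("retained n_eff = %.0f < %.0f: too small for stable LDSC",
                    n_eff, n_eff_floor), call. = FALSE)
  keep
}

#' Effective sample size of a case-control design
#'
#' `n_eff = 4 v (1 - v) n`, the sample size of a balanced (50/50) design
#' with equivalent GWAS power, where `v` is the case share.
#'
#' @param v case share(s) in (0, 1).
#' @param n sample size(s).
#' @return effective sample size, vectorized over `v` and `n`.
#' @export
effective_n <- function(v, n) {
  if (any(v <= 0 | v >= 1)) stop("prevalence must lie strictly within (0, 1)")
  if (any(n <= 0)) stop("n must be positive")
  4 * v * (1 - v) * n
}

#' Sum of effective sample sizes over cohorts
#'
#' @param v vector of per-cohort case shares.
#' @param n vector of per-cohort sample sizes.
#' @return scalar sum of `4 v (1-v) n` over cohorts.
#' @export
effective_n_sum <- function(v, n) sum(effective_n(v, n))

#' Sum score with person-mean rescaling of modest missingness
#'
#' Dichotomous item responses are averaged within person over non-missing
#' items and multiplied by the item count, yielding a score on the 0..k
#' scale; individuals answering fewer than `min_items` items get `NA`.
#'
#' @param items n x k 0/1 matrix, `NA` allowed.
#' @param min_items minimum answered items required (default `k - 3`).
#' @return numeric score vector of length n.
#' @export
sum_score <- function(items, min_items = ncol(items) - 3) {
  k <- ncol(items)
  answered <- rowSums(!is.na(items))
  sc <- rowMeans(items, na.rm = TRUE) * k
  sc[answered < min_items] <- NA_real_
  sc[answered == 0] <- NA_real_
  sc
}

#' Write / read a severity map as a tab-separated table
#'
#' @param map severity_map.
#' @param path file path.
#' @return `path` (write) or a `severity_map` (read).
#' @export
write_severity_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_severity_map
#' @export
read_severity_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  severity_map(d$cut, d$n_case, d$n_control)
}
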