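# Generalized least squares modelling of genetic correlations as a
# function of severity, weighted by the block-jackknife sampling
# covariance of the selected elements.

#' Extract a GLS design from a genetic covariance structure
#'
#' Two selection modes:
#' * `"external"`: the outcomes are the genetic correlations between each
#'   cut-point trait and one named external trait; the design is
#'   intercept + severity z (+ optionally centered z squared).
#' * `"decay"`: the outcomes are the correlations of the first cut with
#'   cuts 2..k; the single predictor is the severity distance from cut 1.
#'
#' The weight matrix `V_y` is the corresponding submatrix of the joint
#' sampling covariance (`V_R` by default — the standardized-S /
#' delta-method matrix), so correlated estimation errors across outcomes
#' (inevitable when all cuts derive from one sample) propagate into the
#' coefficient covariance.
#'
#' @param struct a `genetic_cov_struct` with `R`/`V_R` available.
#' @param severity a `severity_map` or numeric vector of severity z scores
#'   for the cut-point traits, in trait order.
#' @param mode `"external"` or `"decay"`.
#' @param external trait id (or index) of the external trait
#'   (`"external"` mode).
#' @param cuts trait ids (or indices) of the cut-point traits; default all
#'   traits except `external`.
#' @param quadratic include a centered quadratic severity term.
#' @param use_R model elements of `R` (default) rather than `S`.
#' @return object of class `gls_design`: list with `y`, `X`, `V`,
#'   `labels`, `mode`, `severity`, `center` (the centering constant of the
#'   quadratic term, if any).
#' @export
build_gls_inputs <- function(struct, severity, mode = c("external", "decay"),
                             external = NULL, cuts = NULL, quadratic = FALSE,
                             use_R = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(struct, "genetic_cov_struct"))
  Mat <- if (use_R) struct[["R"]] else struct[["S"]]
  Vm <- if (use_R) struct[["V_R"]] else struct[["V_S"]]
  if (is.null(Mat) || is.null(Vm))
    stop(if (use_R) "struct carries no R/V_R" else "struct carries no S/V_S")
  k <- length(struct$traits)
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    m <- match(x, struct$traits)
    if (anyNA(m)) stop("trait(s) not in struct: ", paste(x[is.na(m)], collapse = ", "))
    m
  }
  z <- if (inherits(severity, "severity_map")) severity$severity_z else as.numeric(severity)
  if (mode == "external") {
    if (is.null(external)) stop("external mode needs an external trait")
    e <- resolve(external)
    cc <- if (is.null(cuts)) setdiff(seq_len(k), e) else resolve(cuts)
    if (length(z) != length(cc))
      stop("severity length must match the number of cut-point traits")
    pos <- vech_pos(cc, rep(e, length(cc)), k)
    y <- Mat[cbind(cc, e)]
    ctr <- if (quadratic) mean(z) else 0
    X <- if (quadratic) cbind(intercept = 1, severity = z - ctr,
                              severity2 = (z - ctr)^2)
    else cbind(intercept = 1, severity = z)
    labels <- paste0(struct$traits[cc], ":", struct$traits[e])
  } else {
    cc <- if (is.null(cuts)) seq_len(k) else resolve(cuts)
    if (length(z) != length(cc))
      stop("severity length must match the number of cut-point traits")
    o <- order(z)
    cc <- cc[o]; z <- z[o]
    first <- cc[1]; rest <- cc[-1]
    pos <- vech_pos(rest, rep(first, length(rest)), k)
    y <- Mat[cbind(rest, first)]
    X <- cbind(intercept = 1, distance = z[-1] - z[1])
    ctr <- 0
    labels <- paste0(struct$traits[rest], ":", struct$traits[first])
  }
  if (mode == "external" && length(y) < ncol(X))
    stop(sprintf("need >= %d elements for %d coefficients", ncol(X), ncol(X)))
  V <- Vm[pos, pos, drop = FALSE]
  structure(list(y = y, X = X, V = V, labels = labels, mode = mode,
                 severity = z, center = ctr),
            class = "gls_design")
}

#' Closed-form generalized least squares fit
#'
#' `beta = (X' V^-1 X)^-1 X' V^-1 y` with coefficient covariance
#' `(X' V^-1 X)^-1`; Wald `z = beta / SE` and two-sided normal p values.
#' `V` is smoothed to positive definite if needed; a condition number
#' above 1e10 triggers a warning.
#'
#' @param d a `gls_design` (or any list with `y`, `X`, `V`).
#' @return object of class `gls_fit`: list with `coefficients` (data.frame
#'   est/se/z/p per design column), `vcov`, `fitted`, `residuals`,
#'   `design`.
#' @export
gls_fit <- function(d) {
  y <- d$y; X <- as.matrix(d$X); V <- d$V
  stopifnot(length(y) == nrow(X), nrow(V) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)) - 1)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  V <- smooth_to_psd(V, eps = 1e-12 * max(diag(V)))
  check_condition(V, "GLS weight matrix V")
  ch <- chol(V)
  Xi <- backsolve(ch, X, transpose = TRUE)   # ch^-T X
  yi <- backsolve(ch, y, transpose = TRUE)
  XtVX <- crossprod(Xi)
  if (rcond(XtVX) < 1e-14) stop("X' V^-1 X is singular")
  cov_b <- solve(XtVX)
  beta <- drop(cov_b %*% crossprod(Xi, yi))
  se <- sqrt(diag(cov_b))
  zst <- beta / se
  coefs <- data.frame(term = colnames(X), est = beta, se = se, z = zst,
                      p = 2 * pnorm(-abs(zst)), row.names = NULL)
  fitted <- drop(X %*% beta)
  structure(list(coefficients = coefs, vcov = cov_b, fitted = fitted,
                 residuals = y - fitted, design = d),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Generalized least squares fit",
      if (!is.null(x$design$mode)) sprintf("(%s mode)", x$design$mode), "\n")
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Severity-trend test of genetic correlations with an external trait
#'
#' Regresses the genetic correlation between each severity cut and an
#' external trait on cut-point severity (latent-normal z), by GLS with the
#' joint sampling covariance as weight. A positive slope means genetic
#' sharing with the external trait increases with severity.
#'
#' @inheritParams build_gls_inputs
#' @return a [gls_fit()] result.
#' @export
severity_trend_test <- function(struct, severity, external, quadratic = FALSE,
                                cuts = NULL, use_R = TRUE) {
  gls_fit(build_gls_inputs(struct, severity, mode = "external",
                           external = external, cuts = cuts,
                           quadratic = quadratic, use_R = use_R))
}

#' Decay test of genetic correlations with severity distance
#'
#' Regresses the genetic correlations between the least severe cut and
#' every other cut on the severity distance separating them. A negative
#' slope (rg units per standardized-severity unit) indicates progressive
#' genetic differentiation across the spectrum; the single-liability model
#' predicts slope 0.
#'
#' @inheritParams build_gls_inputs
#' @return a [gls_fit()] result; with only two cuts the slope is exactly
#'   determined (df = 0) and a warning is issued.
#' @export
decay_test <- function(struct, severity, cuts = NULL, use_R = TRUE) {
  d <- build_gls_inputs(struct, severity, mode = "decay", cuts = cuts,
                        use_R = use_R)
  if (length(d$y) < ncol(d$X)) {
    # two cuts: a free intercept is not identified, so anchor it at the
    # exact rg of a cut with itself (1 at distance 0) and fit the slope
    warning("two cuts only: intercept fixed at 1, slope exactly determined (df = 0)",
            call. = FALSE)
    d$y <- d$y - 1
    d$X <- d$X[, "distance", drop = FALSE]
  } else if (length(d$y) == ncol(d$X)) {
    warning("as many elements as coefficients: fit exactly determined (df = 0)",
            call. = FALSE)
  }
  gls_fit(d)
}

#' Serialize a GLS fit to JSON
#'
#' @param fit a `gls_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gls_fit <- function(fit, path) {
  out <- list(mode = fit$design$mode, labels = fit$design$labels,
              severity = fit$design$severity, center = fit$design$center,
              coefficients = fit$coefficients, vcov = fit$vcov,
              fitted = fit$fitted, residuals = fit$residuals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
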