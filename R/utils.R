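#' @importFrom stats qnorm pnorm dnorm pchisq rnorm runif rbinom cor sd var
#'   complete.cases coef
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-vectorization index table
#'
#' Distinct elements of a symmetric k x k matrix in the package's canonical
#' order: row-major lower triangle, diagonal included, i.e.
#' (1,1), (2,1), (2,2), (3,1), (3,2), (3,3), ...
#' This is the coordinate system of every sampling covariance matrix `V`
#' produced by [multivariate_ldsc()].
#'
#' @param k matrix dimension.
#' @return data.frame with integer columns `row`, `col` (`row >= col`) and
#'   `k*(k+1)/2` rows.
#' @export
vech_index <- function(k) {
  stopifnot(k >= 1)
  row <- unlist(lapply(seq_len(k), function(i) rep(i, i)))
  col <- unlist(lapply(seq_len(k), function(i) seq_len(i)))
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Half-vectorize a symmetric matrix
#'
#' @param M symmetric matrix.
#' @return numeric vector in [vech_index()] order.
#' @export
vech <- function(M) {
  idx <- vech_index(nrow(M))
  M[cbind(idx$row, idx$col)]
}

#' Reconstruct a symmetric matrix from its half-vectorization
#'
#' @param v vector in [vech_index()] order.
#' @param k matrix dimension (inferred from length if omitted).
#' @return symmetric k x k matrix.
#' @export
unvech <- function(v, k = NULL) {
  if (is.null(k)) k <- as.integer((sqrt(8 * length(v) + 1) - 1) / 2)
  stopifnot(k * (k + 1) / 2 == length(v))
  M <- matrix(0, k, k)
  idx <- vech_index(k)
  M[cbind(idx$row, idx$col)] <- v
  M[cbind(idx$col, idx$row)] <- v
  M
}

# position of element (i, j) within the vech order
vech_pos <- function(i, j, k) {
  r <- pmax(i, j); c <- pmin(i, j)
  as.integer(r * (r - 1) / 2 + c)
}

#' Project a symmetric matrix to the positive semidefinite cone
#'
#' Eigenvalues below `eps` (default `1e-10 * max(eigenvalue)`) are clipped up
#' to `eps` and the matrix reconstructed. Needed before inverting sampling
#' covariance matrices in GLS/SEM weighting; a block-jackknife `V` can be
#' indefinite through sampling noise alone.
#'
#' @param V symmetric matrix.
#' @param eps absolute eigenvalue floor; default `1e-10` times the largest
#'   eigenvalue (0 if all eigenvalues are non-positive).
#' @return matrix with attribute `max_change`, the largest absolute
#'   elementwise change applied.
#' @export
smooth_to_psd <- function(V, eps = NULL) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (is.null(eps)) eps <- 1e-10 * max(max(e$values), 0)
  if (all(e$values >= eps)) {
    attr(V, "max_change") <- 0
    return(V)
  }
  lam <- pmax(e$values, eps)
  Vp <- e$vectors %*% (lam * t(e$vectors))
  Vp <- (Vp + t(Vp)) / 2
  attr(Vp, "max_change") <- max(abs(Vp - V))
  Vp
}

# Run expr with a private RNG stream; global .Random.seed untouched.
# seed = NULL draws from the current stream (and does perturb it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# condition-number guard used before solving GLS / SEM systems
check_condition <- function(M, label, threshold = 1e10) {
  kap <- tryCatch(kappa(M, exact = FALSE), error = function(e) Inf)
  if (is.finite(kap) && kap > threshold)
    warning(sprintf("%s is ill-conditioned (kappa ~ %.3g)", label, kap),
            call. = FALSE)
  invisible(kap)
}
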