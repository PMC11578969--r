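#' REML variance components for the polygenic null model
#'
#' Fits `y = X b + u + e` with `var(u) = G sigma2_g`, `var(e) = I sigma2_e`
#' by restricted maximum likelihood. The GRM is eigendecomposed once; the
#' restricted log-likelihood is profiled over the total variance and
#' maximized over the heritability ratio `h2 = sigma2_g / (sigma2_g +
#' sigma2_e)` by deterministic 1-D search on `[1e-6, 1 - 1e-6]`
#' (tolerance 1e-8, no random restarts).
#'
#' @param y Numeric phenotype vector (finite values only).
#' @param X Fixed-effects design matrix (default: intercept only).
#' @param G A `grm` object or bare symmetric matrix.
#' @return A `variance_components` object: `sigma2_g`, `sigma2_e`, `h2`,
#'   `loglik` (restricted, at the optimum), and `boundary` (`TRUE` when
#'   the optimum sits at the h2 search boundary).
#' @export
reml_null <- function(y, X = NULL, G) {
  if (inherits(G, "grm")) G <- G$values
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  stopifnot(nrow(X) == n, nrow(G) == n)
  p <- qr(X)$rank
  if (n < p + 2) stop("too few observations for REML (n < rank(X) + 2)")
  eg <- eigen(G, symmetric = TRUE)
  reml_null_eig(y, X, eg$values, eg$vectors)
}

# REML on a precomputed eigendecomposition of G (shared with the LOCO scan)
reml_null_eig <- function(y, X, d, U) {
  n <- length(y)
  p <- qr(X)$rank
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  neg2_restricted_ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    if (any(v <= 0)) return(Inf)
    w <- 1 / v
    A <- crossprod(Xt, Xt * w)
    b <- solve(A, crossprod(Xt, w * yt))
    r <- yt - Xt %*% b
    q <- sum(w * r^2)
    (n - p) * log(q / (n - p)) + sum(log(v)) +
      determinant(A, logarithm = TRUE)$modulus
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  opt <- stats::optimize(neg2_restricted_ll, c(lo, hi), tol = 1e-8)
  h2 <- opt$minimum
  boundary <- h2 < 1e-4 || h2 > 1 - 1e-4
  # recover the profiled total variance at the optimum
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  A <- crossprod(Xt, Xt * w)
  b <- solve(A, crossprod(Xt, w * yt))
  r <- yt - Xt %*% b
  sigma2_p <- sum(w * r^2) / (n - p)
  loglik <- -0.5 * (opt$objective + (n - p) * (1 + log(2 * pi)))
  structure(list(sigma2_g = h2 * sigma2_p,
                 sigma2_e = (1 - h2) * sigma2_p,
                 h2 = h2,
                 loglik = as.numeric(loglik),
                 boundary = boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f%s\n",
              x$sigma2_g, x$sigma2_e, x$h2,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
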