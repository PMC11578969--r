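#' Per-SNP generalized-least-squares association scan
#'
#' For each SNP column, fits `y = X b + x_snp beta + eps` with
#' `cov(eps) = sigma2 * Sigma` by GLS, where `Sigma` is a known covariance
#' structure (for the mixed-model scan, `h2 G + (1 - h2) I`) and the
#' overall residual scale `sigma2` is re-estimated per SNP from the
#' whitened residuals. The Wald statistic is `chi2 = (beta / se)^2` with a
#' 1-df chi-squared p-value. With `Sigma = I` this reduces exactly to
#' ordinary least squares.
#'
#' Missing dosages are mean-imputed; SNPs with zero dosage variance after
#' imputation are emitted with missing statistics.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effects design matrix (default intercept).
#' @param dosage n x m dosage matrix (column names = SNP ids).
#' @param Sigma n x n covariance structure (default identity = OLS).
#' @return data.frame: `snp`, `freq` (mean dosage / 2), `beta`, `se`,
#'   `chi2`, `p`.
#' @export
gls_assoc <- function(y, X = NULL, dosage, Sigma = NULL) {
  n <- length(y)
  dosage <- as.matrix(dosage)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(dosage) == n, nrow(X) == n)
  if (is.null(Sigma)) {
    d <- rep(1, n); U <- diag(n)
  } else {
    eg <- eigen(Sigma, symmetric = TRUE)
    d <- eg$values; U <- eg$vectors
  }
  gls_assoc_eig(y, X, dosage, d, U)
}

# scan given the eigendecomposition of the covariance structure
gls_assoc_eig <- function(y, X, dosage, d, U) {
  n <- length(y)
  p <- ncol(X)
  if (any(d <= 0)) stop("covariance structure is not positive definite")
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  if (anyNA(dosage)) {
    for (j in seq_len(ncol(dosage))) {
      miss <- is.na(dosage[, j])
      if (any(miss)) dosage[miss, j] <- 2 * freq[j]
    }
  }
  s <- 1 / sqrt(d)
  yt <- s * crossprod(U, y)
  Xt <- crossprod(U, X) * s
  qrX <- qr(Xt)
  Q <- qr.Q(qrX)
  ry <- yt - Q %*% crossprod(Q, yt)
  rss0 <- sum(ry^2)
  Gt <- crossprod(U, dosage) * s
  Rg <- Gt - Q %*% crossprod(Q, Gt)
  gg <- colSums(Rg^2)
  gy <- as.numeric(crossprod(Rg, ry))
  ok <- gg > n * .Machine$double.eps * 100
  beta <- se <- chi2 <- pval <- rep(NA_real_, ncol(dosage))
  beta[ok] <- gy[ok] / gg[ok]
  rss <- rss0 - beta[ok]^2 * gg[ok]
  df <- n - qrX$rank - 1
  sigma2 <- pmax(rss, 0) / df
  se[ok] <- sqrt(sigma2 / gg[ok])
  chi2[ok] <- (beta[ok] / se[ok])^2
  pval[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE)
  data.frame(snp = colnames(dosage) %||% sprintf("snp%d", seq_along(beta)),
             freq = freq, beta = beta, se = se, chi2 = chi2, p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mixed-linear-model association scan with LOCO relationship matrices
#'
#' For each chromosome, variance components of the polygenic null model
#' are estimated once by REML using the genomic relationship matrix built
#' from all *other* chromosomes (leave one chromosome out, so the tested
#' SNP never contributes to the polygenic covariance), then every SNP on
#' that chromosome is tested by GLS under the fitted covariance structure
#' `h2 G(-c) + (1 - h2) I` with a 1-df Wald test.
#'
#' @param y Phenotype vector, one value per animal in genotype row order
#'   (or a named vector matched by animal id).
#' @param X Fixed-effects design matrix (default intercept; see
#'   [build_design()]).
#' @param genotypes A `genotype_matrix`.
#' @param grms Optional named list of precomputed LOCO `grm` objects
#'   (names = excluded chromosome); computed on the fly when `NULL`.
#' @param maf_min Minor-allele-frequency filter applied to tested SNPs
#'   (default 0.01; monomorphic SNPs always yield missing statistics).
#' @return An `assoc_results` data.frame: `snp`, `chr`, `bp`, `freq`,
#'   `beta`, `se`, `chi2`, `p`; per-chromosome null-model fits are kept in
#'   `attr(, "null_models")`.
#' @export
mlma_loco_scan <- function(y, X = NULL, genotypes, grms = NULL,
                           maf_min = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosage)
  if (!is.null(names(y))) y <- y[genotypes$animal_ids]
  if (length(y) != n) stop("phenotype length does not match genotypes")
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  map <- genotypes$map
  chrs <- unique(map$chr)
  nulls <- list()
  out <- vector("list", length(chrs))
  for (k in seq_along(chrs)) {
    c_ <- chrs[k]
    G <- if (!is.null(grms)) grms[[as.character(c_)]]
         else compute_grm(genotypes, exclude_chromosome = c_)
    if (inherits(G, "grm")) {
      if (!is.null(G$excluded_chromosome) &&
          !identical(G$excluded_chromosome, c_)) {
        stop("grm supplied for chromosome ", c_,
             " excludes a different chromosome")
      }
      G <- G$values
    }
    eg <- eigen(G, symmetric = TRUE)
    vc <- reml_null_eig(y, X, eg$values, eg$vectors)
    nulls[[as.character(c_)]] <- vc
    on_c <- map$chr == c_
    dos <- genotypes$dosage[, on_c, drop = FALSE]
    d <- vc$h2 * eg$values + (1 - vc$h2)
    res <- gls_assoc_eig(y, X, dos, d, eg$vectors)
    maf <- pmin(res$freq, 1 - res$freq)
    low <- maf < maf_min
    res[low, c("beta", "se", "chi2", "p")] <- NA_real_
    out[[k]] <- cbind(res[, "snp", drop = FALSE],
                      chr = map$chr[on_c], bp = map$bp[on_c],
                      res[, c("freq", "beta", "se", "chi2", "p")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "null_models") <- nulls
  class(res) <- c("assoc_results", "data.frame")
  res
}

#' Fixed-effects design matrix for the association model
#'
#' Builds the default design used throughout: intercept plus treatment
#' contrasts for parity class and ventilation class, from a covariate
#' table keyed by `animal_id`.
#'
#' @param covariates data.frame with `animal_id` and the requested columns.
#' @param terms Character vector of covariate columns (default
#'   `c("parity", "ventilation")`); factors are expanded to treatment
#'   contrasts.
#' @param animal_ids Row order to enforce (default: table order).
#' @return Numeric design matrix with an intercept column.
#' @export
build_design <- function(covariates, terms = c("parity", "ventilation"),
                         animal_ids = NULL) {
  stopifnot("animal_id" %in% names(covariates))
  if (!is.null(animal_ids)) {
    covariates <- covariates[match(animal_ids, covariates$animal_id), ,
                             drop = FALSE]
    if (anyNA(covariates$animal_id)) stop("covariates missing for some animals")
  }
  terms <- intersect(terms, names(covariates))
  if (length(terms) == 0) {
    return(matrix(1, nrow(covariates), 1,
                  dimnames = list(covariates$animal_id, "(Intercept)")))
  }
  df <- covariates[, terms, drop = FALSE]
  for (t in terms) df[[t]] <- factor(df[[t]])
  # drop single-level factors (would break model.matrix)
  df <- df[, vapply(df, function(x) nlevels(x) > 1, logical(1)), drop = FALSE]
  if (ncol(df) == 0) {
    return(matrix(1, nrow(covariates), 1,
                  dimnames = list(covariates$animal_id, "(Intercept)")))
  }
  X <- stats::model.matrix(~ ., data = df)
  rownames(X) <- covariates$animal_id
  X
}
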