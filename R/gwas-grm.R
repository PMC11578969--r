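#' Genomic relationship matrix from standardized dosages
#'
#' VanRaden/GCTA-style GRM: dosages are centered at twice the sample allele
#' frequency and scaled by the binomial standard deviation,
#' `z = (x - 2p) / sqrt(2 p (1 - p))`, missing dosages are replaced by `2p`,
#' and `G = Z Z' / m` over the included SNPs. Monomorphic SNPs are dropped
#' (with a message). Optionally excludes one chromosome, which is how the
#' leave-one-chromosome-out scan builds its per-chromosome matrices.
#'
#' @param genotypes A `genotype_matrix`.
#' @param exclude_chromosome Chromosome to leave out, or `NULL` for all.
#' @return A `grm` object: list with `values` (n x n symmetric matrix),
#'   `excluded_chromosome`, `n_snps` used.
#' @export
compute_grm <- function(genotypes, exclude_chromosome = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  keep <- rep(TRUE, ncol(genotypes$dosage))
  if (!is.null(exclude_chromosome)) {
    keep <- !(genotypes$map$chr %in% exclude_chromosome)
  }
  X <- genotypes$dosage[, keep, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (sum(poly) < 2) {
    stop("fewer than 2 polymorphic SNPs available for the GRM",
         if (!is.null(exclude_chromosome))
           paste0(" after excluding chromosome ",
                  paste(exclude_chromosome, collapse = ",")))
  }
  if (any(!poly)) {
    message(sprintf("compute_grm: dropping %d monomorphic SNP(s)",
                    sum(!poly)))
  }
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  if (anyNA(Z)) Z[is.na(Z)] <- 0       # missing -> 2p, i.e. centered 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  G <- (G + t(G)) / 2
  structure(list(values = G,
                 excluded_chromosome = exclude_chromosome,
                 n_snps = ncol(Z)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d from %d SNPs%s\n",
              nrow(x$values), ncol(x$values), x$n_snps,
              if (is.null(x$excluded_chromosome)) "" else
                paste0(" (chromosome ",
                       paste(x$excluded_chromosome, collapse = ","),
                       " left out)")))
  invisible(x)
}

#' Windowed LD pruning of SNPs
#'
#' Greedy sliding-window pruning in the PLINK `--indep-pairwise` style:
#' within each window of `window_snps` SNPs (per chromosome), while any
#' retained pair has squared dosage correlation above `r2_max`, the member
#' with the lower minor-allele frequency is removed (ties: the later map
#' position); the window then slides by `step_snps`. Missing dosages are
#' mean-imputed before correlation; monomorphic SNPs are removed up front
#' with a message.
#'
#' @param genotypes A `genotype_matrix`.
#' @param window_snps,step_snps,r2_max Pruning parameters (defaults 50, 5,
#'   0.1, the study's `indep-pairwise 50 5 0.1`).
#' @return Character vector of retained SNP ids, in map order.
#' @export
ld_prune <- function(genotypes, window_snps = 50, step_snps = 5,
                     r2_max = 0.1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            window_snps >= 2, step_snps >= 1, r2_max >= 0)
  X <- genotypes$dosage
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (any(!poly)) {
    message(sprintf("ld_prune: removing %d monomorphic SNP(s)", sum(!poly)))
  }
  maf <- pmin(p, 1 - p)
  keep <- poly
  for (chr in unique(genotypes$map$chr)) {
    idx_chr <- which(genotypes$map$chr == chr & keep)
    if (length(idx_chr) < 2) next
    Xc <- X[, idx_chr, drop = FALSE]
    if (anyNA(Xc)) {
      for (j in seq_len(ncol(Xc))) {
        miss <- is.na(Xc[, j])
        if (any(miss)) Xc[miss, j] <- 2 * p[idx_chr[j]]
      }
    }
    m_c <- length(idx_chr)
    alive <- rep(TRUE, m_c)
    starts <- seq(1, max(1, m_c - 1), by = step_snps)
    for (s in starts) {
      win <- s:min(s + window_snps - 1, m_c)
      act <- win[alive[win]]
      if (length(act) < 2) next
      r2 <- stats::cor(Xc[, act, drop = FALSE])^2
      diag(r2) <- 0
      while (any(r2 > r2_max)) {
        hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- act[hit[1]]; b <- act[hit[2]]
        drop_local <- if (maf[idx_chr[a]] < maf[idx_chr[b]]) hit[1]
          else if (maf[idx_chr[b]] < maf[idx_chr[a]]) hit[2]
          else max(hit)               # tie: later map position
        alive[act[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
    keep[idx_chr[!alive]] <- FALSE
  }
  genotypes$map$snp[keep]
}
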