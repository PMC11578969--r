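#' Genome-wide and suggestive significance thresholds
#'
#' Bonferroni threshold `0.05 / N` and suggestive threshold `1 / N`
#' (one expected false positive per genome scan), where `N` is the number
#' of independent SNPs left after LD pruning.
#'
#' @param n_pruned Number of independent SNPs after pruning.
#' @return List: `bonferroni`, `suggestive`, `n_independent_snps`.
#' @examples
#' significance_thresholds(42729)  # ~1.17e-6 and ~2.34e-5
#' @export
significance_thresholds <- function(n_pruned) {
  n_pruned <- as.numeric(n_pruned)
  stopifnot(length(n_pruned) == 1, n_pruned >= 1)
  list(bonferroni = 0.05 / n_pruned,
       suggestive = 1 / n_pruned,
       n_independent_snps = n_pruned)
}

#' Chromosome-wise thresholds from the effective number of segments
#'
#' For each chromosome of genetic length `L` (cM), the effective number of
#' independent chromosomal segments is `Me = 2 Ne L / log(Ne L)` (natural
#' log) with effective population size `Ne`, and the chromosome-wise
#' threshold is `0.05 / Me`. Physical length is converted at 1 Mb = 1 cM.
#'
#' @param L_cM Named numeric vector of chromosome lengths in cM (names =
#'   chromosome ids), e.g. from [chromosome_lengths_cM()].
#' @param Ne Effective population size (default 60).
#' @return data.frame: `chromosome`, `L_cM`, `Me`, `threshold`.
#' @examples
#' chromosome_wise_threshold(c(`1` = 100))  # Me ~ 1379.4, thr ~ 3.62e-5
#' @export
chromosome_wise_threshold <- function(L_cM, Ne = 60) {
  stopifnot(all(L_cM > 0), Ne > 0)
  if (any(Ne * L_cM <= 1)) {
    stop("Ne * L must exceed 1 for the segment formula (log nonpositive)")
  }
  Me <- 2 * Ne * L_cM / log(Ne * L_cM)
  data.frame(chromosome = names(L_cM) %||% as.character(seq_along(L_cM)),
             L_cM = as.numeric(L_cM), Me = as.numeric(Me),
             threshold = 0.05 / as.numeric(Me),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chromosome genetic lengths from a SNP map
#'
#' Takes the spanned physical length per chromosome (largest mapped
#' position) and converts it at 1 Mb = 1 cM.
#'
#' @param map data.frame with `chr` and `bp` columns.
#' @return Named numeric vector, cM per chromosome.
#' @export
chromosome_lengths_cM <- function(map) {
  L <- tapply(map$bp, map$chr, max) / 1e6
  stats::setNames(as.numeric(L), names(L))
}

#' Bundle the three significance-threshold schemes
#'
#' @param n_pruned Independent SNP count after LD pruning.
#' @param L_cM Chromosome lengths in cM.
#' @param Ne Effective population size for the segment formula.
#' @return A `threshold_set`: `bonferroni`, `suggestive`,
#'   `chromosome_wise` (named vector by chromosome), `n_independent_snps`,
#'   `Me` table.
#' @export
threshold_set <- function(n_pruned, L_cM, Ne = 60) {
  gw <- significance_thresholds(n_pruned)
  cw <- chromosome_wise_threshold(L_cM, Ne)
  thr <- cw$threshold
  names(thr) <- cw$chromosome
  structure(list(bonferroni = gw$bonferroni,
                 suggestive = gw$suggestive,
                 chromosome_wise = thr,
                 n_independent_snps = gw$n_independent_snps,
                 Me = cw),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> N = %g independent SNPs\n", x$n_independent_snps))
  cat(sprintf("  bonferroni: %.3g   suggestive: %.3g\n",
              x$bonferroni, x$suggestive))
  cat(sprintf("  chromosome-wise: %s\n",
              paste(sprintf("%s=%.3g", names(x$chromosome_wise),
                            x$chromosome_wise), collapse = " ")))
  invisible(x)
}

#' Label SNPs by the significance levels they reach
#'
#' Applies the three thresholds with the inclusive convention
#' `p <= threshold`. Passing the Bonferroni threshold implies passing the
#' suggestive one (thresholds are nested by construction).
#'
#' @param assoc An `assoc_results` data.frame (needs `chr` and `p`).
#' @param thresholds A `threshold_set`.
#' @return `assoc` with added logical columns `sig_bonferroni`,
#'   `sig_chromosome_wise`, `sig_suggestive`.
#' @export
classify_hits <- function(assoc, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("chr", "p") %in% names(assoc)))
  cw <- thresholds$chromosome_wise[as.character(assoc$chr)]
  assoc$sig_bonferroni <- !is.na(assoc$p) & assoc$p <= thresholds$bonferroni
  assoc$sig_chromosome_wise <- !is.na(assoc$p) & !is.na(cw) & assoc$p <= cw
  assoc$sig_suggestive <- !is.na(assoc$p) & assoc$p <= thresholds$suggestive
  assoc
}

#' Genomic inflation factor with a median-based confidence interval
#'
#' `lambda` is the median observed 1-df chi-squared statistic divided by
#' the null median `qchisq(0.5, 1)`. The 95% interval is the
#' distribution-free order-statistic interval for the sample median
#' (binomial ranks at 2.5% / 97.5%) mapped through the same ratio.
#'
#' @param stat Numeric vector of chi-squared statistics, or p-values with
#'   `input = "p"` (converted through the 1-df upper tail).
#' @param input `"chi2"` (default) or `"p"`.
#' @return An `inflation_result`: `lambda`, `ci95` (length 2), `n`.
#' @export
genomic_inflation <- function(stat, input = c("chi2", "p")) {
  input <- match.arg(input)
  stat <- stat[is.finite(stat)]
  if (length(stat) == 0) stop("no finite test statistics supplied")
  if (input == "p") stat <- stats::qchisq(stat, df = 1, lower.tail = FALSE)
  n <- length(stat)
  if (n < 100) {
    warning("genomic inflation estimated from fewer than 100 tests")
  }
  null_med <- stats::qchisq(0.5, df = 1)
  lambda <- stats::median(stat) / null_med
  srt <- sort(stat)
  lo_rank <- max(1L, stats::qbinom(0.025, n, 0.5))
  hi_rank <- min(n, stats::qbinom(0.975, n, 0.5) + 1L)
  ci <- c(srt[lo_rank], srt[hi_rank]) / null_med
  ci <- c(min(ci[1], lambda), max(ci[2], lambda))
  structure(list(lambda = lambda, ci95 = ci, n = n),
            class = "inflation_result")
}

#' @export
print.inflation_result <- function(x, ...) {
  cat(sprintf("<inflation_result> lambda = %.3f (95%% CI %.3f-%.3f, n = %d)\n",
              x$lambda, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Quantile-quantile coordinates for p-values
#'
#' Observed `-log10(p)` (ascending p) against the `-log10` of the uniform
#' order-statistic quantiles `(i - 0.5) / n`, ready for plotting.
#'
#' @param p Numeric p-values.
#' @return data.frame: `expected`, `observed`, both `-log10` scaled.
#' @export
qq_table <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) == 0) stop("no finite p-values supplied")
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(sort(p)))
}
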