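# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, explicit matrix inverses) so they
# exercise none of the package's own code paths.

t0 <- as.POSIXct("2021-06-05 00:00:00", tz = "UTC")

make_series <- function(values, interval_min = 10, start = t0,
                        ventilation = "mechanical", parity = 3L,
                        gaps_after = integer(0), id = "test") {
  # gaps_after: indices after which an extra interval is inserted
  steps <- rep(interval_min, length(values) - 1)
  steps[gaps_after] <- steps[gaps_after] + 2 * interval_min
  ts <- start + c(0, cumsum(steps)) * 60
  tv_series(id, ts, values, ventilation = ventilation, parity = parity,
            barn_id = "barn_T")
}

naive_window_devs <- function(values, ts_min, stat, w = 6, interval = 10,
                              tol = 2) {
  out_t <- numeric(0); out_d <- numeric(0)
  for (t in seq_along(values)) {
    if (t < w) next
    ok <- TRUE
    for (k in (t - w + 2):t) {
      if (abs((ts_min[k] - ts_min[k - 1]) - interval) > tol) ok <- FALSE
    }
    if (!ok) next
    win <- values[(t - w + 1):t]
    ctr <- if (stat == "average") mean(win) else median(win)
    out_t <- c(out_t, ts_min[t])
    out_d <- c(out_d, values[t] - ctr)
  }
  list(ts_min = out_t, dev = out_d)
}

naive_hsd_daily <- function(values, ts_min, thr, interval = 10, tol = 2,
                            min_run = 1) {
  day <- floor(ts_min / 1440)
  vapply(sort(unique(day)), function(d) {
    ix <- which(day == d)
    runs <- integer(0); cur <- 0
    for (j in seq_along(ix)) {
      contiguous <- j > 1 &&
        abs((ts_min[ix[j]] - ts_min[ix[j - 1]]) - interval) <= tol
      if (values[ix[j]] > thr) {
        if (cur > 0 && contiguous) cur <- cur + 1
        else { if (cur > 0) runs <- c(runs, cur); cur <- 1 }
      } else {
        if (cur > 0) runs <- c(runs, cur); cur <- 0
      }
    }
    if (cur > 0) runs <- c(runs, cur)
    sum(runs[runs >= min_run]) * interval
  }, numeric(1))
}

naive_hsu <- function(values, thr) {
  a <- 0; b <- 0
  for (v in values) {
    if (v > thr) a <- a + (v - thr) else b <- b + (v - thr)
  }
  c(HSU_A = a, HSU_B = b)
}

naive_nor <- function(med, ave, var_tv) {
  n01 <- function(x) (x - min(x)) / (max(x) - min(x))
  list(Nor_medvar = n01(med) * n01(var_tv),
       Nor_avevar = n01(ave) * n01(var_tv))
}

# explicit-inverse GLS for one SNP: y = X b + g beta + eps, cov(eps) ~ V
naive_gls_one <- function(y, X, g, V) {
  M <- cbind(X, g)
  Vi <- solve(V)
  C <- solve(t(M) %*% Vi %*% M)
  bh <- C %*% t(M) %*% Vi %*% y
  r <- y - M %*% bh
  df <- length(y) - ncol(M)
  s2 <- as.numeric(t(r) %*% Vi %*% r) / df
  k <- ncol(M)
  beta <- bh[k]
  se <- sqrt(s2 * C[k, k])
  chi2 <- (beta / se)^2
  c(beta = beta, se = se, chi2 = chi2,
    p = pchisq(chi2, 1, lower.tail = FALSE))
}

naive_overlap <- function(snps, features, flank) {
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(features))) {
      if (as.character(snps$chr[i]) != as.character(features$chr[j])) next
      lo <- snps$bp[i] - flank; hi <- snps$bp[i] + flank
      if (features$end[j] >= lo && features$start[j] <= hi) {
        d <- 0
        if (snps$bp[i] < features$start[j]) d <- features$start[j] - snps$bp[i]
        if (snps$bp[i] > features$end[j]) d <- snps$bp[i] - features$end[j]
        rows[[length(rows) + 1]] <-
          data.frame(snp = snps$snp[i], feature_id = features$feature_id[j],
                     distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(snp = character(0), feature_id = character(0),
                      distance = numeric(0)))
  }
  do.call(rbind, rows)
}

minutes_of <- function(series) {
  as.numeric(difftime(series$timestamps, t0, units = "mins"))
}

# tiny cohort used in several files
small_cohort <- function(seed = 11, n_animals = 30, n_days = 2) {
  simulate_cohort(sim_config(n_animals = n_animals, n_chromosomes = 2,
                             snps_per_chromosome = 40, n_days = n_days,
                             seed = seed))
}

make_genotypes <- function(dosage, chr = rep(1L, ncol(dosage)),
                           bp = seq_len(ncol(dosage)) * 1000) {
  n <- nrow(dosage); m <- ncol(dosage)
  ids <- sprintf("an_%03d", seq_len(n))
  snp <- sprintf("s_%d_%d", chr, bp)
  dimnames(dosage) <- list(ids, snp)
  structure(list(dosage = dosage,
                 map = data.frame(snp = snp, chr = chr, bp = bp,
                                  a1 = "A", a2 = "B",
                                  stringsAsFactors = FALSE),
                 animal_ids = ids,
                 freq = colMeans(dosage, na.rm = TRUE) / 2),
            class = "genotype_matrix")
}
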