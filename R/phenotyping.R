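#' @keywords internal
#' k-th smallest value per row, by repeated vectorized min extraction.
#' Cost O(ncol * k) vectorized passes; avoids a per-row sort call.
row_kth_smallest <- function(M, k) {
  stopifnot(k >= 1, k <= ncol(M))
  for (i in seq_len(k - 1)) {
    j <- max.col(-M, ties.method = "first")
    M[cbind(seq_len(nrow(M)), j)] <- Inf
  }
  out <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) out <- pmin(out, M[, j])
  out
}

row_median <- function(M) {
  w <- ncol(M)
  if (w %% 2 == 1) {
    row_kth_smallest(M, (w + 1) / 2)
  } else {
    (row_kth_smallest(M, w / 2) + row_kth_smallest(M, w / 2 + 1)) / 2
  }
}

# TRUE at position i (i >= 2) when timestamps i-1 -> i sit on the nominal grid
grid_step_ok <- function(timestamps, interval, tol) {
  d <- diff(as.numeric(timestamps)) / 60
  abs(d - interval) <= tol
}

#' Moving-window deviations of a temperature series
#'
#' For every time point with a complete trailing window of `window_length`
#' consecutive on-grid observations ending at that point, the deviation is
#' the observed value minus the window mean (`stat = "average"`) or window
#' median (`stat = "median"`); the window includes the point itself.
#' Windows spanning a sampling gap (consecutive timestamps off the nominal
#' `interval` by more than `interval_tol` minutes) yield no deviation.
#'
#' @param series A `tv_series`.
#' @param stat `"average"` or `"median"` window statistic.
#' @param window_length Observations per window (default 6).
#' @param interval Nominal sampling interval in minutes (default 10).
#' @param interval_tol Grid tolerance in minutes (default 2).
#' @return A `deviation_series`: list with `animal_id`, `timestamps` (the
#'   window-end times), `deviations`, `window_stat`.
#' @examples
#' s <- tv_series("a", as.POSIXct("2021-06-05", tz = "UTC") + 600 * (0:5),
#'                c(1, 2, 3, 4, 5, 6))
#' window_deviations(s, "average")$deviations  # 6 - mean(1:6) = 2.5
#' @export
window_deviations <- function(series, stat = c("average", "median"),
                              window_length = 6, interval = 10,
                              interval_tol = 2) {
  stat <- match.arg(stat)
  stopifnot(inherits(series, "tv_series"), window_length >= 2)
  n <- length(series$tv)
  empty <- structure(list(animal_id = series$animal_id,
                          timestamps = series$timestamps[0],
                          deviations = numeric(0), window_stat = stat),
                     class = "deviation_series")
  if (n < window_length) {
    warning(sprintf("series %s has %d observation(s), shorter than the window (%d)",
                    series$animal_id, n, window_length))
    return(empty)
  }
  # complete windows: the window_length - 1 steps ending at t are all on-grid
  ok_step <- grid_step_ok(series$timestamps, interval, interval_tol)
  bad <- cumsum(c(0, !ok_step))
  ends <- seq(window_length, n)
  complete <- bad[ends] - bad[ends - window_length + 1] == 0
  ends <- ends[complete]
  if (length(ends) == 0) return(empty)
  E <- stats::embed(series$tv, window_length)[ends - window_length + 1, ,
                                              drop = FALSE]
  center <- if (stat == "average") rowMeans(E) else row_median(E)
  structure(list(animal_id = series$animal_id,
                 timestamps = series$timestamps[ends],
                 deviations = series$tv[ends] - center,
                 window_stat = stat),
            class = "deviation_series")
}

#' @export
print.deviation_series <- function(x, ...) {
  cat(sprintf("<deviation_series> %s: %d deviations (%s windows)\n",
              x$animal_id, length(x$deviations), x$window_stat))
  invisible(x)
}

#' Log-transformed variance of window deviations
#'
#' Natural log of the sample variance (denominator n - 1) of the
#' deviations. Degenerate input (< 2 deviations, or zero variance, which
#' would give -Inf) returns `NA`.
#'
#' @param devs A `deviation_series` (or bare numeric vector).
#' @return Scalar, or `NA_real_` when undefined.
#' @export
ln_variance <- function(devs) {
  x <- if (inherits(devs, "deviation_series")) devs$deviations else devs
  if (length(x) < 2) return(NA_real_)
  v <- stats::var(x)
  if (v <= 0) return(NA_real_)
  log(v)
}

#' Lag-1 autocorrelation of window deviations
#'
#' Pearson correlation between deviations at consecutive grid points;
#' pairs spanning a sampling gap are excluded. Requires at least 3
#' deviations and nonzero variance on both sides of the pairing,
#' otherwise `NA`.
#'
#' @inheritParams window_deviations
#' @param devs A `deviation_series`.
#' @return Scalar in [-1, 1], or `NA_real_`.
#' @export
lag1_autocorrelation <- function(devs, interval = 10, interval_tol = 2) {
  stopifnot(inherits(devs, "deviation_series"))
  x <- devs$deviations
  if (length(x) < 3) return(NA_real_)
  ok <- grid_step_ok(devs$timestamps, interval, interval_tol)
  a <- x[-length(x)][ok]
  b <- x[-1][ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Moment skewness of window deviations
#'
#' Skewness g1 = m3 / m2^(3/2) with central moments using denominator n.
#' Zero variance or fewer than 3 deviations returns `NA`.
#'
#' @param devs A `deviation_series` (or bare numeric vector).
#' @return Scalar, or `NA_real_`.
#' @export
skewness <- function(devs) {
  x <- if (inherits(devs, "deviation_series")) devs$deviations else devs
  n <- length(x)
  if (n < 3) return(NA_real_)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(NA_real_)
  mean(xc^3) / m2^1.5
}

#' Daily maximum vaginal temperature
#'
#' Maximum observed temperature per calendar day (days with no records are
#' omitted, not zeroed), plus a one-number-per-animal aggregate over days.
#'
#' @param series A `tv_series`.
#' @param aggregate `"mean"` (default), `"median"` or `"max"` over daily
#'   maxima.
#' @return List with `daily` (data.frame: `day`, `max_tv`) and `aggregate`.
#' @export
daily_max_tv <- function(series, aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(series, "tv_series"), length(series$tv) > 0)
  day <- as.Date(series$timestamps, tz = "UTC")
  mx <- tapply(series$tv, day, max)
  daily <- data.frame(day = as.Date(names(mx)), max_tv = as.numeric(mx))
  agg <- switch(aggregate,
                mean = mean(daily$max_tv),
                median = stats::median(daily$max_tv),
                max = max(daily$max_tv))
  list(daily = daily, aggregate = agg)
}

#' Daily heat-stress duration
#'
#' Minutes per day during which the temperature consistently exceeded the
#' animal's ventilation-specific heat-stress threshold: within each day,
#' runs of consecutive on-grid observations strictly above the threshold
#' of length at least `cfg$min_run_length` contribute (run length x
#' sampling interval) minutes. Runs are broken by sampling gaps as well as
#' by dips to or below the threshold.
#'
#' @param series A `tv_series`.
#' @param cfg An [hs_config()].
#' @return List with `daily` (data.frame: `day`, `hsd_min`) and
#'   `aggregate` (per `cfg$aggregate` over recorded days).
#' @export
hs_duration <- function(series, cfg = hs_config()) {
  stopifnot(inherits(series, "tv_series"), length(series$tv) > 0)
  thr <- hs_threshold_for(cfg, series$ventilation)
  day <- as.Date(series$timestamps, tz = "UTC")
  above <- series$tv > thr
  # run id increments at gap or state change; day boundaries handled by split
  step_ok <- c(FALSE, grid_step_ok(series$timestamps, cfg$interval,
                                   cfg$interval_tol))
  new_run <- !step_ok | c(TRUE, diff(above) != 0)
  run_id <- cumsum(new_run)
  per_day <- tapply(seq_along(above), day, function(ix) {
    runs <- rle_runs(run_id[ix], above[ix])
    sum(runs[runs >= cfg$min_run_length]) * cfg$interval
  })
  daily <- data.frame(day = as.Date(names(per_day)),
                      hsd_min = as.numeric(per_day))
  agg <- switch(cfg$aggregate,
                mean = mean(daily$hsd_min),
                median = stats::median(daily$hsd_min),
                max = max(daily$hsd_min))
  list(daily = daily, aggregate = agg, threshold = thr)
}

# lengths of above-threshold runs, given per-observation run ids
rle_runs <- function(run_id, above) {
  if (!any(above)) return(integer(0))
  as.integer(table(run_id[above]))
}

#' Heat-stress units above and below the threshold
#'
#' Signed sums of temperature deviations from the heat-stress threshold
#' over the whole recording period: `HSU_A` sums the positive deviations
#' (observations strictly above the threshold, so `HSU_A >= 0`), `HSU_B`
#' sums the non-positive ones (`HSU_B <= 0`, or its absolute value when
#' `cfg$hsu_b_absolute`).
#'
#' @param series A `tv_series`.
#' @param cfg An [hs_config()].
#' @return Named list `HSU_A`, `HSU_B`, `threshold`.
#' @export
heat_stress_units <- function(series, cfg = hs_config()) {
  stopifnot(inherits(series, "tv_series"))
  thr <- hs_threshold_for(cfg, series$ventilation)
  d <- series$tv - thr
  hsu_a <- sum(d[d > 0])
  hsu_b <- sum(d[d <= 0])
  if (cfg$hsu_b_absolute) hsu_b <- abs(hsu_b)
  list(HSU_A = hsu_a, HSU_B = hsu_b, threshold = thr)
}

#' Normalized variance-product indicators
#'
#' Population-level min-max products: each animal's median (or mean)
#' whole-series temperature is min-max normalized across animals and
#' multiplied by its min-max normalized whole-series temperature variance.
#'
#' @param stats_table data.frame with columns `animal_id`, `med`, `ave`,
#'   `var_tv` (per-animal median, mean and variance of the whole series).
#' @return data.frame with `animal_id`, `Nor_medvar`, `Nor_avevar`, both
#'   in [0, 1].
#' @export
normalized_variance_products <- function(stats_table) {
  stopifnot(all(c("animal_id", "med", "ave", "var_tv") %in%
                  names(stats_table)))
  if (nrow(stats_table) < 2) {
    stop("normalization needs at least 2 animals")
  }
  norm01 <- function(x, what) {
    r <- range(x, na.rm = TRUE)
    if (!all(is.finite(r)) || r[2] == r[1]) {
      stop("min-max normalization undefined: zero range in ", what)
    }
    (x - r[1]) / (r[2] - r[1])
  }
  nv <- norm01(stats_table$var_tv, "Tv variance")
  data.frame(animal_id = stats_table$animal_id,
             Nor_medvar = norm01(stats_table$med, "median Tv") * nv,
             Nor_avevar = norm01(stats_table$ave, "mean Tv") * nv,
             stringsAsFactors = FALSE)
}

#' Derive all twelve climatic-resilience indicators for a cohort
#'
#' Computes, per animal: log-variance, lag-1 autocorrelation and skewness
#' of average- and median-window deviations (6 indicators), the aggregate
#' daily maximum temperature, the aggregate daily heat-stress duration,
#' heat-stress units above/below the threshold, and the two population
#' min-max normalized variance products, plus the covariates carried on
#' each series. Indicators undefined for an animal (degenerate series)
#' come back as `NA`, never silently zero.
#'
#' @param cohort A `tv_cohort` or plain list of `tv_series`.
#' @param cfg An [hs_config()].
#' @return A `cr_phenotypes` data.frame, one row per animal, with columns
#'   `animal_id`, `LnVar_Ave`, `LnVar_Med`, `Autocor_Ave`, `Autocor_Med`,
#'   `Skew_Ave`, `Skew_Med`, `Max_Tv`, `HSD`, `HSU_A`, `HSU_B`,
#'   `Nor_avevar`, `Nor_medvar`, `parity`, `ventilation`, `barn`.
#' @export
derive_all_indicators <- function(cohort, cfg = hs_config()) {
  stopifnot(length(cohort) > 0)
  ids <- vapply(cohort, function(s) s$animal_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate animal ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  one <- function(s) {
    dev_a <- suppressWarnings(
      window_deviations(s, "average", cfg$window_length, cfg$interval,
                        cfg$interval_tol))
    dev_m <- suppressWarnings(
      window_deviations(s, "median", cfg$window_length, cfg$interval,
                        cfg$interval_tol))
    hsu <- heat_stress_units(s, cfg)
    data.frame(
      animal_id = s$animal_id,
      LnVar_Ave = ln_variance(dev_a),
      LnVar_Med = ln_variance(dev_m),
      Autocor_Ave = lag1_autocorrelation(dev_a, cfg$interval,
                                         cfg$interval_tol),
      Autocor_Med = lag1_autocorrelation(dev_m, cfg$interval,
                                         cfg$interval_tol),
      Skew_Ave = skewness(dev_a),
      Skew_Med = skewness(dev_m),
      Max_Tv = daily_max_tv(s, cfg$aggregate)$aggregate,
      HSD = hs_duration(s, cfg)$aggregate,
      HSU_A = hsu$HSU_A,
      HSU_B = hsu$HSU_B,
      med = stats::median(s$tv),
      ave = mean(s$tv),
      var_tv = if (length(s$tv) > 1) stats::var(s$tv) else NA_real_,
      parity = s$parity,
      ventilation = s$ventilation,
      barn = s$barn_id,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, lapply(cohort, one))
  rownames(tab) <- NULL
  nor <- normalized_variance_products(tab[, c("animal_id", "med", "ave",
                                              "var_tv")])
  tab <- merge(tab, nor, by = "animal_id", sort = FALSE)
  cols <- c("animal_id", "LnVar_Ave", "LnVar_Med", "Autocor_Ave",
            "Autocor_Med", "Skew_Ave", "Skew_Med", "Max_Tv", "HSD",
            "HSU_A", "HSU_B", "Nor_avevar", "Nor_medvar",
            "parity", "ventilation", "barn")
  out <- tab[, cols]
  attr(out, "aggregate") <- cfg$aggregate
  class(out) <- c("cr_phenotypes", "data.frame")
  out
}

#' Names of the twelve climatic-resilience indicators
#' @return Character vector of indicator column names.
#' @export
cr_indicator_names <- function() {
  c("LnVar_Ave", "LnVar_Med", "Autocor_Ave", "Autocor_Med",
    "Skew_Ave", "Skew_Med", "Max_Tv", "HSD", "HSU_A", "HSU_B",
    "Nor_avevar", "Nor_medvar")
}
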