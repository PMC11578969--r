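test_that("window deviations match hand-computed examples and handle gaps", {
  s_const <- make_series(rep(39, 6))
  expect_equal(window_deviations(s_const, "average")$deviations, 0)

  s <- make_series(1:6)
  expect_equal(window_deviations(s, "average")$deviations, 6 - 3.5)

  s_out <- make_series(c(1, 2, 3, 4, 5, 100))
  expect_equal(window_deviations(s_out, "median")$deviations, 100 - 3.5)

  # a gap between obs 6 and 7 invalidates every window spanning it,
  # leaving only the windows ending at obs 6 and obs 12
  s_gap <- make_series(1:12, gaps_after = 6)
  dev <- window_deviations(s_gap, "average")
  expect_equal(dev$deviations, c(6 - mean(1:6), 12 - mean(7:12)))

  expect_warning(window_deviations(make_series(1:3)), "shorter")
})

test_that("window deviations agree exactly with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(6:60, 1)
    vals <- round(rnorm(n, 39, 0.5), 3)
    gaps <- if (n > 8 && runif(1) < 0.5) sample(n - 1, 2) else integer(0)
    s <- make_series(vals, gaps_after = gaps)
    mins <- minutes_of(s)
    for (st in c("average", "median")) {
      got <- window_deviations(s, st)
      ora <- naive_window_devs(vals, mins, st)
      expect_equal(minutes_of(list(timestamps = got$timestamps)), ora$ts_min)
      expect_equal(got$deviations, ora$dev, tolerance = 1e-12)
    }
  }
})

test_that("deviation summary statistics match hand calculations", {
  dev <- structure(list(animal_id = "a",
                        timestamps = t0 + 600 * (0:3),
                        deviations = c(1, -1, 1, -1),
                        window_stat = "average"),
                   class = "deviation_series")
  expect_equal(ln_variance(dev), log(4 / 3))
  expect_equal(ln_variance(c(2, -2, 2, -2)), log(4 / 3) + 2 * log(2))
  expect_true(is.na(ln_variance(rep(0, 5))))
  expect_true(is.na(ln_variance(c(1))))

  alt <- structure(list(animal_id = "a", timestamps = t0 + 600 * (0:7),
                        deviations = rep(c(1, -1), 4),
                        window_stat = "average"),
                   class = "deviation_series")
  expect_lt(lag1_autocorrelation(alt), -0.9)
  const <- alt; const$deviations <- rep(1, 8)
  expect_true(is.na(lag1_autocorrelation(const)))

  set.seed(1)
  wn <- structure(list(animal_id = "a", timestamps = t0 + 600 * (0:9999),
                       deviations = rnorm(10000), window_stat = "average"),
                  class = "deviation_series")
  expect_lt(abs(lag1_autocorrelation(wn)), 0.05)

  # lag pairs spanning a gap are excluded: inject a gap and check the
  # estimate equals cor() on the contiguous pairs only
  gap <- structure(list(animal_id = "a",
                        timestamps = t0 + c(0:4, 10:14) * 600,
                        deviations = c(1, 2, 1, 2, 1, 5, 6, 5, 6, 5),
                        window_stat = "average"),
                   class = "deviation_series")
  x <- gap$deviations
  pairs_keep <- c(1:4, 6:9)
  expect_equal(lag1_autocorrelation(gap),
               cor(x[pairs_keep], x[pairs_keep + 1]))

  expect_equal(skewness(c(-2, -1, 0, 1, 2)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 0.09375 / 0.1875^1.5)
  expect_equal(skewness(-c(0, 0, 0, 1)), -0.09375 / 0.1875^1.5)
  expect_true(is.na(skewness(rep(3, 5))))
})

test_that("daily maxima aggregate over recorded days only", {
  s1 <- make_series(c(38.5, 39.9, 39.1))
  expect_equal(daily_max_tv(s1)$aggregate, 39.9)

  two_days <- tv_series("a", t0 + c(0, 600, 86400, 87000),
                        c(38.0, 39.0, 40.0, 39.5))
  dm <- daily_max_tv(two_days)
  expect_equal(dm$daily$max_tv, c(39.0, 40.0))
  expect_equal(dm$aggregate, 39.5)

  # a day with no records is omitted, not zero
  skip_day <- tv_series("a", t0 + c(0, 2 * 86400), c(39, 40))
  expect_equal(nrow(daily_max_tv(skip_day)$daily), 2)
  expect_equal(daily_max_tv(skip_day)$aggregate, 39.5)
})

test_that("heat-stress duration counts on-grid exceedance runs", {
  cfg <- hs_config()
  vals <- c(39.5, 39.8, 39.9, 39.77, 39.5, 39.6)
  s <- make_series(vals)  # three consecutive exceedances of 39.76
  expect_equal(hs_duration(s, cfg)$daily$hsd_min, 30)

  s_none <- make_series(rep(39.0, 6))
  expect_equal(hs_duration(s_none, cfg)$daily$hsd_min, 0)

  s_all <- make_series(rep(40, 144))
  expect_equal(hs_duration(s_all, cfg)$daily$hsd_min, 1440)

  # natural ventilation uses the higher threshold
  s_nat <- make_series(c(39.77, 39.77, 39.77, 39, 39, 39),
                       ventilation = "natural")
  expect_equal(hs_duration(s_nat, cfg)$daily$hsd_min, 0)

  # minimum run length filters isolated spikes
  cfg2 <- hs_config(min_run_length = 2)
  s_spike <- make_series(c(39, 40, 39, 40, 40, 39))
  expect_equal(hs_duration(s_spike, cfg2)$daily$hsd_min, 20)

  # oracle comparison on random series with gaps
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(10:80, 1)
    vals <- 39.76 + rnorm(n, 0, 0.1)
    gaps <- if (runif(1) < 0.5) sample(n - 1, 2) else integer(0)
    s <- make_series(vals, gaps_after = gaps)
    got <- hs_duration(s, cfg)$daily$hsd_min
    ora <- naive_hsd_daily(vals, minutes_of(s), 39.76)
    expect_equal(got, ora)
  }
})

test_that("heat-stress units have the documented signs and sums", {
  thr <- 39.76
  s <- make_series(thr + c(0.1, 0.2, -0.3))
  hsu <- heat_stress_units(s)
  expect_equal(hsu$HSU_A, 0.3)
  expect_equal(hsu$HSU_B, -0.3)

  below <- make_series(rep(39, 5))
  expect_equal(heat_stress_units(below)$HSU_A, 0)

  # shifting every value up weakly increases both sums
  up <- make_series(thr + c(0.1, 0.2, -0.3) + 0.05)
  hsu_up <- heat_stress_units(up)
  expect_gte(hsu_up$HSU_A, hsu$HSU_A)
  expect_gte(hsu_up$HSU_B, hsu$HSU_B)

  # absolute-value variant
  expect_equal(heat_stress_units(s, hs_config(hsu_b_absolute = TRUE))$HSU_B,
               0.3)

  # order invariance of the sums (oracle comparison)
  set.seed(3)
  vals <- 39.76 + rnorm(50, 0, 0.2)
  ora <- naive_hsu(vals, thr)
  got <- heat_stress_units(make_series(vals))
  expect_equal(got$HSU_A, unname(ora["HSU_A"]))
  expect_equal(got$HSU_B, unname(ora["HSU_B"]))
  expect_equal(got$HSU_A - abs(got$HSU_B),
               sum(vals - thr), tolerance = 1e-10)
})

test_that("normalized variance products hit the min-max corners", {
  tab <- data.frame(animal_id = c("a", "b", "c"),
                    med = c(38, 39, 40), ave = c(38, 39, 40),
                    var_tv = c(0.1, 0.2, 0.3))
  nor <- normalized_variance_products(tab)
  expect_equal(nor$Nor_medvar, c(0, 0.25, 1))
  expect_equal(nor$Nor_avevar, c(0, 0.25, 1))

  ora <- naive_nor(tab$med, tab$ave, tab$var_tv)
  expect_equal(nor$Nor_medvar, ora$Nor_medvar)

  expect_error(normalized_variance_products(tab[1, ]), "2 animals")
  tab0 <- tab; tab0$var_tv <- 0.2
  expect_error(normalized_variance_products(tab0), "zero range")
})

test_that("the full indicator table is complete, flagged and order-free", {
  co <- small_cohort(seed = 21, n_animals = 20, n_days = 2)
  phen <- derive_all_indicators(co$tv)
  expect_equal(nrow(phen), 20)
  expect_true(all(cr_indicator_names() %in% names(phen)))
  expect_true(all(phen$Nor_medvar >= 0 & phen$Nor_medvar <= 1))
  expect_true(all(phen$Nor_avevar >= 0 & phen$Nor_avevar <= 1))
  expect_true(all(phen$HSU_A >= 0), all(phen$HSU_B <= 0))
  # non-degenerate between-animal variation for every indicator
  v <- vapply(cr_indicator_names(), function(k) var(phen[[k]]), numeric(1))
  expect_true(all(v > 0))

  # permutation invariance
  perm <- sample(length(co$tv))
  phen2 <- derive_all_indicators(co$tv[perm])
  phen2 <- phen2[match(phen$animal_id, phen2$animal_id), ]
  expect_equal(phen2$LnVar_Ave, phen$LnVar_Ave)
  expect_equal(phen2$Nor_medvar, phen$Nor_medvar)

  # duplicate ids rejected
  expect_error(derive_all_indicators(c(co$tv[1], co$tv[1])), "duplicate")

  # identical series: degenerate population surfaces as an error
  flat <- lapply(1:3, function(i)
    tv_series(paste0("id", i), t0 + 600 * (0:9), rep(39, 10)))
  expect_error(derive_all_indicators(flat), "zero range")
})
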