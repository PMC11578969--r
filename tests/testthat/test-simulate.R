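test_that("genotype simulation respects dosage range, seed determinism and HW frequency", {
  cfg <- sim_config(n_animals = 4, n_chromosomes = 1,
                    snps_per_chromosome = 3, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$dosage), c(4, 3))
  expect_true(all(g$dosage %in% 0:2))
  expect_true(all(diff(g$map$bp) > 0))
  expect_identical(g$dosage, simulate_genotypes(cfg)$dosage)

  # binomial sampling oracle: observed freq within 3 SE of the target
  cfg2 <- sim_config(n_animals = 2000, n_chromosomes = 1,
                     snps_per_chromosome = 1, maf_range = c(0.3, 0.3),
                     seed = 5)
  g2 <- simulate_genotypes(cfg2)
  p_hat <- mean(g2$dosage) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 2000))
  expect_lt(abs(p_hat - 0.3), 3 * se)

  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("latent traits carry the planted architecture", {
  # null architecture: pure noise, no SNP correlation in expectation
  cfg0 <- sim_config(n_animals = 300, n_chromosomes = 1,
                     snps_per_chromosome = 30, polygenic_h2 = 0,
                     n_qtl = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0)
  tr0 <- simulate_latent_traits(g0, cfg0)
  expect_equal(unname(tr0$realized_h2), c(0, 0))
  cors <- abs(cor(g0$dosage, tr0$latent_baseline))
  expect_lt(mean(cors), 3 / sqrt(300))  # null correlations, not signal

  # planted QTL explains its configured variance fraction (exact by
  # construction: components are empirically standardized)
  cfg1 <- sim_config(n_animals = 1000, n_chromosomes = 1,
                     snps_per_chromosome = 50, n_qtl = 1,
                     qtl_variance_fraction = 0.05, polygenic_h2 = 0.2,
                     seed = 3)
  g1 <- simulate_genotypes(cfg1)
  tr1 <- simulate_latent_traits(g1, cfg1)
  qtl <- g1$dosage[, tr1$qtl_snp_ids[1]]
  r2 <- cor(qtl, tr1$latent_baseline)^2
  expect_lt(abs(r2 - 0.05), 0.025)     # Monte-Carlo slack around 5%
  expect_true(all(tr1$qtl_snp_ids %in% g1$map$snp))
  expect_true(all(tr1$realized_h2 >= 0 & tr1$realized_h2 <= 1))
  expect_equal(unname(tr1$realized_h2["baseline"]), 0.25, tolerance = 0.05)

  # determinism
  expect_identical(tr1$latent_baseline,
                   simulate_latent_traits(g1, cfg1)$latent_baseline)

  expect_error(sim_config(n_qtl = 10, qtl_variance_fraction = 0.1,
                          polygenic_h2 = 0.3),
               "environmental variance")
})

test_that("environment has the 5-min grid, diurnal cycle and heat waves", {
  cfg <- sim_config(n_animals = 2, n_days = 1, snps_per_chromosome = 2,
                    n_chromosomes = 1, seed = 4, heatwave_prob = 0)
  env <- simulate_environment(cfg)
  expect_equal(nrow(env), 288)
  expect_true(all(diff(as.numeric(env$timestamp)) == 300))
  expect_true(all(env$relative_humidity >= 0 & env$relative_humidity <= 100))

  # amplitude 0, noise 0 -> constant series
  cfg0 <- sim_config(n_animals = 2, n_days = 1, snps_per_chromosome = 2,
                     n_chromosomes = 1, seed = 4, env_amplitude = 0,
                     env_noise_sd = 0, heatwave_prob = 0)
  env0 <- simulate_environment(cfg0)
  expect_equal(var(env0$ambient_temp), 0)

  # wave days run hotter than quiet days
  cfgw <- sim_config(n_animals = 2, n_days = 12, snps_per_chromosome = 2,
                     n_chromosomes = 1, seed = 6, heatwave_prob = 0.4)
  envw <- simulate_environment(cfgw)
  waves <- attr(envw, "wave_days")
  expect_gt(length(waves), 0)
  day <- as.integer(format(envw$timestamp, "%d"))
  day <- day - min(day) + 1
  dmax <- tapply(envw$ambient_temp, day, max)
  expect_gt(min(dmax[waves]), max(dmax[setdiff(seq_len(12), waves)]))
})

test_that("temperature series follow the generative model", {
  cfg <- sim_config(n_animals = 6, n_chromosomes = 1,
                    snps_per_chromosome = 10, n_days = 2,
                    missing_rate = 0, seed = 8)
  co <- simulate_cohort(cfg)
  expect_s3_class(co$tv[[1]], "tv_series")
  expect_true(all(vapply(co$tv, function(s) length(s$tv), integer(1)) == 288))
  expect_true(all(unlist(lapply(co$tv, `[[`, "tv")) >= 37))
  expect_true(all(unlist(lapply(co$tv, `[[`, "tv")) <= 42.5))

  # degenerate noise: Tv equals the deterministic component, so two
  # animals with equal latent values and parity differ only via genetics
  cfg0 <- sim_config(n_animals = 3, n_chromosomes = 1,
                     snps_per_chromosome = 10, n_days = 1,
                     missing_rate = 0, ar_sd = 0, ar_rho = 0,
                     polygenic_h2 = 0, baseline_sd = 0, sensitivity_sd = 0,
                     parity_effect_sd = 0, seed = 9)
  co0 <- simulate_cohort(cfg0)
  tvs <- vapply(co0$tv, `[[`, numeric(144), "tv")
  expect_equal(tvs[, 1], tvs[, 2])  # identical deterministic paths
  expect_equal(tvs[, 1], tvs[, 3])

  # missingness drops records
  cfgm <- sim_config(n_animals = 4, n_chromosomes = 1,
                     snps_per_chromosome = 10, n_days = 2,
                     missing_rate = 0.3, seed = 10)
  com <- simulate_cohort(cfgm)
  lens <- vapply(com$tv, function(s) length(s$tv), integer(1))
  expect_true(all(lens < 288))

  # mismatched animal sets rejected
  g2 <- simulate_genotypes(sim_config(n_animals = 5, n_chromosomes = 1,
                                      snps_per_chromosome = 10, seed = 12))
  expect_error(simulate_tv_series(g2, co$truth, co$env, cfg), "match")
})

test_that("the whole generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_animals = 5, n_chromosomes = 1,
                    snps_per_chromosome = 8, n_days = 1, seed = 13)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth$latent_heat_sensitivity,
                   b$truth$latent_heat_sensitivity)
  expect_identical(a$env$ambient_temp, b$env$ambient_temp)
  expect_identical(lapply(a$tv, `[[`, "tv"), lapply(b$tv, `[[`, "tv"))
})
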