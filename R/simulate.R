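#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

stage_seed <- function(cfg, offset) {
  (as.numeric(cfg$seed) + offset) %% .Machine$integer.max
}

#' Simulate SNP genotypes under Hardy-Weinberg sampling
#'
#' Draws a dosage matrix (counts of the `B` allele, values in \{0, 1, 2\})
#' for `n_animals` across `n_chromosomes * snps_per_chromosome` loci.
#' Per-SNP allele frequencies are uniform on `maf_range`; genotypes are
#' independent binomial(2, p) draws, so loci carry no linkage
#' disequilibrium. SNPs receive strictly increasing base-pair positions per
#' chromosome. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `genotype_matrix`: list with `dosage` (animals x SNPs integer
#'   matrix, dimnames set), `map` (data.frame: `snp`, `chr`, `bp`, `a1`,
#'   `a2`), `animal_ids`, and `freq` (the generating allele frequencies).
#' @examples
#' g <- simulate_genotypes(sim_config(n_animals = 4, n_chromosomes = 1,
#'                                    snps_per_chromosome = 3, seed = 1))
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n_animals
  m_per <- cfg$snps_per_chromosome
  m <- cfg$n_chromosomes * m_per
  with_seed(stage_seed(cfg, 101), {
    p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    dosage <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)),
                     nrow = n, ncol = m)
    bp <- unlist(lapply(seq_len(cfg$n_chromosomes), function(chr) {
      sort(sample.int(cfg$chromosome_length_bp, m_per))
    }), use.names = FALSE)
    chr <- rep(seq_len(cfg$n_chromosomes), each = m_per)
    snp <- sprintf("snp_%d_%d", chr, bp)
    animal_ids <- sprintf("sow_%04d", seq_len(n))
    dimnames(dosage) <- list(animal_ids, snp)
    structure(list(dosage = dosage,
                   map = data.frame(snp = snp, chr = chr, bp = bp,
                                    a1 = "A", a2 = "B",
                                    stringsAsFactors = FALSE),
                   animal_ids = animal_ids,
                   freq = p),
              class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chr))))
  invisible(x)
}

#' Simulate the latent genetic architecture of the cohort
#'
#' Builds two latent animal-level traits with known genetic architecture:
#' a thermal *baseline* (resting body-temperature offset) and a *heat
#' sensitivity* (gain on ambient heat load). Each trait is the sum of
#' planted-QTL effects, a polygenic term over all remaining SNPs, and
#' environmental noise. Components are empirically standardized so each
#' planted QTL explains exactly `qtl_variance_fraction` of the trait
#' variance, the polygenic term exactly `polygenic_h2`, and the trait has
#' unit variance; the realized heritability is recorded per trait.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param cfg The [sim_config()] used to generate `genotypes`.
#' @return A `truth_record`: list with `qtl_snp_ids`, `qtl_effects`
#'   (QTL x trait matrix of per-standardized-dosage effects),
#'   `latent_baseline`, `latent_heat_sensitivity` (named numeric, unit
#'   variance), `genetic_values` (per trait), and `realized_h2`.
#' @export
simulate_latent_traits <- function(genotypes, cfg) {
  cfg <- validate_sim_config(cfg)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosage)
  m <- ncol(genotypes$dosage)
  genetic_total <- cfg$n_qtl * cfg$qtl_variance_fraction + cfg$polygenic_h2
  if (genetic_total >= 1) stop("genetic variance fractions exceed 1")

  scale_to_var <- function(x, v) {
    if (v == 0 || length(x) < 2) return(rep(0, length(x)))
    s <- stats::sd(x)
    if (s == 0) stop("degenerate component: zero variance before scaling")
    (x - mean(x)) / s * sqrt(v)
  }

  with_seed(stage_seed(cfg, 202), {
    # spread planted QTL across chromosomes round-robin
    qtl_idx <- integer(0)
    if (cfg$n_qtl > 0) {
      per_chr <- split(seq_len(m), genotypes$map$chr)
      take <- rep(seq_along(per_chr), length.out = cfg$n_qtl)
      qtl_idx <- unlist(lapply(seq_along(per_chr), function(c) {
        k <- sum(take == c)
        if (k == 0) integer(0) else sample(per_chr[[c]], k)
      }), use.names = FALSE)
    }
    traits <- c("baseline", "heat_sensitivity")
    Z <- scale(genotypes$dosage)      # column-standardized dosages
    Z[is.na(Z)] <- 0                  # monomorphic columns contribute nothing
    qtl_eff <- matrix(0, nrow = length(qtl_idx), ncol = length(traits),
                      dimnames = list(genotypes$map$snp[qtl_idx], traits))
    latent <- genetic <- matrix(0, nrow = n, ncol = length(traits),
                                dimnames = list(genotypes$animal_ids, traits))
    for (k in seq_along(traits)) {
      g_qtl <- rep(0, n)
      for (j in seq_along(qtl_idx)) {
        sgn <- sample(c(-1, 1), 1)
        w <- sgn * sqrt(cfg$qtl_variance_fraction)
        qtl_eff[j, k] <- w
        g_qtl <- g_qtl + w * Z[, qtl_idx[j]]
      }
      poly_idx <- setdiff(seq_len(m), qtl_idx)
      g_poly <- scale_to_var(Z[, poly_idx, drop = FALSE] %*%
                               stats::rnorm(length(poly_idx)),
                             cfg$polygenic_h2)
      e <- scale_to_var(stats::rnorm(n), 1 - genetic_total)
      genetic[, k] <- g_qtl + g_poly
      latent[, k] <- genetic[, k] + e
    }
    realized_h2 <- vapply(seq_along(traits), function(k) {
      tv <- stats::var(latent[, k])
      if (tv == 0) 0 else stats::var(genetic[, k]) / tv
    }, numeric(1))
    names(realized_h2) <- traits
    structure(list(qtl_snp_ids = genotypes$map$snp[qtl_idx],
                   qtl_effects = qtl_eff,
                   latent_baseline = latent[, "baseline"],
                   latent_heat_sensitivity = latent[, "heat_sensitivity"],
                   genetic_values = genetic,
                   realized_h2 = realized_h2),
              class = "truth_record")
  })
}

#' Simulate barn ambient conditions
#'
#' Ambient temperature on a regular grid at `env_interval_min` minutes:
#' a sinusoidal diurnal cycle peaking mid-afternoon (15:00), day-scale
#' heat-wave episodes (each wave day adds `heatwave_boost` deg C), and
#' Gaussian noise. Relative humidity moves inversely with the temperature
#' anomaly and is clipped to [0, 100].
#'
#' @param cfg A [sim_config()].
#' @return An `environment_series` data.frame with columns `timestamp`
#'   (POSIXct, UTC), `ambient_temp`, `relative_humidity`; heat-wave day
#'   indices are stored in `attr(, "wave_days")`.
#' @export
simulate_environment <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  with_seed(stage_seed(cfg, 303), {
    step <- cfg$env_interval_min
    minutes <- seq(0, cfg$n_days * 1440 - step, by = step)
    origin <- as.POSIXct("2021-06-05 00:00:00", tz = "UTC")
    ts <- origin + minutes * 60
    hour <- (minutes / 60) %% 24
    day <- minutes %/% 1440 + 1
    # scheduled episodes: a fixed fraction of days, at random positions,
    # so heat-stress exposure does not swing between replicate cohorts
    n_wave <- round(cfg$heatwave_prob * cfg$n_days)
    wave_days <- if (n_wave > 0) sort(sample.int(cfg$n_days, n_wave))
                 else integer(0)
    temp <- cfg$env_base_temp +
      cfg$env_amplitude * cos(2 * pi * (hour - 15) / 24) +
      ifelse(day %in% wave_days, cfg$heatwave_boost, 0) +
      stats::rnorm(length(minutes), sd = cfg$env_noise_sd)
    rh <- pmin(100, pmax(0, 70 - 1.5 * (temp - cfg$env_base_temp) +
                           stats::rnorm(length(minutes), sd = 3)))
    structure(data.frame(timestamp = ts, ambient_temp = temp,
                         relative_humidity = rh),
              wave_days = wave_days,
              class = c("environment_series", "data.frame"))
  })
}

#' Heat load experienced at given ambient temperatures
#'
#' Nonnegative thermal-stress transform of ambient temperature: degrees
#' above the comfort temperature, zero below it.
#'
#' @param ambient_temp Numeric, deg C.
#' @param comfort_temp Comfort temperature, deg C (default 25).
#' @return Numeric vector of the same length.
#' @export
heat_load <- function(ambient_temp, comfort_temp = 25) {
  pmax(0, ambient_temp - comfort_temp)
}

#' Simulate vaginal-temperature series for the cohort
#'
#' For each animal, vaginal temperature on a 10-minute grid is the sum of
#' the population mean, a parity effect, a circadian cycle, the animal's
#' latent thermal baseline, its latent heat sensitivity times the current
#' heat load, and AR(1) sensor noise. Records are then dropped completely
#' at random at `missing_rate`, values are clipped to the physiological
#' band [37, 42.5] deg C (clip count retained), and each animal is assigned
#' a ventilation class and a barn.
#'
#' @param genotypes A `genotype_matrix` (defines the animal set).
#' @param truth A `truth_record` from [simulate_latent_traits()].
#' @param env An `environment_series` from [simulate_environment()].
#' @param cfg The shared [sim_config()].
#' @return A `tv_cohort`: named list of `tv_series` objects (one per
#'   animal; fields `animal_id`, `timestamps`, `tv`, `ventilation`,
#'   `parity`, `barn_id`), with attributes `covariates` (data.frame) and
#'   `n_clipped`.
#' @export
simulate_tv_series <- function(genotypes, truth, env, cfg) {
  cfg <- validate_sim_config(cfg)
  ids <- genotypes$animal_ids
  if (!identical(ids, names(truth$latent_baseline))) {
    stop("animal sets of genotypes and truth record do not match")
  }
  with_seed(stage_seed(cfg, 404), {
    n <- length(ids)
    step <- cfg$sampling_interval_min
    minutes <- seq(0, cfg$n_days * 1440 - step, by = step)
    origin <- as.POSIXct("2021-06-05 00:00:00", tz = "UTC")
    ts_grid <- origin + minutes * 60
    # heat load on the Tv grid, read from the nearest (last) ambient record
    env_min <- as.numeric(difftime(env$timestamp, origin, units = "mins"))
    idx <- findInterval(minutes, env_min)
    idx[idx < 1] <- 1
    hl <- heat_load(env$ambient_temp[idx], cfg$comfort_temp)
    circ <- cfg$tv_circadian_amp * cos(2 * pi * ((minutes / 60) %% 24 - 16) / 24)

    n_mech <- round(cfg$ventilation_split * n)
    ventilation <- sample(rep(c("mechanical", "natural"),
                              c(n_mech, n - n_mech)))
    parity <- sample(cfg$parity_levels, n, replace = TRUE)
    parity_eff <- stats::rnorm(length(cfg$parity_levels),
                               sd = cfg$parity_effect_sd)
    names(parity_eff) <- as.character(cfg$parity_levels)
    barn <- ifelse(ventilation == "mechanical", "barn_M", "barn_N")

    baseline <- truth$latent_baseline * cfg$baseline_sd
    lhs <- truth$latent_heat_sensitivity
    sens <- cfg$sensitivity_mean + lhs * cfg$sensitivity_sd
    # low-resilience animals (high latent sensitivity) also run noisier,
    # more autocorrelated residuals -- the signal the deviation-based
    # indicators are designed to pick up
    sd_i <- cfg$ar_sd * pmax(0.2, 1 + cfg$ar_sd_gain * lhs)
    rho_i <- pmin(0.92, pmax(0, cfg$ar_rho + cfg$ar_rho_gain * lhs))
    skew_i <- pmax(0.05, cfg$noise_skew + cfg$noise_skew_gain * lhs)

    n_clipped <- 0L
    cohort <- vector("list", n)
    T_ <- length(minutes)
    for (i in seq_len(n)) {
      det <- cfg$tv_mu + parity_eff[as.character(parity[i])] + circ +
        baseline[i] + sens[i] * hl
      if (cfg$ar_sd > 0) {
        # stationary AR(1): x_t = rho x_{t-1} + eps_t, sd(x) = sd_i.
        # Right-skewed innovations (standardized gamma with skewness
        # 2/sqrt(shape)) mimic spiky temperature excursions.
        innov_sd <- sd_i[i] * sqrt(1 - rho_i[i]^2)
        if (cfg$noise_skew > 0) {
          shape <- (2 / skew_i[i])^2
          eps <- (stats::rgamma(T_, shape = shape) - shape) / sqrt(shape) *
            innov_sd
        } else {
          eps <- stats::rnorm(T_, sd = innov_sd)
        }
        x0 <- stats::rnorm(1, sd = sd_i[i])
        noise <- as.numeric(stats::filter(eps, rho_i[i],
                                          method = "recursive", init = x0))
      } else {
        noise <- rep(0, T_)
      }
      tv <- det + noise
      clip <- tv < 37 | tv > 42.5
      n_clipped <- n_clipped + sum(clip)
      tv <- pmin(42.5, pmax(37, tv))
      keep <- if (cfg$missing_rate > 0) {
        stats::runif(T_) >= cfg$missing_rate
      } else rep(TRUE, T_)
      cohort[[i]] <- tv_series(animal_id = ids[i],
                               timestamps = ts_grid[keep],
                               tv = tv[keep],
                               ventilation = ventilation[i],
                               parity = parity[i],
                               barn_id = barn[i])
    }
    names(cohort) <- ids
    covariates <- data.frame(animal_id = ids, ventilation = ventilation,
                             parity = parity, barn = barn,
                             stringsAsFactors = FALSE)
    if (n_clipped > 0) {
      message(sprintf("simulate_tv_series: clipped %d record(s) to [37, 42.5] degC",
                      n_clipped))
    }
    structure(cohort, covariates = covariates, n_clipped = n_clipped,
              class = "tv_cohort")
  })
}

#' Construct a single-animal vaginal-temperature series
#'
#' @param animal_id Identifier.
#' @param timestamps POSIXct, strictly increasing.
#' @param tv Numeric temperatures (deg C), same length as `timestamps`.
#' @param ventilation `"mechanical"` or `"natural"`.
#' @param parity Integer parity.
#' @param barn_id Barn identifier.
#' @return A `tv_series` object.
#' @export
tv_series <- function(animal_id, timestamps, tv,
                      ventilation = c("mechanical", "natural"),
                      parity = NA_integer_, barn_id = NA_character_) {
  ventilation <- match.arg(ventilation)
  stopifnot(length(timestamps) == length(tv))
  if (length(timestamps) > 1 && any(diff(as.numeric(timestamps)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (any(!is.finite(tv))) stop("tv must be finite where present")
  structure(list(animal_id = animal_id,
                 timestamps = as.POSIXct(timestamps, tz = "UTC"),
                 tv = as.numeric(tv),
                 ventilation = ventilation,
                 parity = as.integer(parity),
                 barn_id = barn_id),
            class = "tv_series")
}

#' @export
print.tv_series <- function(x, ...) {
  cat(sprintf("<tv_series> %s: %d records (%s ventilation, parity %s)\n",
              x$animal_id, length(x$tv), x$ventilation, x$parity))
  invisible(x)
}

#' Simulate a complete cohort in one call
#'
#' Runs genotype, latent-trait, environment and temperature-series
#' simulation with one shared configuration and seed lineage.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes`, `truth`, `env`, `tv` (a `tv_cohort`) and
#'   `covariates`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  genotypes <- simulate_genotypes(cfg)
  truth <- simulate_latent_traits(genotypes, cfg)
  env <- simulate_environment(cfg)
  tv <- simulate_tv_series(genotypes, truth, env, cfg)
  list(genotypes = genotypes, truth = truth, env = env, tv = tv,
       covariates = attr(tv, "covariates"))
}
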