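#' Simulation configuration for the synthetic sow cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort size, genome
#' layout, genetic architecture of the two latent animal traits (thermal
#' baseline and heat sensitivity), barn environment, vaginal-temperature
#' sampling, and missingness. Defaults emulate the study design the package
#' targets: ~8 weeks of 10-minute vaginal-temperature records, ambient
#' conditions on a 5-minute grid, two ventilation classes, parities 2-7,
#' and indicator heritabilities in the low-to-moderate range reported for
#' climatic-resilience traits, at a genome scale (5 chromosomes x 600 SNPs,
#' 400 animals, 14 days) that keeps a full pipeline run in minutes.
#'
#' @param n_animals Number of sows in the cohort.
#' @param n_chromosomes Number of autosomes to simulate.
#' @param snps_per_chromosome SNPs per chromosome (independent loci,
#'   Hardy-Weinberg sampling; no LD is simulated).
#' @param maf_range Length-2 numeric, allele-frequency range in (0, 0.5]
#'   from which per-SNP minor-allele frequencies are drawn uniformly.
#' @param n_qtl Number of planted QTL shared by both latent traits.
#' @param qtl_variance_fraction Fraction of each latent trait's variance
#'   explained by each planted QTL.
#' @param polygenic_h2 Fraction of each latent trait's variance explained by
#'   the polygenic background (all non-QTL SNPs with small normal weights).
#'   Total genetic fraction is `n_qtl * qtl_variance_fraction + polygenic_h2`
#'   and must leave positive environmental variance.
#' @param n_days Length of the recording period in days.
#' @param sampling_interval_min Vaginal-temperature sampling interval (min).
#' @param env_interval_min Ambient-condition sampling interval (min).
#' @param ventilation_split Proportion of animals housed under mechanical
#'   (vs natural) ventilation.
#' @param parity_levels Integer vector of parities sampled uniformly per
#'   animal (default 2:7).
#' @param missing_rate Proportion of vaginal-temperature records dropped
#'   completely at random (the grid keeps holes; nothing is imputed).
#' @param chromosome_length_bp Physical length per chromosome used when
#'   placing SNPs (bp).
#' @param comfort_temp Ambient comfort temperature (deg C); heat load is
#'   `max(0, ambient - comfort_temp)`.
#' @param env_base_temp,env_amplitude,env_noise_sd Mean level, diurnal
#'   half-amplitude and noise sd of the ambient-temperature cycle (deg C).
#' @param heatwave_prob Probability that a day belongs to a heat-wave
#'   episode (each wave day adds `heatwave_boost` deg C).
#' @param heatwave_boost Ambient uplift on heat-wave days (deg C).
#' @param tv_mu Population mean vaginal temperature (deg C).
#' @param tv_circadian_amp Half-amplitude of the circadian vaginal-
#'   temperature cycle (deg C).
#' @param baseline_sd Between-animal sd of the thermal baseline (deg C).
#' @param sensitivity_mean,sensitivity_sd Mean and between-animal sd of the
#'   heat-sensitivity gain (deg C of body temperature per deg C of heat load).
#' @param ar_rho,ar_sd Population AR(1) coefficient and stationary sd
#'   (deg C) of the sensor residuals; defaults (0.6, 0.15) keep lag-1
#'   autocorrelation indicators non-degenerate.
#' @param ar_sd_gain,ar_rho_gain Per-animal modulation of the residual sd
#'   and AR coefficient by the latent heat-sensitivity trait. Animals with
#'   low resilience (high sensitivity) run noisier, more autocorrelated
#'   temperature residuals, which is exactly the variability the
#'   deviation-based indicators quantify; these gains give the
#'   log-variance, autocorrelation and skewness indicators heritable
#'   variation in the low-to-moderate range reported for such traits.
#' @param noise_skew,noise_skew_gain Skewness of the AR(1) innovations
#'   (standardized-gamma draws; 0 means Gaussian) and its per-animal
#'   modulation by latent heat sensitivity. Body-temperature excursions
#'   are right-skewed spikes, and animals differ in how spiky they run;
#'   this is what makes the skewness indicators heritable.
#' @param parity_effect_sd Between-parity-class sd of the fixed parity
#'   effect on vaginal temperature (deg C).
#' @param seed Integer seed; every stochastic stage is deterministic given
#'   the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_animals = 8, n_chromosomes = 1,
#'                   snps_per_chromosome = 20, n_days = 2, seed = 1)
#' @export
sim_config <- function(n_animals = 400,
                       n_chromosomes = 5,
                       snps_per_chromosome = 600,
                       maf_range = c(0.05, 0.45),
                       n_qtl = 0,
                       qtl_variance_fraction = 0.05,
                       polygenic_h2 = 0.25,
                       n_days = 14,
                       sampling_interval_min = 10,
                       env_interval_min = 5,
                       ventilation_split = 0.5,
                       parity_levels = 2:7,
                       missing_rate = 0.02,
                       chromosome_length_bp = 120e6,
                       comfort_temp = 25,
                       env_base_temp = 24,
                       env_amplitude = 6,
                       env_noise_sd = 1,
                       heatwave_prob = 0.25,
                       heatwave_boost = 6,
                       tv_mu = 38.6,
                       tv_circadian_amp = 0.25,
                       baseline_sd = 0.25,
                       sensitivity_mean = 0.08,
                       sensitivity_sd = 0.04,
                       ar_rho = 0.6,
                       ar_sd = 0.15,
                       ar_sd_gain = 0.25,
                       ar_rho_gain = 0.15,
                       noise_skew = 0.6,
                       noise_skew_gain = 0.45,
                       parity_effect_sd = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_animals = as.integer(n_animals),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    maf_range = as.numeric(maf_range),
    n_qtl = as.integer(n_qtl),
    qtl_variance_fraction = qtl_variance_fraction,
    polygenic_h2 = polygenic_h2,
    n_days = as.integer(n_days),
    sampling_interval_min = sampling_interval_min,
    env_interval_min = env_interval_min,
    ventilation_split = ventilation_split,
    parity_levels = as.integer(parity_levels),
    missing_rate = missing_rate,
    chromosome_length_bp = chromosome_length_bp,
    comfort_temp = comfort_temp,
    env_base_temp = env_base_temp,
    env_amplitude = env_amplitude,
    env_noise_sd = env_noise_sd,
    heatwave_prob = heatwave_prob,
    heatwave_boost = heatwave_boost,
    tv_mu = tv_mu,
    tv_circadian_amp = tv_circadian_amp,
    baseline_sd = baseline_sd,
    sensitivity_mean = sensitivity_mean,
    sensitivity_sd = sensitivity_sd,
    ar_rho = ar_rho,
    ar_sd = ar_sd,
    ar_sd_gain = ar_sd_gain,
    ar_rho_gain = ar_rho_gain,
    noise_skew = noise_skew,
    noise_skew_gain = noise_skew_gain,
    parity_effect_sd = parity_effect_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_animals >= 1, cfg$n_chromosomes >= 1,
            cfg$snps_per_chromosome >= 1, cfg$n_days >= 1)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be an increasing pair inside (0, 0.5]")
  }
  props <- c(ventilation_split = cfg$ventilation_split,
             missing_rate = cfg$missing_rate,
             qtl_variance_fraction = cfg$qtl_variance_fraction,
             heatwave_prob = cfg$heatwave_prob)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  if (cfg$polygenic_h2 < 0 || cfg$polygenic_h2 >= 1) {
    stop("polygenic_h2 must lie in [0, 1)")
  }
  genetic_total <- cfg$n_qtl * cfg$qtl_variance_fraction + cfg$polygenic_h2
  if (genetic_total >= 1) {
    stop("n_qtl * qtl_variance_fraction + polygenic_h2 = ",
         signif(genetic_total, 4),
         " leaves no positive environmental variance")
  }
  if (cfg$n_qtl > cfg$n_chromosomes * cfg$snps_per_chromosome) {
    stop("more QTL requested than simulated SNPs")
  }
  if (cfg$n_qtl > 0 &&
      ceiling(cfg$n_qtl / cfg$n_chromosomes) > cfg$snps_per_chromosome) {
    stop("snps_per_chromosome too small for the requested QTL layout")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d animals, %d parity classes, %.0f%% mechanical ventilation\n",
              x$n_animals, length(x$parity_levels), 100 * x$ventilation_split))
  cat(sprintf("  genome: %d chromosomes x %d SNPs, MAF in [%.2f, %.2f]\n",
              x$n_chromosomes, x$snps_per_chromosome,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  genetics: %d QTL x %.3f + polygenic h2 %.2f\n",
              x$n_qtl, x$qtl_variance_fraction, x$polygenic_h2))
  cat(sprintf("  recording: %d days at %g-min Tv / %g-min ambient sampling, %.0f%% missing\n",
              x$n_days, x$sampling_interval_min, x$env_interval_min,
              100 * x$missing_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Heat-stress threshold configuration
#'
#' Holds the ventilation-class-specific vaginal-temperature thresholds above
#' which a sow is considered heat-stressed, together with the moving-window
#' geometry used for the deviation-based indicators. The default thresholds
#' (39.76 deg C under mechanical and 39.78 deg C under natural ventilation)
#' are the published estimates for lactating sows; they are inputs here, not
#' re-estimated.
#'
#' @param threshold_mechanical Threshold for mechanically ventilated barns
#'   (deg C).
#' @param threshold_natural Threshold for naturally ventilated barns (deg C).
#' @param window_length Number of consecutive observations per moving window.
#' @param interval Nominal sampling interval of the series (minutes).
#' @param interval_tol Tolerance (minutes) when deciding whether two
#'   consecutive timestamps sit on the nominal grid; windows or lag pairs
#'   spanning a larger gap are split.
#' @param min_run_length Minimum number of consecutive above-threshold
#'   observations for a run to count towards heat-stress duration.
#' @param aggregate How daily maximum temperature and daily heat-stress
#'   duration are collapsed to one value per animal: `"mean"` (default),
#'   `"median"` or `"max"` over recorded days.
#' @param hsu_b_absolute If `TRUE`, report the below-threshold heat-stress
#'   units as an absolute value instead of the raw (non-positive) signed sum.
#'
#' @return An object of class `hs_config`.
#' @examples
#' hs_config()
#' @export
hs_config <- function(threshold_mechanical = 39.76,
                      threshold_natural = 39.78,
                      window_length = 6,
                      interval = 10,
                      interval_tol = 2,
                      min_run_length = 1,
                      aggregate = c("mean", "median", "max"),
                      hsu_b_absolute = FALSE) {
  aggregate <- match.arg(aggregate)
  stopifnot(threshold_mechanical > 35, threshold_mechanical < 45,
            threshold_natural > 35, threshold_natural < 45,
            window_length >= 2, interval > 0, interval_tol >= 0,
            min_run_length >= 1)
  structure(list(threshold_mechanical = threshold_mechanical,
                 threshold_natural = threshold_natural,
                 window_length = as.integer(window_length),
                 interval = interval,
                 interval_tol = interval_tol,
                 min_run_length = as.integer(min_run_length),
                 aggregate = aggregate,
                 hsu_b_absolute = hsu_b_absolute),
            class = "hs_config")
}

hs_threshold_for <- function(cfg, ventilation) {
  ifelse(ventilation == "mechanical",
         cfg$threshold_mechanical, cfg$threshold_natural)
}
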