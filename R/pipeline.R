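#' Assemble a pipeline configuration
#'
#' One structured configuration tree drives the whole pipeline; every
#' stage can also be called standalone through the package functions.
#' Can be loaded from a YAML file with [read_pipeline_config()].
#'
#' @param sim A [sim_config()] (or list of its arguments) for the
#'   simulation stage; set `simulate = FALSE` to read inputs from files
#'   instead.
#' @param hs An [hs_config()] (or list of its arguments).
#' @param simulate Whether to generate the cohort (default) or read
#'   `plink_prefix` / `tv_path` / `cov_path`.
#' @param plink_prefix,tv_path,cov_path Input paths when `simulate` is
#'   `FALSE`.
#' @param fixed_effects Covariate columns entering the fixed-effects
#'   design (default parity + ventilation).
#' @param maf_min MAF filter for tested SNPs.
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters
#'   (defaults 50, 5, 0.1).
#' @param Ne Effective population size for the chromosome-wise threshold.
#' @param gene_gff3,qtl_file Optional annotation inputs; when absent the
#'   annotation stage is skipped with a log notice.
#' @param flank Annotation window half-width in bp.
#' @param indicators Indicator columns to scan (default: all twelve).
#' @param seed Seed forwarded to the simulation stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), hs = hs_config(),
                            simulate = TRUE,
                            plink_prefix = NULL, tv_path = NULL,
                            cov_path = NULL,
                            fixed_effects = c("parity", "ventilation"),
                            maf_min = 0.01,
                            prune_window = 50, prune_step = 5,
                            prune_r2 = 0.1, Ne = 60,
                            gene_gff3 = NULL, qtl_file = NULL,
                            flank = 500000,
                            indicators = cr_indicator_names(),
                            seed = NULL) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, as.list(sim))
  if (!inherits(hs, "hs_config")) hs <- do.call(hs_config, as.list(hs))
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, hs = hs, simulate = simulate,
                 plink_prefix = plink_prefix, tv_path = tv_path,
                 cov_path = cov_path, fixed_effects = fixed_effects,
                 maf_min = maf_min, prune_window = prune_window,
                 prune_step = prune_step, prune_r2 = prune_r2, Ne = Ne,
                 gene_gff3 = gene_gff3, qtl_file = qtl_file, flank = flank,
                 indicators = indicators),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with top-level keys matching the
#'   `pipeline_config()` arguments (`sim` and `hs` as nested maps).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

log_stage <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes: simulate (or load) -> derive the twelve resilience
#' indicators -> LD-prune, build leave-one-chromosome-out GRMs, fit REML
#' null models and scan every indicator -> thresholds, genomic inflation
#' and Q-Q coordinates -> positional annotation (when feature files are
#' configured). All tables are written as TSV under `out_dir` together
#' with a JSON manifest (package version, seed, configuration hash,
#' per-stage row counts). A rerun with the same configuration and seed
#' reproduces every output.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`phenotypes`,
#'   `assoc` per indicator, `thresholds`, `lambda`, `annotation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage 1: inputs -------------------------------------------------
  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(config$sim)
    genotypes <- cohort$genotypes
    tv <- cohort$tv
    write_plink_text(genotypes, file.path(out_dir, "genotypes"))
    write_tv_tsv(tv, file.path(out_dir, "tv_series.tsv"),
                 file.path(out_dir, "covariates.tsv"))
    write_truth_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
    write_environment_tsv(cohort$env, file.path(out_dir, "environment.tsv"))
    log_stage("simulate: %d animals, %d SNPs, %d Tv records",
              length(tv), ncol(genotypes$dosage),
              sum(vapply(tv, function(s) length(s$tv), integer(1))))
  } else {
    if (is.null(config$plink_prefix) || is.null(config$tv_path) ||
        is.null(config$cov_path)) {
      stop("simulate = FALSE requires plink_prefix, tv_path and cov_path")
    }
    genotypes <- read_plink_text(paste0(config$plink_prefix, ".map"),
                                 paste0(config$plink_prefix, ".ped"))
    tv <- read_tv_tsv(config$tv_path, config$cov_path)
    log_stage("load: %d animals, %d SNPs", length(tv),
              ncol(genotypes$dosage))
  }

  # --- stage 2: phenotyping -------------------------------------------
  phen <- derive_all_indicators(tv, config$hs)
  write_table_tsv(phen, file.path(out_dir, "cr_phenotypes.tsv"))
  log_stage("phenotype: %d animals x %d indicators", nrow(phen),
            length(cr_indicator_names()))

  # --- stage 3: GWAS ---------------------------------------------------
  pruned <- ld_prune(genotypes, config$prune_window, config$prune_step,
                     config$prune_r2)
  thr <- threshold_set(length(pruned),
                       chromosome_lengths_cM(genotypes$map), config$Ne)
  write_table_tsv(data.frame(scheme = c("bonferroni", "suggestive"),
                             threshold = c(thr$bonferroni, thr$suggestive),
                             n_independent_snps = thr$n_independent_snps),
                  file.path(out_dir, "thresholds_genomewide.tsv"))
  write_table_tsv(thr$Me, file.path(out_dir, "thresholds_chromosome_wise.tsv"))
  log_stage("ld_prune: %d of %d SNPs retained", length(pruned),
            ncol(genotypes$dosage))

  indicators <- intersect(config$indicators, names(phen))
  complete <- stats::complete.cases(phen[, indicators, drop = FALSE])
  ids <- phen$animal_id[complete]
  if (length(ids) < length(tv)) {
    log_stage("gwas: dropping %d animal(s) with missing indicators",
              length(tv) - length(ids))
  }
  gsub_ <- subset_animals(genotypes, ids)
  X <- build_design(attr(tv, "covariates"), config$fixed_effects, ids)
  grms <- lapply(unique(gsub_$map$chr), function(c_)
    compute_grm(gsub_, exclude_chromosome = c_))
  names(grms) <- as.character(unique(gsub_$map$chr))

  assoc <- list()
  lam <- list()
  for (ind in indicators) {
    y <- phen[[ind]][match(ids, phen$animal_id)]
    res <- mlma_loco_scan(y, X, gsub_, grms = grms,
                          maf_min = config$maf_min)
    res <- classify_hits(res, thr)
    infl <- genomic_inflation(res$chi2[is.finite(res$chi2)])
    assoc[[ind]] <- res
    lam[[ind]] <- data.frame(indicator = ind, lambda = infl$lambda,
                             ci_low = infl$ci95[1], ci_high = infl$ci95[2],
                             n_tests = infl$n)
    write_table_tsv(res, file.path(out_dir, sprintf("assoc_%s.tsv", ind)))
    write_table_tsv(qq_table(res$p[is.finite(res$p)]),
                    file.path(out_dir, sprintf("qq_%s.tsv", ind)))
    log_stage("gwas[%s]: %d SNPs tested, lambda = %.3f", ind,
              sum(is.finite(res$p)), infl$lambda)
  }
  lambda_tab <- do.call(rbind, lam)
  write_table_tsv(lambda_tab, file.path(out_dir, "lambda.tsv"))

  # --- stage 4: annotation --------------------------------------------
  annotation <- NULL
  sig <- do.call(rbind, lapply(names(assoc), function(ind) {
    a <- assoc[[ind]]
    a <- a[a$sig_suggestive, c("snp", "chr", "bp"), drop = FALSE]
    if (nrow(a) > 0) a$indicator <- ind
    a
  }))
  if (is.null(config$gene_gff3) && is.null(config$qtl_file)) {
    log_stage("annotate: no feature files configured, stage skipped")
  } else if (is.null(sig) || nrow(sig) == 0) {
    log_stage("annotate: no SNP reached the suggestive threshold")
  } else {
    sig <- sig[!duplicated(sig$snp), , drop = FALSE]
    annotation <- list()
    if (!is.null(config$gene_gff3)) {
      genes <- read_gene_gff3(config$gene_gff3)
      gh <- window_lookup(sig, genes, config$flank, "gene")
      write_table_tsv(gh, file.path(out_dir, "gene_hits.tsv"))
      annotation$gene_hits <- gh
      log_stage("annotate: %d gene hit(s)", nrow(gh))
    }
    if (!is.null(config$qtl_file)) {
      qtls <- read_qtl_table(config$qtl_file)
      qh <- window_lookup(sig, qtls, config$flank, "qtl")
      qs <- qtl_type_summary(qh)
      write_table_tsv(qh, file.path(out_dir, "qtl_hits.tsv"))
      write_table_tsv(qs, file.path(out_dir, "qtl_type_summary.tsv"))
      annotation$qtl_hits <- qh
      annotation$qtl_summary <- qs
      if (nrow(qh) > 0) {
        annotation$qtl_enrichment <-
          hypergeometric_qtl_enrichment(qh, qtls)
        write_table_tsv(annotation$qtl_enrichment,
                        file.path(out_dir, "qtl_enrichment.tsv"))
      }
      log_stage("annotate: %d QTL hit(s)", nrow(qh))
    }
  }

  # --- manifest --------------------------------------------------------
  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  cfg_plain$hs <- unclass(cfg_plain$hs)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "crgwas",
    package_version = as.character(utils::packageVersion("crgwas")),
    r_version = R.version.string,
    seed = config$sim$seed,
    config_hash = config_hash(cfg_json),
    n_animals = length(ids),
    n_snps = ncol(genotypes$dosage),
    n_pruned = length(pruned),
    indicator_scans = names(assoc),
    n_indicator_scans = length(assoc),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(phenotypes = phen, assoc = assoc, thresholds = thr,
                 lambda = lambda_tab, pruned = pruned,
                 annotation = annotation, manifest = manifest))
}

# small stable polynomial hash so reruns are comparable without extra deps
config_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Restrict a genotype matrix to a subset of animals
#'
#' @param genotypes A `genotype_matrix`.
#' @param animal_ids Ids to keep, in the desired order.
#' @return A `genotype_matrix` on the subset.
#' @export
subset_animals <- function(genotypes, animal_ids) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(animal_ids, genotypes$animal_ids)
  if (anyNA(idx)) stop("unknown animal id(s)")
  structure(list(dosage = genotypes$dosage[idx, , drop = FALSE],
                 map = genotypes$map,
                 animal_ids = genotypes$animal_ids[idx],
                 freq = colMeans(genotypes$dosage[idx, , drop = FALSE],
                                 na.rm = TRUE) / 2),
            class = "genotype_matrix")
}
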