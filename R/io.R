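#' Write genotypes as PLINK text MAP/PED
#'
#' MAP columns: chromosome, SNP id, genetic position (cM, taken as
#' bp / 1e6), physical position (bp). PED: animal id as family and
#' individual id, zeroed parents/sex, phenotype -9, then two allele
#' columns per SNP coded A/B (dosage counts of B); missing dosage is
#' written `0 0`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param prefix Output path prefix; writes `<prefix>.map` and
#'   `<prefix>.ped`.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  map <- genotypes$map
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(map$chr, map$snp, map$bp / 1e6, map$bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  pair <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  dos <- genotypes$dosage
  lines <- vapply(seq_len(nrow(dos)), function(i) {
    g <- pair[as.character(dos[i, ])]
    g[is.na(g)] <- "0 0"
    paste(genotypes$animal_ids[i], genotypes$animal_ids[i],
          0, 0, 0, -9, paste(g, collapse = " "))
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(map = map_path, ped = ped_path))
}

#' Read PLINK text MAP/PED into a genotype matrix
#'
#' Allele pairs are converted to dosages of the minor allele (the less
#' frequent observed allele per SNP; frequency ties break to the
#' lexicographically later allele name, so A/B coding round-trips).
#' `0 0` genotypes become missing (`NA`); imputation happens only inside
#' the association stage, never at read time.
#'
#' @param map_path,ped_path Paths to whitespace-delimited MAP and PED.
#' @return A `genotype_matrix` (with `NA` for missing dosages).
#' @export
read_plink_text <- function(map_path, ped_path) {
  map_raw <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4) stop("MAP file needs 4 columns")
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * m
  bad <- which(lengths(parts) != want)
  if (length(bad) > 0) {
    stop(sprintf("PED line %d has %d fields, expected %d (6 + 2 x %d SNPs)",
                 bad[1], lengths(parts)[bad[1]], want, m))
  }
  n <- length(parts)
  M <- matrix(unlist(parts), nrow = n, byrow = TRUE)
  animal_ids <- M[, 2]
  a1 <- M[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- M[, 6 + 2 * seq_len(m), drop = FALSE]
  dosage <- matrix(NA_integer_, n, m,
                   dimnames = list(animal_ids, map_raw[[2]]))
  alleles <- matrix("B", m, 2)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    ok <- obs != "0"
    tab <- sort(table(obs[ok]))
    if (length(tab) == 0) next
    if (length(tab) == 1) {
      major <- names(tab)[1]          # monomorphic: minor allele unobserved
      minor <- "<none>"
    } else {
      cand <- names(tab)[tab == min(tab)]
      minor <- cand[order(cand)][length(cand)]   # tie: later allele name
      major <- setdiff(names(tab), minor)[1]
    }
    alleles[j, ] <- c(major, minor)
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == minor) + (a2[, j] == minor)
    d[miss] <- NA_integer_
    dosage[, j] <- d
  }
  structure(list(dosage = dosage,
                 map = data.frame(snp = map_raw[[2]], chr = map_raw[[1]],
                                  bp = map_raw[[4]],
                                  a1 = alleles[, 1], a2 = alleles[, 2],
                                  stringsAsFactors = FALSE),
                 animal_ids = animal_ids,
                 freq = colMeans(dosage, na.rm = TRUE) / 2),
            class = "genotype_matrix")
}

#' Write and read tidy vaginal-temperature TSVs
#'
#' The long table has columns `animal_id`, `timestamp` (ISO-8601, UTC),
#' `tv_celsius`; covariates live in a second table (`animal_id`,
#' `ventilation`, `parity`, `barn`).
#'
#' @param cohort A `tv_cohort` (named list of `tv_series`).
#' @param tv_path,cov_path Output paths.
#' @return Invisibly, the file paths.
#' @export
write_tv_tsv <- function(cohort, tv_path, cov_path) {
  long <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(animal_id = s$animal_id,
               timestamp = format(s$timestamps, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               tv_celsius = s$tv, stringsAsFactors = FALSE)
  }))
  utils::write.table(long, tv_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "NA")
  utils::write.table(attr(cohort, "covariates"), cov_path, quote = FALSE,
                     sep = "\t", row.names = FALSE, na = "NA")
  invisible(c(tv = tv_path, covariates = cov_path))
}

#' @rdname write_tv_tsv
#' @param tv_path,cov_path Input paths for the reader.
#' @return `read_tv_tsv`: a `tv_cohort`.
#' @export
read_tv_tsv <- function(tv_path, cov_path) {
  long <- utils::read.delim(tv_path, stringsAsFactors = FALSE)
  cov <- utils::read.delim(cov_path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "timestamp", "tv_celsius") %in% names(long)),
            all(c("animal_id", "ventilation", "parity", "barn") %in%
                  names(cov)))
  cohort <- lapply(cov$animal_id, function(id) {
    rows <- long[long$animal_id == id, , drop = FALSE]
    ts <- as.POSIXct(rows$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                     tz = "UTC")
    o <- order(ts)
    ci <- cov[cov$animal_id == id, ]
    tv_series(id, ts[o], rows$tv_celsius[o],
              ventilation = ci$ventilation, parity = ci$parity,
              barn_id = ci$barn)
  })
  names(cohort) <- cov$animal_id
  structure(cohort, covariates = cov, class = "tv_cohort")
}

#' Write an environment series, truth record or phenotype table as TSV
#'
#' All tables get a header row and `NA` for missing values.
#'
#' @param x The object to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_environment_tsv <- function(x, path) {
  out <- data.frame(timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    ambient_temp = x$ambient_temp,
                    relative_humidity = x$relative_humidity)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_environment_tsv
#' @export
write_truth_tsv <- function(x, path) {
  stopifnot(inherits(x, "truth_record"))
  tab <- data.frame(animal_id = names(x$latent_baseline),
                    latent_baseline = as.numeric(x$latent_baseline),
                    latent_heat_sensitivity =
                      as.numeric(x$latent_heat_sensitivity))
  header <- c(sprintf("# qtl_snp_ids: %s",
                      paste(x$qtl_snp_ids, collapse = ",")),
              sprintf("# realized_h2: baseline=%.6f heat_sensitivity=%.6f",
                      x$realized_h2["baseline"],
                      x$realized_h2["heat_sensitivity"]))
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(tab, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, na = "NA", append = TRUE))
  invisible(path)
}

#' @rdname write_environment_tsv
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "NA")
  invisible(path)
}
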