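#' Positional feature lookup around SNPs
#'
#' A feature (gene or QTL interval) is a hit for a SNP when its interval
#' intersects `[snp_bp - flank, snp_bp + flank]` on the same chromosome,
#' with inclusive ends — a feature edge exactly `flank` bp away still
#' counts. The reported distance is 0 when the SNP lies inside the
#' feature, otherwise the gap to the nearest feature edge.
#'
#' @param snps data.frame with `snp`, `chr`, `bp`.
#' @param features data.frame with `feature_id`, `chr` (or `chromosome`),
#'   `start`, `end` (1-based inclusive) and optionally further columns
#'   carried through.
#' @param flank Window half-width in bp (default 500000, i.e. 500 kb up
#'   and downstream).
#' @param feature_kind Label stored on each hit (`"gene"` or `"qtl"`).
#' @return data.frame of hits: `snp`, `chr`, `bp`, `feature_id`,
#'   `feature_kind`, `start`, `end`, `distance`, plus any extra feature
#'   columns. SNP chromosomes absent from the feature table are reported
#'   in a message, never silently dropped.
#' @export
window_lookup <- function(snps, features, flank = 500000,
                          feature_kind = c("gene", "qtl")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(all(c("snp", "chr", "bp") %in% names(snps)))
  if ("chromosome" %in% names(features) && !"chr" %in% names(features)) {
    names(features)[names(features) == "chromosome"] <- "chr"
  }
  stopifnot(all(c("feature_id", "chr", "start", "end") %in% names(features)))
  if (any(features$start > features$end)) stop("feature start > end")
  missing_chr <- setdiff(unique(as.character(snps$chr)),
                         unique(as.character(features$chr)))
  if (length(missing_chr) > 0) {
    message("window_lookup: no features on chromosome(s) ",
            paste(missing_chr, collapse = ", "))
  }
  extra <- setdiff(names(features), c("feature_id", "chr", "start", "end"))
  hits <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    f <- features[as.character(features$chr) == as.character(snps$chr[i]) &
                    features$end >= snps$bp[i] - flank &
                    features$start <= snps$bp[i] + flank, , drop = FALSE]
    if (nrow(f) == 0) next
    dist <- pmax(0, pmax(f$start - snps$bp[i], snps$bp[i] - f$end))
    hits[[i]] <- cbind(data.frame(snp = snps$snp[i], chr = snps$chr[i],
                                  bp = snps$bp[i],
                                  feature_id = f$feature_id,
                                  feature_kind = feature_kind,
                                  start = f$start, end = f$end,
                                  distance = dist,
                                  stringsAsFactors = FALSE),
                       f[, extra, drop = FALSE])
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(snp = character(0), chr = character(0),
                      bp = numeric(0), feature_id = character(0),
                      feature_kind = character(0), start = numeric(0),
                      end = numeric(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tally QTL hits by type
#'
#' Counts distinct QTL intervals overlapping the SNP windows per QTL type
#' and their proportion of all distinct QTL hits. Distinctness key:
#' chromosome, start, end, type, trait. Proportions sum to 1.
#'
#' @param hits Output of [window_lookup()] over QTL features; must carry
#'   `qtl_type` and (optionally) `trait_name` columns.
#' @return data.frame: `qtl_type`, `n`, `proportion` (empty when no hits).
#' @export
qtl_type_summary <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(qtl_type = character(0), n = integer(0),
                      proportion = numeric(0), stringsAsFactors = FALSE))
  }
  stopifnot("qtl_type" %in% names(hits))
  trait <- if ("trait_name" %in% names(hits)) hits$trait_name else ""
  key <- paste(hits$chr, hits$start, hits$end, hits$qtl_type, trait,
               sep = "\r")
  uniq <- hits[!duplicated(key), , drop = FALSE]
  tab <- table(uniq$qtl_type)
  data.frame(qtl_type = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of QTL types among hits
#'
#' Upper-tail hypergeometric test per QTL type: given `k` distinct hit QTL
#' out of `n` total hits, and `K` QTL of that type among `N` background
#' QTL, the p-value is `P(X >= k)` for `X ~ Hypergeometric(K, N - K, n)`.
#' A positional stand-in for database-driven enrichment; the study's QTL
#' database and web tooling are not queried.
#'
#' @param hits Output of [window_lookup()] over QTL features.
#' @param background data.frame of all candidate QTL records with
#'   `qtl_type` (and the distinctness columns `chr`/`chromosome`, `start`,
#'   `end`, `trait_name` when available).
#' @return data.frame: `qtl_type`, `hits`, `background`, `p_value`.
#' @export
hypergeometric_qtl_enrichment <- function(hits, background) {
  stopifnot("qtl_type" %in% names(background))
  hit_tab <- qtl_type_summary(hits)
  if ("chromosome" %in% names(background) && !"chr" %in% names(background)) {
    names(background)[names(background) == "chromosome"] <- "chr"
  }
  trait <- if ("trait_name" %in% names(background)) background$trait_name else ""
  bkey <- paste(background$chr, background$start, background$end,
                background$qtl_type, trait, sep = "\r")
  background <- background[!duplicated(bkey), , drop = FALSE]
  bg_tab <- table(background$qtl_type)
  absent <- setdiff(hit_tab$qtl_type, names(bg_tab))
  if (length(absent) > 0) {
    stop("QTL type(s) absent from background: ",
         paste(absent, collapse = ", "))
  }
  n_hit <- sum(hit_tab$n)
  N <- sum(bg_tab)
  out <- lapply(seq_len(nrow(hit_tab)), function(i) {
    k <- hit_tab$n[i]
    K <- as.integer(bg_tab[hit_tab$qtl_type[i]])
    if (k > K) stop("more hits than background records for type ",
                    hit_tab$qtl_type[i])
    p <- stats::phyper(k - 1, K, N - K, n_hit, lower.tail = FALSE)
    data.frame(qtl_type = hit_tab$qtl_type[i], hits = k, background = K,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read gene records from a GFF3 file
#'
#' Imports a GFF3 annotation (via \pkg{rtracklayer}) and returns gene
#' features as a flat table with a coarse biotype classification
#' (protein_coding / ncRNA / pseudogene / other). Attribute parsing is
#' limited to the ID / Name / biotype keys.
#'
#' @param path GFF3 file path.
#' @return data.frame: `feature_id`, `gene_name`, `chr`, `start`, `end`,
#'   `biotype`.
#' @export
read_gene_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  is_gene <- if ("type" %in% names(md)) {
    grepl("gene", md$type, ignore.case = TRUE)
  } else rep(TRUE, nrow(md))
  md <- md[is_gene, , drop = FALSE]
  get_col <- function(nm) if (nm %in% names(md)) as.character(md[[nm]])
             else rep(NA_character_, nrow(md))
  raw_bt <- get_col("biotype")
  if (all(is.na(raw_bt))) raw_bt <- get_col("gene_biotype")
  biotype <- ifelse(is.na(raw_bt), "other",
             ifelse(raw_bt == "protein_coding", "protein_coding",
             ifelse(grepl("pseudogene", raw_bt), "pseudogene",
             ifelse(grepl("RNA", raw_bt), "ncRNA", "other"))))
  id <- get_col("ID")
  if (all(is.na(id))) id <- get_col("gene_id")
  data.frame(feature_id = id,
             gene_name = get_col("Name"),
             chr = as.character(md$seqnames),
             start = md$start, end = md$end,
             biotype = biotype,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read QTL intervals
#'
#' Accepts either the Animal-QTLdb GFF dialect (9 tab-separated columns,
#' attributes carrying `QTL_ID`/`Name`/`trait`/`QTL_type` style keys) or a
#' documented 5-column TSV with header
#' `chromosome  start  end  qtl_type  trait_name`.
#'
#' @param path File path.
#' @param format `"auto"` (default: sniff the header), `"gff"` or `"tsv"`.
#' @return data.frame: `feature_id`, `chr`, `start`, `end`, `qtl_type`,
#'   `trait_name`.
#' @export
read_qtl_table <- function(path, format = c("auto", "gff", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 5)
    first <- first[!grepl("^#", first)]
    format <- if (length(first) > 0 &&
                  length(strsplit(first[1], "\t")[[1]]) >= 9) "gff" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("chromosome", "start", "end", "qtl_type",
                    "trait_name") %in% names(tab)))
    return(data.frame(feature_id = sprintf("qtl_%d", seq_len(nrow(tab))),
                      chr = as.character(tab$chromosome),
                      start = tab$start, end = tab$end,
                      qtl_type = tab$qtl_type,
                      trait_name = tab$trait_name,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 9)
  if (length(bad) > 0) stop("malformed QTL GFF line ", bad[1])
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key,
                                          '\\s*=\\s*"?([^;"]*)"?'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  attrs <- vapply(parts, `[`, character(1), 9)
  chr <- sub("^(Chr\\.?|chr)", "", vapply(parts, `[`, character(1), 1))
  start <- as.numeric(vapply(parts, `[`, character(1), 4))
  end <- as.numeric(vapply(parts, `[`, character(1), 5))
  id <- attr_get(attrs, "QTL_ID")
  id[is.na(id)] <- sprintf("qtl_%d", which(is.na(id)))
  qtl_type <- attr_get(attrs, "QTL_type")
  qtl_type[is.na(qtl_type)] <- vapply(parts, `[`, character(1), 3)[is.na(qtl_type)]
  trait <- attr_get(attrs, "trait")
  trait2 <- attr_get(attrs, "Name")
  trait[is.na(trait)] <- trait2[is.na(trait)]
  swap <- is.na(start) | is.na(end)
  if (any(swap)) stop("QTL GFF records without numeric start/end")
  data.frame(feature_id = id, chr = chr, start = start, end = end,
             qtl_type = qtl_type, trait_name = trait,
             row.names = NULL, stringsAsFactors = FALSE)
}
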