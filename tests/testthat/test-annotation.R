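test_that("window lookup honours the inclusive 500 kb boundary", {
  snps <- data.frame(snp = "s1", chr = 1, bp = 1e6)
  inside <- data.frame(feature_id = "g1", chr = 1,
                       start = 1400000, end = 1450000)
  hit <- window_lookup(snps, inside)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 400000)

  just_out <- data.frame(feature_id = "g2", chr = 1,
                         start = 1500001, end = 1600000)
  expect_equal(nrow(window_lookup(snps, just_out)), 0)

  at_edge <- data.frame(feature_id = "g3", chr = 1,
                        start = 1500000, end = 1600000)
  hit3 <- window_lookup(snps, at_edge)
  expect_equal(nrow(hit3), 1)
  expect_equal(hit3$distance, 500000)

  # SNP inside a feature: distance zero
  container <- data.frame(feature_id = "g4", chr = 1,
                          start = 900000, end = 1100000)
  expect_equal(window_lookup(snps, container)$distance, 0)

  # chromosome mismatches are reported, not dropped silently
  off_chr <- data.frame(feature_id = "g5", chr = 2,
                        start = 1e6, end = 2e6)
  expect_message(res <- window_lookup(snps, off_chr), "chromosome")
  expect_equal(nrow(res), 0)
})

test_that("window lookup agrees with the all-pairs oracle on random fixtures", {
  set.seed(501)
  for (rep in 1:100) {
    n_snp <- sample(1:6, 1); n_feat <- sample(1:12, 1)
    snps <- data.frame(snp = sprintf("s%d", seq_len(n_snp)),
                       chr = sample(1:3, n_snp, replace = TRUE),
                       bp = sample.int(5e6, n_snp))
    start <- sample.int(5e6, n_feat)
    feats <- data.frame(feature_id = sprintf("f%d", seq_len(n_feat)),
                        chr = sample(1:3, n_feat, replace = TRUE),
                        start = start,
                        end = start + sample.int(3e5, n_feat))
    # plant exact-boundary cases now and then
    flank <- 500000
    if (rep %% 10 == 0 && n_feat >= 1) {
      feats$chr[1] <- snps$chr[1]
      feats$start[1] <- snps$bp[1] + flank
      feats$end[1] <- feats$start[1] + 1000
    }
    got <- suppressMessages(window_lookup(snps, feats, flank))
    ora <- naive_overlap(snps, feats, flank)
    key <- function(d) sort(paste(d$snp, d$feature_id, d$distance))
    expect_equal(key(got), key(ora))
  }
})

test_that("lookup results do not depend on feature order", {
  set.seed(502)
  snps <- data.frame(snp = c("a", "b"), chr = c(1, 1), bp = c(2e6, 4e6))
  start <- sample.int(6e6, 20)
  feats <- data.frame(feature_id = sprintf("f%d", 1:20), chr = 1,
                      start = start, end = start + 1e5)
  h1 <- window_lookup(snps, feats)
  h2 <- window_lookup(snps, feats[sample(20), ])
  key <- function(d) sort(paste(d$snp, d$feature_id, d$distance))
  expect_equal(key(h1), key(h2))
})

test_that("QTL type summary counts distinct intervals with unit proportions", {
  mk_hits <- function(types, n_each) {
    do.call(rbind, lapply(seq_along(types), function(i) {
      data.frame(snp = "s", chr = 1, bp = 1,
                 feature_id = sprintf("%s_%d", types[i], seq_len(n_each[i])),
                 feature_kind = "qtl",
                 start = 1000 * seq_len(n_each[i]) + i * 1e6,
                 end = 1000 * seq_len(n_each[i]) + i * 1e6 + 10,
                 distance = 0, qtl_type = types[i],
                 trait_name = "t", stringsAsFactors = FALSE)
    }))
  }
  hits <- mk_hits(c("Meat_and_Carcass", "Health", "Production"),
                  c(7, 5, 4))
  qs <- qtl_type_summary(hits)
  expect_equal(sum(qs$proportion), 1, tolerance = 1e-12)
  expect_equal(qs$proportion[qs$qtl_type == "Meat_and_Carcass"], 7 / 16)
  expect_equal(qs$proportion[qs$qtl_type == "Meat_and_Carcass"] * 100,
               43.75)

  single <- mk_hits("Health", 3)
  expect_equal(qtl_type_summary(single)$proportion, 1)

  # a QTL hit by two SNPs counts once
  dup <- rbind(hits, transform(hits[1, ], snp = "s2"))
  expect_equal(qtl_type_summary(dup)$n, qs$n)

  empty <- hits[0, ]
  expect_equal(nrow(qtl_type_summary(empty)), 0)
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  bg <- data.frame(chr = 1,
                   start = seq_len(1000) * 1e4,
                   end = seq_len(1000) * 1e4 + 100,
                   qtl_type = rep(c("rare", "common"), c(10, 990)),
                   trait_name = "t")
  # all 10 hits from the rare type (background fraction 1%)
  hits <- data.frame(snp = "s", chr = 1, bp = 1,
                     feature_id = sprintf("f%d", 1:10),
                     start = bg$start[1:10], end = bg$end[1:10],
                     distance = 0, qtl_type = "rare", trait_name = "t")
  enr <- hypergeometric_qtl_enrichment(hits, bg)
  expect_lt(enr$p_value[enr$qtl_type == "rare"], 1e-10)
  expect_equal(enr$p_value[enr$qtl_type == "rare"],
               phyper(9, 10, 990, 10, lower.tail = FALSE))

  # single hit: p equals the type's background fraction
  one <- hits[1, ]
  enr1 <- hypergeometric_qtl_enrichment(one, bg)
  expect_equal(enr1$p_value, 10 / 1000)

  # hits drawn exactly proportional to an even background are unenriched
  bg_even <- transform(bg, qtl_type = rep(c("rare", "common"), each = 500))
  prop_hits <- rbind(hits[1:5, ],
                     transform(hits[1:5, ],
                               qtl_type = "common",
                               start = bg$start[501:505],
                               end = bg$end[501:505],
                               feature_id = sprintf("c%d", 1:5)))
  enr_p <- hypergeometric_qtl_enrichment(prop_hits, bg_even)
  expect_true(all(enr_p$p_value >= 0.5))

  expect_error(hypergeometric_qtl_enrichment(
    transform(one, qtl_type = "unknown"), bg), "absent")
})

test_that("QTL readers accept both the GFF dialect and the 5-column TSV", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c(
    "#Animal QTLdb dialect fixture (synthetic)",
    paste("Chr.2", "Animal QTLdb", "Milk", "88000000", "88900000", ".",
          ".", ".", 'QTL_ID=1001;Name="Loin muscle area";QTL_type=Meat_and_Carcass;trait="Loin muscle area";',
          sep = "\t"),
    paste("Chr.2", "Animal QTLdb", "Health", "25000000", "25400000", ".",
          ".", ".", 'QTL_ID=1002;Name="IGF-1 level";QTL_type=Health;trait="IGF-1 level";',
          sep = "\t")),
    gff)
  q <- read_qtl_table(gff)
  expect_equal(nrow(q), 2)
  expect_equal(q$chr, c("2", "2"))
  expect_equal(q$qtl_type, c("Meat_and_Carcass", "Health"))
  expect_equal(q$start, c(88000000, 25000000))
  expect_equal(q$trait_name[2], "IGF-1 level")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tstart\tend\tqtl_type\ttrait_name",
               "3\t18000000\t18500000\tProduction\tADG"), tsv)
  q2 <- read_qtl_table(tsv)
  expect_equal(q2$qtl_type, "Production")
  expect_equal(q2$end, 18500000)
})

test_that("gene GFF3 reading classifies biotypes", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("1", "test", "gene", "1400000", "1450000", ".", "+", ".",
          "ID=gene:G1;Name=HSPX1;biotype=protein_coding", sep = "\t"),
    paste("1", "test", "gene", "2000000", "2001000", ".", "-", ".",
          "ID=gene:G2;Name=NC1;biotype=lncRNA", sep = "\t"),
    paste("1", "test", "gene", "3000000", "3000500", ".", "+", ".",
          "ID=gene:G3;Name=PS1;biotype=processed_pseudogene", sep = "\t")),
    gff)
  genes <- read_gene_gff3(gff)
  expect_equal(nrow(genes), 3)
  expect_equal(genes$biotype, c("protein_coding", "ncRNA", "pseudogene"))
  expect_equal(genes$start[1], 1400000)
  hits <- window_lookup(data.frame(snp = "s", chr = 1, bp = 1e6), genes)
  expect_equal(hits$feature_id, "gene:G1")
})
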