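# window extraction, motif scanning, region classification, annotation

toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

test_that("extract_window returns the centred 11-mer", {
  g <- toy_genome(c(c1 = "ACGTACGTACGTACGT"))
  expect_identical(extract_window(g, "c1", 8), "GTACGTACGTA")
  expect_identical(nchar(extract_window(g, "c1", 6)), 11L)
  # centre base is the reference base at pos
  w <- extract_window(g, "c1", 7)
  expect_identical(substr(w, 6, 6), "G")
  expect_error(extract_window(g, "c1", 4), "out of bounds")
  expect_error(extract_window(g, "c1", 12), "out of bounds")
  expect_error(extract_window(g, "c9", 8), "unknown contig")
})

test_that("scan_sre matches hexamers at any of the six offsets", {
  ese <- motif_set("ESE", "AAAAAA")
  expect_true(scan_sre("AAAAAAAAAAA", ese))
  expect_false(scan_sre("ACGTACGTACG", motif_set("ESE", "TTTTTT")))
  # offset-by-offset: motif exactly at each start
  for (off in 0:5) {
    w <- strrep("C", 11)
    substr(w, off + 1, off + 6) <- "AAAAAA"
    expect_true(scan_sre(w, ese))
  }
  expect_error(scan_sre("ACGT", ese), "11-mer")
  # substrings containing N never match
  expect_false(scan_sre("AANAAAAANAA", ese))
})

test_that("scan_sre equals the exhaustive substring oracle", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (i in 1:2000) {
    w <- paste(sample(bases, 11, TRUE), collapse = "")
    hexes <- vapply(1:3, function(j)
      paste(sample(bases, 6, TRUE), collapse = ""), character(1))
    ms <- motif_set("ESS", hexes)
    oracle <- any(vapply(unique(hexes), function(h)
      grepl(h, w, fixed = TRUE), logical(1)))
    expect_identical(scan_sre(w, ms), oracle)
  }
})

test_that("region classification honours exact exon boundaries", {
  models <- gene_models(data.frame(
    gene_id = "g1", contig = "c1", strand = "+",
    start = c(101, 301), end = c(200, 400)))
  probe <- function(pos) {
    r <- classify_region(data.frame(contig = "c1", pos = pos), models)
    unname(r$region)
  }
  expect_identical(probe(100), "intergenic")
  expect_identical(probe(101), "exonic")      # first exon base
  expect_identical(probe(200), "exonic")      # last exon base
  expect_identical(probe(201), "intronic")
  expect_identical(probe(300), "intronic")
  expect_identical(probe(301), "exonic")
  expect_identical(probe(400), "exonic")
  expect_identical(probe(401), "intergenic")
  r <- classify_region(data.frame(contig = "c1", pos = 250), models)
  expect_identical(r$gene_id, "g1")           # intron owned by g1
})

test_that("BED12 gene models convert 0-based blocks to 1-based exons", {
  bed <- paste("c1", 100, 400, "g1", 0, "+", 100, 400, 0, 2,
               "100,100", "0,200", sep = "\t")
  tf <- tempfile(fileext = ".bed")
  writeLines(bed, tf)
  models <- read_gene_models(tf)
  expect_equal(models$exons$start, c(101, 301))
  expect_equal(models$exons$end, c(200, 400))
})

test_that("overlapping genes give one annotation per gene", {
  models <- gene_models(data.frame(
    gene_id = c("gA", "gA", "gB"), contig = "c1", strand = "+",
    start = c(101, 301, 150), end = c(200, 400, 180)))
  r <- classify_region(data.frame(contig = "c1", pos = 160), models)
  expect_equal(nrow(r), 2)
  expect_setequal(r$gene_id, c("gA", "gB"))
  expect_setequal(r$region, c("exonic", "exonic"))
})

test_that("annotation enforces region/category consistency", {
  set.seed(22)
  seq_bg <- paste(sample(c("A", "C"), 500, TRUE), collapse = "")
  # plant an ESE hexamer in an intron: must NOT be called (ISE only there)
  seqv <- strsplit(seq_bg, "")[[1]]
  seqv[231:236] <- strsplit("GGGGGG", "")[[1]]   # ESE motif inside intron
  g <- toy_genome(c(c1 = paste(seqv, collapse = "")))
  models <- gene_models(data.frame(
    gene_id = "g1", contig = "c1", strand = "+",
    start = c(101, 301), end = c(200, 400)))
  sets <- list(ESE = motif_set("ESE", "GGGGGG"),
               ESS = motif_set("ESS", "TTTTTT"),
               ISE = motif_set("ISE", "AAAAAA"))
  variants <- data.frame(contig = "c1", pos = c(233, 150),
                         ref = toupper(seqv[c(233, 150)]), alt = "T")
  ann <- annotate_variants(variants, g, models, sets)
  intronic <- ann[ann$region == "intronic", ]
  expect_identical(intronic$categories, "")     # ESE does not count there
  # an exonic variant whose window holds the ESE motif is called ESE
  seqv[146:151] <- strsplit("GGGGGG", "")[[1]]
  g2 <- toy_genome(c(c1 = paste(seqv, collapse = "")))
  variants$ref <- toupper(seqv[variants$pos])   # keep ref concordant
  ann2 <- annotate_variants(variants, g2, models, sets)
  expect_identical(ann2$categories[ann2$region == "exonic"], "ESE")
})

test_that("VCF/FASTA reference mismatches are warned and counted", {
  g <- toy_genome(c(c1 = strrep("ACGT", 30)))
  models <- gene_models(data.frame(gene_id = "g1", contig = "c1",
                                   strand = "+", start = 20, end = 100))
  sets <- list(ESE = motif_set("ESE", "AAAAAA"),
               ESS = motif_set("ESS", "CCCCCC"),
               ISE = motif_set("ISE", "GGGGGG"))
  variants <- data.frame(contig = "c1", pos = c(50, 60),
                         ref = c("T", "A"), alt = c("G", "C"))
  # pos 50: FASTA base is "G" (cycle ACGT), so ref "T" mismatches
  expect_warning(ann <- annotate_variants(variants, g, models, sets),
                 "ref allele differing")
  expect_equal(attr(ann, "ref_mismatch"), 2L)
})

test_that("every planted SRE variant in a synthetic cohort is recovered", {
  co <- default_test_cohort()
  genome <- read_genome(co$fasta_path)
  models <- read_gene_models(co$gene_model_path)
  sets <- read_motif_sets(co$motif_paths[["ESE"]], co$motif_paths[["ESS"]],
                          co$motif_paths[["ISE"]])
  geno <- read_vcf_dosages(co$vcf_path)
  ann <- annotate_variants(geno$variants, genome, models, sets)

  tv <- co$truth$variants
  planted <- tv[!is.na(tv$planted_category), ]
  for (i in seq_len(nrow(planted))) {
    rows <- ann[ann$key == planted$key[i], ]
    expect_true(planted$planted_category[i] %in%
                  unlist(strsplit(rows$categories, ",")))
  }
  # region/category consistency across the full cohort
  cats <- strsplit(ann$categories, ",")
  exo_ok <- ann$region != "exonic" |
    vapply(cats, function(x) all(x %in% c("ESE", "ESS")), logical(1))
  int_ok <- ann$region != "intronic" |
    vapply(cats, function(x) all(x %in% "ISE"), logical(1))
  expect_true(all(exo_ok & int_ok))
  # exactly one region label per (variant, gene) and windows centred right
  expect_true(all(ann$region %in% c("exonic", "intronic", "intergenic")))
  expect_identical(substr(ann$window, 6, 6),
                   geno$variants$ref[match(ann$key, geno$variants$key)])
})
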