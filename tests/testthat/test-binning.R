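# MAF computation and gene-level rare-variant binning

test_that("compute_maf counts alleles and folds to the minor allele", {
  expect_equal(compute_maf(c(0, 0, 1, 0)), 0.125)
  expect_equal(compute_maf(rep(0, 10)), 0)
  expect_equal(compute_maf(c(2, 2, 2, 1)), 1 / 8)   # alt is major: folded
  expect_equal(compute_maf(c(1, NA, 0, 0)), 1 / 6)  # missing excluded
  expect_error(compute_maf(c(NA, NA)), "missing")
  expect_error(compute_maf(c(0, 3)), "dosages")
})

test_that("compute_maf equals brute-force allele counting", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    d <- sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(0.7, 0.15, 0.05, 0.1))
    if (all(is.na(d))) next
    alleles <- c(unlist(lapply(d[!is.na(d)], function(x)
      c(rep(1, x), rep(0, 2 - x)))))
    p_alt <- mean(alleles)
    expect_equal(compute_maf(d), min(p_alt, 1 - p_alt))
  }
})

# handcrafted annotation/dosage fixture: two genes, controlled categories
make_bin_fixture <- function(n = 300) {
  keys <- sprintf("c1:%d", 1:8 * 50)
  ann <- data.frame(
    key = keys, contig = "c1", pos = 1:8 * 50,
    rsid = sprintf("rs%d", 1:8),
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gB", NA),
    region = c(rep("exonic", 4), "exonic", "exonic", "intronic",
               "intergenic"),
    categories = c("ESE", "ESS", "ESE,ESS", "ESE", "ESE", "", "ISE", ""),
    window = strrep("A", 11), stringsAsFactors = FALSE)
  dos <- matrix(0L, n, 8, dimnames = list(NULL, keys))
  dos[1:4, 1] <- 1L            # maf 4/(2n)
  dos[5:8, 2] <- 1L
  dos[9:12, 3] <- 1L
  dos[13:16, 4] <- 1L          # gA coding: 4 loci, 16 alleles
  dos[1:2, 5] <- 1L            # gB coding: 1 locus, 2 alleles -> too small
  dos[1:10, 6] <- 1L           # no category: never binned
  dos[3:4, 7] <- 1L            # gB intronic ISE
  dos[1:8, 8] <- 1L            # intergenic
  list(ann = ann, geno = list(dosages = dos,
                              variants = data.frame(key = keys)))
}

test_that("binning reproduces hand-computed loci and allele counts", {
  fx <- make_bin_fixture()
  bins <- bin_by_gene(fx$ann, fx$geno, bin_config(category_mode = "coding"))
  expect_named(bins, "gA")
  expect_equal(bins$gA$m_loci, 4)
  expect_equal(bins$gA$total_allele_count, 16)
  man <- bin_manifest(bins)
  expect_equal(man$unique_loci, 4)
  expect_equal(man$variants_across_cohort, 16)
  # gB's single coding locus (2 alleles) is below the 5-allele minimum
  expect_false("gB" %in% names(bins))
})

test_that("category modes never admit out-of-category variants", {
  fx <- make_bin_fixture()
  b_int <- suppressWarnings(
    bin_by_gene(fx$ann, fx$geno, bin_config(category_mode = "intronic",
                                            min_bin_size = 1)))
  expect_named(b_int, "gB")
  expect_equal(b_int$gB$loci, "c1:350")    # the ISE locus only
  b_cod <- bin_by_gene(fx$ann, fx$geno,
                       bin_config(category_mode = "coding",
                                  min_bin_size = 1))
  expect_false("c1:350" %in% unlist(lapply(b_cod, `[[`, "loci")))
  # combined-mode loci dominate each single mode
  b_com <- bin_by_gene(fx$ann, fx$geno,
                       bin_config(category_mode = "combined",
                                  min_bin_size = 1))
  for (g in names(b_com)) {
    m_single <- max(length(b_cod[[g]]$loci), length(b_int[[g]]$loci))
    expect_gte(b_com[[g]]$m_loci, m_single)
  }
})

test_that("common, monomorphic and threshold-equal variants are excluded", {
  n <- 300
  keys <- c("c1:10", "c1:20", "c1:30")
  ann <- data.frame(key = keys, contig = "c1", pos = c(10, 20, 30),
                    rsid = NA, gene_id = "gA", region = "exonic",
                    categories = "ESE", window = strrep("A", 11),
                    stringsAsFactors = FALSE)
  dos <- matrix(0L, n, 3, dimnames = list(NULL, keys))
  dos[1:12, 1] <- 1L           # maf 0.02 >= 0.01: excluded
  dos[1:3, 2] <- c(2L, 1L, 1L) # maf 4/600 < 0.01: kept
  dos[, 3] <- 0L               # monomorphic: excluded
  bins <- bin_by_gene(ann, list(dosages = dos),
                      bin_config(min_bin_size = 1))
  expect_equal(bins$gA$loci, "c1:20")
  # exactly at the threshold is excluded too (strict inequality): maf 0.01
  dos[, 1] <- 0L; dos[1:6, 1] <- 1L   # 6/600 = 0.01
  bins2 <- bin_by_gene(ann, list(dosages = dos),
                       bin_config(min_bin_size = 1))
  expect_false("c1:10" %in% bins2$gA$loci)
})

test_that("major-allele-coded and missing dosages are handled", {
  n <- 200
  keys <- c("c1:10", "c1:20")
  ann <- data.frame(key = keys, contig = "c1", pos = c(10, 20), rsid = NA,
                    gene_id = "gA", region = "exonic", categories = "ESE",
                    window = strrep("A", 11), stringsAsFactors = FALSE)
  dos <- matrix(2L, n, 2, dimnames = list(NULL, keys))
  dos[1:3, 1] <- 1L                       # alt freq ~ 0.99: minor is ref
  dos[1:3, 2] <- 1L
  dos[5:6, 2] <- NA
  bins <- bin_by_gene(ann, list(dosages = dos), bin_config(min_bin_size = 1))
  expect_equal(unname(bins$gA$mafs[1]), 3 / (2 * n))
  expect_true(all(bins$gA$G[, 1] %in% c(0, 1)))  # folded coding
  # missing genotypes: non-carriers for counts, mean-imputed in G
  maf2 <- 3 / (2 * (n - 2))                # folded minor (= ref) frequency
  expect_equal(unname(bins$gA$mafs[2]), maf2)
  expect_equal(sort(unique(bins$gA$G[, 2])), sort(c(0, 2 * maf2, 1)))
  expect_equal(bins$gA$total_allele_count, 3 + 3)
})

test_that("QC accounting conserves the variant total", {
  fx <- make_bin_fixture()
  for (mode in c("coding", "intronic", "combined")) {
    bins <- suppressWarnings(
      bin_by_gene(fx$ann, fx$geno, bin_config(category_mode = mode)))
    qc <- attr(bins, "qc")
    stages <- c("retained", "dropped_small_bin", "dropped_by_maf",
                "dropped_monomorphic", "dropped_by_category",
                "dropped_by_region")
    expect_equal(sum(unlist(qc[stages])), qc$n_variants, info = mode)
  }
})

test_that("binning is deterministic and stable under re-runs", {
  fx <- make_bin_fixture()
  b1 <- bin_by_gene(fx$ann, fx$geno, bin_config())
  b2 <- bin_by_gene(fx$ann, fx$geno, bin_config())
  expect_identical(b1, b2)
})

test_that("the locus-count bin-size rule is available", {
  fx <- make_bin_fixture()
  # gA has 4 coding loci: passes allele_count (16 >= 5) but fails a
  # 5-locus minimum under the alternative rule
  bins <- suppressWarnings(
    bin_by_gene(fx$ann, fx$geno,
                bin_config(min_bin_size = 5, size_rule = "locus_count")))
  expect_false("gA" %in% names(bins))
})
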