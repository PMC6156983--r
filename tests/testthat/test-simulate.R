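# synthetic cohort generator

test_that("cohort dimensions match the configuration", {
  cfg <- sim_config(n_samples = 100, n_genes = 5, seed = 1)
  co <- simulate_cohort(cfg)
  ph <- read_phenotypes(co$phenotype_path)
  expect_equal(nrow(ph), 100)
  geno <- read_vcf_dosages(co$vcf_path)
  expect_equal(length(geno$samples), 100)
  expect_identical(geno$samples, ph$sample_id)
  expect_equal(nrow(geno$variants), 5 * cfg$n_variants_per_gene)
  genome <- read_genome(co$fasta_path)
  expect_equal(length(genome), 5)
  # every variant lies on a generated contig, within bounds
  expect_true(all(geno$variants$contig %in% names(genome)))
  lens <- stats::setNames(vapply(names(genome),
                                 function(x) length(genome[[x]]), numeric(1)),
                          names(genome))
  expect_true(all(geno$variants$pos <= lens[geno$variants$contig]))
  unlink(co$dir, recursive = TRUE)
})

test_that("a fixed seed reproduces byte-identical files", {
  cfg <- sim_config(n_samples = 60, n_genes = 3, seed = 77,
                    causal_genes = "gene01", effect_size = 0.4)
  co1 <- simulate_cohort(cfg, dir = tempfile())
  co2 <- simulate_cohort(cfg, dir = tempfile())
  for (f in c("fasta_path", "gene_model_path", "vcf_path",
              "phenotype_path")) {
    expect_identical(unname(tools::md5sum(co1[[f]])),
                     unname(tools::md5sum(co2[[f]])), info = f)
  }
  for (m in names(co1$motif_paths))
    expect_identical(unname(tools::md5sum(co1$motif_paths[[m]])),
                     unname(tools::md5sum(co2$motif_paths[[m]])))
  # and a different seed does not
  co3 <- simulate_cohort(sim_config(n_samples = 60, n_genes = 3, seed = 78,
                                    causal_genes = "gene01",
                                    effect_size = 0.4), dir = tempfile())
  expect_false(identical(unname(tools::md5sum(co1$vcf_path)),
                         unname(tools::md5sum(co3$vcf_path))))
  unlink(c(co1$dir, co2$dir, co3$dir), recursive = TRUE)
})

test_that("empirical MAFs track the drawn MAFs to binomial accuracy", {
  cfg <- sim_config(n_samples = 400, n_genes = 6, seed = 9)
  co <- simulate_cohort(cfg)
  geno <- read_vcf_dosages(co$vcf_path)
  tv <- co$truth$variants
  emp <- colMeans(geno$dosages[, tv$key]) / 2
  sd_bin <- sqrt(tv$maf_drawn * (1 - tv$maf_drawn) / (2 * 400))
  frac_in <- mean(abs(emp - tv$maf_drawn) <= 3 * sd_bin)
  expect_gt(frac_in, 0.98)
  unlink(co$dir, recursive = TRUE)
})

test_that("plant_sre_site writes the motif into the 11-mer window", {
  set.seed(31)
  seq_t <- strrep("T", 40)
  planted <- plant_sre_site(seq_t, 10, "AAAAAA")
  win <- substr(planted, 5, 15)
  expect_true(scan_sre(win, motif_set("ESE", "AAAAAA")))
  expect_true(grepl("AAAAAA", win, fixed = TRUE))   # brute-force check
  # boundary: window under-runs the contig
  expect_error(plant_sre_site(strrep("T", 20), 3, "AAAAAA"),
               "out of bounds")
  expect_error(plant_sre_site(seq_t, 10, "AAAA"), "hexamer")
  # vector-of-bases representation round-trips
  v <- plant_sre_site(rep("T", 40), 10, "CCCCCC")
  expect_type(v, "character")
  expect_length(v, 40)
  expect_true(grepl("CCCCCC", paste(v[5:15], collapse = "")))
})

test_that("planted sites survive into the written genome", {
  set.seed(32)
  cfg <- sim_config(n_samples = 50, n_genes = 4, seed = 13)
  co <- simulate_cohort(cfg)
  genome <- read_genome(co$fasta_path)
  sets <- read_motif_sets(co$motif_paths[["ESE"]], co$motif_paths[["ESS"]],
                          co$motif_paths[["ISE"]])
  tv <- co$truth$variants
  planted <- tv[!is.na(tv$planted_category), ]
  for (i in seq_len(nrow(planted))) {
    win <- extract_window(genome, planted$contig[i], planted$pos[i])
    expect_true(scan_sre(win, sets[[planted$planted_category[i]]]),
                info = planted$key[i])
  }
  unlink(co$dir, recursive = TRUE)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(n_samples = 100, exon_len = 15, intron_len = 15,
                          n_variants_per_gene = 50), "too small")
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(sex_ratio = 1.2), "sex_ratio")
  cfg <- sim_config(causal_genes = "gene99", n_genes = 3)
  expect_error(simulate_cohort(cfg), "gene99")
})

test_that("motif catalogs are disjoint across categories", {
  cfg <- sim_config(n_samples = 40, n_genes = 2, seed = 5)
  co <- simulate_cohort(cfg)
  sets <- read_motif_sets(co$motif_paths[["ESE"]], co$motif_paths[["ESS"]],
                          co$motif_paths[["ISE"]])
  expect_length(intersect(sets$ESE$hexamers, sets$ESS$hexamers), 0)
  expect_length(intersect(sets$ESE$hexamers, sets$ISE$hexamers), 0)
  expect_length(intersect(sets$ESS$hexamers, sets$ISE$hexamers), 0)
  unlink(co$dir, recursive = TRUE)
})

test_that("truth table flags exactly the requested causal structure", {
  cfg <- sim_config(n_samples = 80, n_genes = 4, causal_genes = "gene02",
                    causal_variants_per_gene = 3, effect_size = 0.7,
                    seed = 21)
  co <- simulate_cohort(cfg)
  tv <- co$truth$variants
  expect_equal(sum(tv$causal), 3)
  expect_true(all(tv$gene_id[tv$causal] == "gene02"))
  expect_true(all(tv$region[tv$causal] == "exonic"))
  expect_true(all(tv$planted_category[tv$causal] %in% c("ESE", "ESS")))
  expect_true(all(tv$beta[tv$causal] == 0.7))
  expect_true(all(tv$maf_drawn[tv$causal] < 0.01))
  expect_identical(co$truth$genes$causal, c(FALSE, TRUE, FALSE, FALSE))
  unlink(co$dir, recursive = TRUE)
})
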