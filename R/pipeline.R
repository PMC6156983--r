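#' Configuration for a full pipeline run
#'
#' @param fasta,vcf,gene_models_path,phenotypes Input paths (reference
#'   genome, multi-sample VCF, BED12 gene models, phenotype TSV).
#' @param motifs Named character vector/list with elements `ESE`, `ESS`,
#'   `ISE`: paths to the hexamer catalogs.
#' @param out_dir Output directory for tables and the run manifest.
#' @param modes Category modes to run (any of `"coding"`, `"intronic"`,
#'   `"combined"`).
#' @param bin An [bin_config()] (the `category_mode` field is overridden
#'   per mode).
#' @param assoc An [assoc_config()].
#' @param run_loo Run the leave-one-out contribution analysis for every
#'   significant or suggestive gene.
#' @param scan_alt,stranded Passed to [annotate_variants()].
#' @return An object of class `sre_pipeline_config`.
#' @export
pipeline_config <- function(fasta, vcf, gene_models_path, phenotypes, motifs,
                            out_dir,
                            modes = c("coding", "intronic", "combined"),
                            bin = bin_config(),
                            assoc = assoc_config(),
                            run_loo = TRUE,
                            scan_alt = FALSE, stranded = FALSE) {
  paths <- c(fasta = fasta, vcf = vcf, gene_models = gene_models_path,
             phenotypes = phenotypes, unlist(motifs))
  missing_p <- paths[!file.exists(paths)]
  if (length(missing_p))
    stop("input file(s) not found: ", paste(missing_p, collapse = ", "))
  stopifnot(length(modes) >= 1,
            all(modes %in% c("coding", "intronic", "combined")),
            all(c("ESE", "ESS", "ISE") %in% names(motifs)))
  structure(list(fasta = fasta, vcf = vcf,
                 gene_models_path = gene_models_path,
                 phenotypes = phenotypes, motifs = motifs,
                 out_dir = out_dir, modes = modes, bin = bin, assoc = assoc,
                 run_loo = run_loo, scan_alt = scan_alt, stranded = stranded),
            class = "sre_pipeline_config")
}

#' Run the rare-variant SRE association pipeline
#'
#' Executes annotate -> bin -> SKAT-O -> BH-FDR (-> leave-one-out) for each
#' requested category mode and writes per-mode results tables, contribution
#' tables for significant/suggestive genes, a QC summary with exact variant
#' accounting per filter stage, and a run manifest (input checksums and
#' configuration digest). Given identical inputs and configuration the
#' outputs are byte-identical.
#'
#' @param config An [pipeline_config()].
#' @return Result bundle (class `sre_pipeline_result`): `results` (named
#'   per-mode [fdr_table()] data frames), `bins` (per-mode gene bins),
#'   `contributions` (per-mode [leave_one_out()] tables), `qc` (per-mode
#'   accounting), `null_model`, `annotations`, `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sre_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("read_genome", read_genome(config$fasta))
  models <- stage("read_gene_models", read_gene_models(config$gene_models_path))
  motif_sets <- stage("read_motifs",
                      read_motif_sets(config$motifs[["ESE"]],
                                      config$motifs[["ESS"]],
                                      config$motifs[["ISE"]]))
  geno <- stage("read_vcf", read_vcf_dosages(config$vcf))
  pheno <- stage("read_phenotypes", read_phenotypes(config$phenotypes))
  if (!identical(geno$samples, pheno$sample_id)) {
    if (!setequal(geno$samples, pheno$sample_id))
      stop("pipeline stage 'sample_alignment' failed: VCF and phenotype ",
           "sample sets differ")
    pheno <- pheno[match(geno$samples, pheno$sample_id), , drop = FALSE]
  }

  null <- stage("null_model",
                fit_null_model(pheno$phenotype,
                               pheno[, c("age", "sex")],
                               sample_ids = pheno$sample_id))

  ref_mismatch <- 0L
  ann <- withCallingHandlers(
    stage("annotate", annotate_variants(geno$variants, genome, models,
                                        motif_sets,
                                        scan_alt = config$scan_alt,
                                        stranded = config$stranded)),
    warning = function(w) {
      if (grepl("ref allele differing", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ref_mismatch <- attr(ann, "ref_mismatch")

  results <- list(); bins_all <- list(); contribs <- list(); qc <- list()
  files <- character(0)
  for (mode in config$modes) {
    bcfg <- config$bin
    bcfg$category_mode <- mode
    bins <- stage(paste0("bin[", mode, "]"),
                  suppressWarnings(bin_by_gene(ann, geno, bcfg)))
    qc[[mode]] <- attr(bins, "qc")
    bins_all[[mode]] <- bins
    if (!length(bins)) {
      results[[mode]] <- fdr_table(data.frame(
        gene_id = character(0), unique_loci = integer(0),
        variants_across_cohort = integer(0), skat_o_pvalue = numeric(0)))
      next
    }
    assoc_res <- stage(paste0("test[", mode, "]"),
                       lapply(bins, skat_o, null = null,
                              config = config$assoc))
    results[[mode]] <- stage(paste0("fdr[", mode, "]"),
                             fdr_table(assoc_res))

    f <- file.path(config$out_dir, paste0("results_", mode, ".tsv"))
    utils::write.table(format_result_table(results[[mode]]), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)

    if (config$run_loo) {
      hits <- results[[mode]]$gene_id[results[[mode]]$suggestive]
      hits <- hits[vapply(hits, function(g) bins[[g]]$m_loci >= 2, logical(1))]
      if (length(hits)) {
        ct <- do.call(rbind, lapply(hits, function(g)
          stage(paste0("loo[", mode, ":", g, "]"),
                leave_one_out(bins[[g]], null, config$assoc))))
        contribs[[mode]] <- ct
        f <- file.path(config$out_dir, paste0("contributions_", mode, ".tsv"))
        utils::write.table(format_result_table(ct), f, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }

  qc_tab <- do.call(rbind, lapply(qc, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  qc_tab$ref_mismatch <- ref_mismatch
  f <- file.path(config$out_dir, "qc_summary.tsv")
  utils::write.table(qc_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  manifest <- c(
    sprintf("srevar_version\t%s",
            tryCatch(as.character(utils::packageVersion("srevar")),
                     error = function(e) "dev")),
    sprintf("config_digest\t%s", config_digest(config)),
    sprintf("input_md5_%s\t%s", c("fasta", "vcf", "gene_models",
                                  "phenotypes"),
            tools::md5sum(c(config$fasta, config$vcf,
                            config$gene_models_path, config$phenotypes))),
    sprintf("modes\t%s", paste(config$modes, collapse = ",")),
    sprintf("maf_threshold\t%g", config$bin$maf_threshold),
    sprintf("min_bin_size\t%d", config$bin$min_bin_size),
    sprintf("n_samples\t%d", null$n),
    sprintf("mc_seed\t%d", config$assoc$mc_seed))
  f <- file.path(config$out_dir, "manifest.tsv")
  writeLines(manifest, f)
  files <- c(files, f)

  structure(list(results = results, bins = bins_all,
                 contributions = contribs, qc = qc, null_model = null,
                 annotations = ann, files = files, config = config),
            class = "sre_pipeline_result")
}

# stable digest of the run configuration (md5 of its deparsed form)
config_digest <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

# fixed-notation p-value formatting so reruns are byte-identical across
# platforms and locales
format_result_table <- function(tab) {
  for (cl in names(tab))
    if (is.numeric(tab[[cl]]) && !is.integer(tab[[cl]]))
      tab[[cl]] <- sprintf("%.6g", tab[[cl]])
  tab
}

#' @export
print.sre_pipeline_result <- function(x, ...) {
  cat("SRE rare-variant association pipeline result\n")
  for (mode in names(x$results)) {
    r <- x$results[[mode]]
    cat(sprintf("  %-9s %3d gene bins tested, %d significant (FDR<0.05), %d suggestive (FDR<0.1)\n",
                mode, nrow(r), sum(r$significant), sum(r$suggestive)))
  }
  invisible(x)
}

#' Analyze a synthetic cohort in memory
#'
#' Runs annotate -> bin -> SKAT-O -> FDR on a [simulate_cohort()] result
#' (or any list with the same path fields) without writing report files —
#' the lightweight route for simulation studies with many replicate
#' cohorts.
#'
#' @param cohort A `synthetic_cohort` (or list with `fasta_path`,
#'   `gene_model_path`, `motif_paths`, `vcf_path`, `phenotype_path`).
#' @param modes Category modes to run.
#' @param bin An [bin_config()]; `category_mode` is overridden per mode.
#' @param assoc An [assoc_config()].
#' @return List with `results` (per-mode [fdr_table()]s), `bins` (per-mode
#'   bin lists), `null` (the fitted null model), `annotations`.
#' @export
analyze_cohort <- function(cohort, modes = "coding", bin = bin_config(),
                           assoc = assoc_config()) {
  genome <- read_genome(cohort$fasta_path)
  models <- read_gene_models(cohort$gene_model_path)
  motif_sets <- read_motif_sets(cohort$motif_paths[["ESE"]],
                                cohort$motif_paths[["ESS"]],
                                cohort$motif_paths[["ISE"]])
  geno <- read_vcf_dosages(cohort$vcf_path)
  pheno <- read_phenotypes(cohort$phenotype_path)
  stopifnot(identical(geno$samples, pheno$sample_id))
  null <- fit_null_model(pheno$phenotype, pheno[, c("age", "sex")],
                         sample_ids = pheno$sample_id)
  ann <- annotate_variants(geno$variants, genome, models, motif_sets)
  results <- list(); bins_all <- list()
  for (mode in modes) {
    bcfg <- bin
    bcfg$category_mode <- mode
    bins <- suppressWarnings(bin_by_gene(ann, geno, bcfg))
    bins_all[[mode]] <- bins
    results[[mode]] <- if (length(bins))
      fdr_table(lapply(bins, skat_o, null = null, config = assoc))
    else
      data.frame(gene_id = character(0), skat_o_pvalue = numeric(0))
  }
  list(results = results, bins = bins_all, null = null, annotations = ann)
}
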