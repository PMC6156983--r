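#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the association
#' analysis assumes: a cohort of ~700 unrelated samples, genes with
#' multiple exons on their own contigs, biallelic SNPs with a
#' rare-variant-heavy MAF spectrum and Hardy-Weinberg genotypes, SRE
#' hexamer context planted around variant sites, and a continuous
#' phenotype that is linear in age, sex and the planted per-gene burden
#' plus Gaussian noise.
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes, each on its own contig `gene<k>`.
#' @param exons_per_gene,exon_len,intron_len Gene structure (bp).
#' @param n_variants_per_gene SNPs simulated per gene (spaced >= 12 bp so
#'   planted 11-mer windows cannot overwrite each other).
#' @param maf_range Uniform MAF spectrum for non-causal variants; default
#'   `[1/(2 n_samples), 0.05]`.
#' @param causal_genes Character vector of gene ids (e.g. `"gene03"`)
#'   receiving causal variants.
#' @param causal_variants_per_gene Exonic causal loci per causal gene.
#' @param causal_maf_range MAF range for causal loci (kept strictly below
#'   the 0.01 rarity threshold so they enter the bins).
#' @param effect_size Phenotype units per minor allele at causal loci.
#' @param b_age,b_sex Covariate effects (phenotype units per year; per
#'   male). Defaults 0.02 and 0.1 keep the adjustment non-trivial.
#' @param age_mean,age_sd,sex_ratio Cohort demographics (sex_ratio =
#'   fraction male; sex coded 0 = female, 1 = male).
#' @param noise_sd Residual standard deviation of the phenotype.
#' @param sre_density Fraction of non-causal variants whose 11-mer window
#'   gets a category-appropriate motif planted (exonic: ESE or ESS;
#'   intronic: ISE). Causal variants always get an exonic ESE/ESS context.
#' @param n_motifs_per_category Hexamers per motif catalog; the three
#'   catalogs are disjoint by construction.
#' @param pad Flanking sequence before the first and after the last exon.
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @return An object of class `sre_sim_config`.
#' @export
sim_config <- function(n_samples = 695L,
                       n_genes = 20L,
                       exons_per_gene = 3L,
                       exon_len = 150L,
                       intron_len = 300L,
                       n_variants_per_gene = 30L,
                       maf_range = NULL,
                       causal_genes = character(0),
                       causal_variants_per_gene = 4L,
                       causal_maf_range = c(0.002, 0.01),
                       effect_size = 0,
                       b_age = 0.02,
                       b_sex = 0.1,
                       age_mean = 72.95,
                       age_sd = 7.05,
                       sex_ratio = 391 / 695,
                       noise_sd = 1,
                       sre_density = 0.8,
                       n_motifs_per_category = 40L,
                       pad = 50L,
                       seed = 1L) {
  if (is.null(maf_range)) maf_range <- c(1 / (2 * n_samples), 0.05)
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_variants_per_gene = as.integer(n_variants_per_gene),
              maf_range = maf_range, causal_genes = causal_genes,
              causal_variants_per_gene = as.integer(causal_variants_per_gene),
              causal_maf_range = causal_maf_range,
              effect_size = effect_size, b_age = b_age, b_sex = b_sex,
              age_mean = age_mean, age_sd = age_sd, sex_ratio = sex_ratio,
              noise_sd = noise_sd, sre_density = sre_density,
              n_motifs_per_category = as.integer(n_motifs_per_category),
              pad = as.integer(pad), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_samples > 0, n_genes > 0, exons_per_gene > 0, exon_len > 0,
              intron_len > 0, n_variants_per_gene > 0,
              sex_ratio >= 0, sex_ratio <= 1, noise_sd > 0,
              sre_density >= 0, sre_density <= 1,
              maf_range[1] > 0, maf_range[2] <= 0.5, pad >= 6)
  })
  # capacity: variant slots are spaced >= 12 bp, >= 6 bp from region edges
  slots_exon <- cfg$exons_per_gene * max(0, (cfg$exon_len - 11) %/% 12 + 1)
  slots_intron <- (cfg$exons_per_gene - 1L) *
    max(0, (cfg$intron_len - 11) %/% 12 + 1)
  if (slots_exon + slots_intron < cfg$n_variants_per_gene)
    stop("exon/intron lengths too small to hold ", cfg$n_variants_per_gene,
         " variants per gene (capacity ", slots_exon + slots_intron, ")")
  if (length(cfg$causal_genes) && cfg$causal_variants_per_gene >
        slots_exon)
    stop("not enough exonic positions for the requested causal variants")
  structure(cfg, class = "sre_sim_config")
}

#' Plant an SRE hexamer so a SNP's 11-mer window contains it
#'
#' Writes `motif` into `sequence` at a (randomly chosen) offset such that
#' the window `[pos - 5, pos + 5]` contains the motif as a substring.
#'
#' @param sequence Character vector of single bases (a contig under
#'   construction), or a single string.
#' @param pos 1-based SNP position; the 11-mer window must fit within the
#'   sequence.
#' @param motif A hexamer string.
#' @return The modified sequence, in the representation it was given.
#' @export
plant_sre_site <- function(sequence, pos, motif) {
  single <- length(sequence) == 1L && nchar(sequence[1]) > 1L
  seqv <- if (single) strsplit(sequence, "")[[1]] else sequence
  if (nchar(motif) != 6L) stop("motif must be a hexamer")
  if (pos - 5L < 1L || pos + 5L > length(seqv))
    stop(sprintf("11-mer window around pos %d out of bounds (1..%d)",
                 pos, length(seqv)))
  offset <- sample.int(6L, 1L) - 1L        # motif start in window: 0..5
  start <- pos - 5L + offset
  seqv[start:(start + 5L)] <- strsplit(toupper(motif), "")[[1]]
  if (single) paste(seqv, collapse = "") else seqv
}

# disjoint hexamer catalogs drawn without replacement from the 4096-mer space
draw_motif_catalogs <- function(n_per_cat) {
  bases <- c("A", "C", "G", "T")
  all_hex <- apply(expand.grid(rep(list(bases), 6)), 1, paste, collapse = "")
  pick <- sample(all_hex, 3 * n_per_cat)
  list(ESE = pick[seq_len(n_per_cat)],
       ESS = pick[n_per_cat + seq_len(n_per_cat)],
       ISE = pick[2 * n_per_cat + seq_len(n_per_cat)])
}

#' Simulate a synthetic cohort for the SRE association pipeline
#'
#' Writes a FASTA genome (one contig per gene region), BED12 gene models,
#' three disjoint hexamer motif catalogs, a VCF v4.2 with GT genotypes in
#' Hardy-Weinberg proportions, and a phenotype/covariate TSV, and returns
#' the paths together with a truth table of the planted structure.
#'
#' The phenotype is
#' `y_i = b_age age_i + b_sex sex_i + sum_j beta g_ij + eps_i`,
#' `eps ~ N(0, noise_sd^2)`, summing over causal loci. Causal variants are
#' exonic with an ESE/ESS hexamer planted in their 11-mer window and MAFs
#' below the rarity threshold, so they are recovered by the annotation and
#' binning stages.
#'
#' @param config An [sim_config()].
#' @param dir Output directory (created if needed).
#' @return An object of class `synthetic_cohort`: list with `fasta_path`,
#'   `gene_model_path`, `motif_paths` (named ESE/ESS/ISE), `vcf_path`,
#'   `phenotype_path`, `truth` (list of `variants` and `genes` data
#'   frames), and `config`.
#' @export
simulate_cohort <- function(config, dir = tempfile("cohort")) {
  stopifnot(inherits(config, "sre_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_samples
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  bad_causal <- setdiff(config$causal_genes, gene_ids)
  if (length(bad_causal))
    stop("causal gene(s) not in the simulated gene set: ",
         paste(bad_causal, collapse = ", "))
  motifs <- draw_motif_catalogs(config$n_motifs_per_category)

  contig_len <- 2L * config$pad +
    config$exons_per_gene * config$exon_len +
    (config$exons_per_gene - 1L) * config$intron_len

  seqs <- list(); bed <- character(config$n_genes)
  var_rows <- list(); gt_cols <- list()
  sample_ids <- sprintf("S%04d", seq_len(n))
  vid <- 0L

  for (gi in seq_len(config$n_genes)) {
    g <- gene_ids[gi]
    exon_starts <- config$pad + 1L +
      (seq_len(config$exons_per_gene) - 1L) *
        (config$exon_len + config$intron_len)
    exon_ends <- exon_starts + config$exon_len - 1L
    seqv <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)

    # candidate variant slots, spaced 12 bp, 6 bp inside each region
    slot_in <- function(s, e) {
      if (e - s + 1L < 11L) return(integer(0))
      seq(s + 5L, e - 5L, by = 12L)
    }
    exon_slots <- unlist(mapply(slot_in, exon_starts, exon_ends,
                                SIMPLIFY = FALSE))
    intron_slots <- if (config$exons_per_gene > 1L)
      unlist(mapply(slot_in, exon_ends[-config$exons_per_gene] + 1L,
                    exon_starts[-1L] - 1L, SIMPLIFY = FALSE))
    else integer(0)

    causal <- g %in% config$causal_genes
    n_causal <- if (causal) config$causal_variants_per_gene else 0L
    n_rest <- config$n_variants_per_gene - n_causal
    # remaining variants split across territories proportionally to slots
    n_intron <- min(length(intron_slots),
                    round(n_rest * length(intron_slots) /
                            (length(exon_slots) + length(intron_slots))))
    n_exon_rest <- n_rest - n_intron
    if (n_exon_rest > length(exon_slots) - n_causal) {
      n_exon_rest <- length(exon_slots) - n_causal
      n_intron <- n_rest - n_exon_rest
    }
    sample_vec <- function(x, k) x[sample.int(length(x), k)]
    pos_causal <- sort(sample_vec(exon_slots, n_causal))
    pos_exon <- sort(sample_vec(setdiff(exon_slots, pos_causal), n_exon_rest))
    pos_intron <- sort(sample_vec(intron_slots, n_intron))

    plan <- rbind(
      if (n_causal) data.frame(pos = pos_causal, region = "exonic",
                               causal = TRUE),
      if (n_exon_rest) data.frame(pos = pos_exon, region = "exonic",
                                  causal = FALSE),
      if (n_intron) data.frame(pos = pos_intron, region = "intronic",
                               causal = FALSE))
    plan <- plan[order(plan$pos), , drop = FALSE]

    for (k in seq_len(nrow(plan))) {
      vid <- vid + 1L
      p <- plan$pos[k]
      planted <- NA_character_
      if (plan$causal[k] || stats::runif(1) < config$sre_density) {
        planted <- if (plan$region[k] == "exonic") {
          cat_pick <- sample(c("ESE", "ESS"), 1L)
          cat_pick
        } else "ISE"
        seqv <- plant_sre_site(seqv, p, sample(motifs[[planted]], 1L))
      }
      maf <- if (plan$causal[k])
        stats::runif(1, config$causal_maf_range[1], config$causal_maf_range[2])
      else
        stats::runif(1, config$maf_range[1], config$maf_range[2])
      dos <- stats::rbinom(n, 2L, maf)
      ref <- seqv[p]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      var_rows[[vid]] <- data.frame(
        gene_id = g, contig = g, pos = p,
        key = paste0(g, ":", p), rsid = sprintf("sv%05d", vid),
        ref = ref, alt = alt, region = plan$region[k],
        planted_category = planted, causal = plan$causal[k],
        beta = if (plan$causal[k]) config$effect_size else 0,
        maf_drawn = maf, stringsAsFactors = FALSE)
      gt_cols[[vid]] <- dos
    }
    seqs[[g]] <- paste(seqv, collapse = "")

    block_sizes <- paste(rep(config$exon_len, config$exons_per_gene),
                         collapse = ",")
    block_starts <- paste(exon_starts - exon_starts[1], collapse = ",")
    bed[gi] <- paste(g, exon_starts[1] - 1L, exon_ends[config$exons_per_gene],
                     g, 0, "+", exon_starts[1] - 1L,
                     exon_ends[config$exons_per_gene], 0,
                     config$exons_per_gene, block_sizes, block_starts,
                     sep = "\t")
  }

  truth_var <- do.call(rbind, var_rows)
  G_all <- do.call(cbind, gt_cols)
  colnames(G_all) <- truth_var$key

  # ref alleles may have been overwritten by a later neighbouring plant;
  # re-read from the final sequence
  for (g in gene_ids) {
    i <- which(truth_var$gene_id == g)
    sq <- strsplit(seqs[[g]], "")[[1]]
    truth_var$ref[i] <- sq[truth_var$pos[i]]
    resample <- truth_var$alt[i] == truth_var$ref[i]
    for (j in which(resample))
      truth_var$alt[i[j]] <- sample(setdiff(c("A", "C", "G", "T"),
                                            truth_var$ref[i[j]]), 1L)
  }

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$sex_ratio)
  burden <- as.vector(G_all[, truth_var$causal, drop = FALSE] %*%
                        truth_var$beta[truth_var$causal])
  y <- config$b_age * age + config$b_sex * sex + burden +
    stats::rnorm(n, 0, config$noise_sd)

  # ---- write artifacts ----
  fasta_path <- file.path(dir, "genome.fa")
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- gene_ids
  Biostrings::writeXStringSet(genome, fasta_path, width = 60L)

  gene_model_path <- file.path(dir, "genes.bed")
  writeLines(bed, gene_model_path)

  motif_paths <- c(ESE = file.path(dir, "ese_motifs.txt"),
                   ESS = file.path(dir, "ess_motifs.txt"),
                   ISE = file.path(dir, "ise_motifs.txt"))
  for (cat_nm in names(motif_paths))
    writeLines(c(paste0("# ", cat_nm, " hexamer motifs (synthetic catalog)"),
                 motifs[[cat_nm]]), motif_paths[[cat_nm]])

  vcf_path <- file.path(dir, "cohort.vcf")
  write_snp_vcf(vcf_path, truth_var, G_all, sample_ids,
                contig_lengths = stats::setNames(rep(contig_len,
                                                     config$n_genes),
                                                 gene_ids))

  phenotype_path <- file.path(dir, "phenotypes.tsv")
  ph <- data.frame(sample_id = sample_ids,
                   phenotype = sprintf("%.10g", y),
                   age = sprintf("%.10g", age), sex = sex)
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_genes <- data.frame(
    gene_id = gene_ids, contig = gene_ids,
    causal = gene_ids %in% config$causal_genes,
    beta = ifelse(gene_ids %in% config$causal_genes,
                  config$effect_size, 0),
    stringsAsFactors = FALSE)

  structure(list(
    fasta_path = fasta_path, gene_model_path = gene_model_path,
    motif_paths = motif_paths, vcf_path = vcf_path,
    phenotype_path = phenotype_path,
    truth = list(variants = truth_var, genes = truth_genes),
    config = config, dir = dir
  ), class = "synthetic_cohort")
}

# minimal VCF v4.2 writer for biallelic SNPs with GT-only genotypes
write_snp_vcf <- function(path, variants, dosages, sample_ids,
                          contig_lengths) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[dosages + 1L],
                   nrow = nrow(dosages))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=srevar_simulate_cohort",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            contig_lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$contig[i], variants$pos[i], variants$rsid[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt_str[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d genes, %d variants (%s)\n",
              x$config$n_samples, x$config$n_genes,
              nrow(x$truth$variants), x$dir))
  ncausal <- sum(x$truth$genes$causal)
  if (ncausal)
    cat(sprintf("  causal genes: %s (beta = %g)\n",
                paste(x$truth$genes$gene_id[x$truth$genes$causal],
                      collapse = ", "), x$config$effect_size))
  invisible(x)
}
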