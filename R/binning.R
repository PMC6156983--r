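#' Configuration for rare-variant gene binning
#'
#' @param maf_threshold Variants with cohort minor allele frequency below
#'   this (strictly) are "rare"; the conventional 0.01.
#' @param min_bin_size Minimum bin size: by default the total minor-allele
#'   count of the gene across the cohort must reach this value
#'   (`size_rule = "allele_count"`); set `size_rule = "locus_count"` to
#'   require this many distinct loci instead.
#' @param category_mode Which SRE categories select variants into bins:
#'   `"coding"` (ESE + ESS), `"intronic"` (ISE), or `"combined"` (all).
#' @param size_rule See `min_bin_size`.
#' @return An object of class `sre_bin_config`.
#' @export
bin_config <- function(maf_threshold = 0.01,
                       min_bin_size = 5L,
                       category_mode = c("coding", "intronic", "combined"),
                       size_rule = c("allele_count", "locus_count")) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5, min_bin_size >= 1)
  structure(list(maf_threshold = maf_threshold,
                 min_bin_size = as.integer(min_bin_size),
                 category_mode = match.arg(category_mode),
                 size_rule = match.arg(size_rule)),
            class = "sre_bin_config")
}

mode_categories <- function(mode) {
  switch(mode,
         coding = c("ESE", "ESS"),
         intronic = "ISE",
         combined = c("ESE", "ESS", "ISE"))
}

#' Group rare SRE variants into gene bins
#'
#' Selects variants whose SRE categories (for the gene at hand) intersect
#' the mode's category set and whose cohort MAF is strictly positive and
#' strictly below the threshold, groups them by gene, and drops bins below
#' the minimum size. Dosages are folded to minor-allele coding where the
#' alt allele is the major one; missing genotypes count as non-carriers in
#' `total_allele_count` and are mean-imputed (`2 * MAF`) in the association
#' matrix `G`.
#'
#' @param annotations An [annotate_variants()] data frame.
#' @param geno A list from [read_vcf_dosages()] (or any list with
#'   `dosages` and `variants` of the same shape).
#' @param config An [bin_config()].
#' @return List of `gene_bin` objects (fields `gene_id`, `loci`, `rsids`,
#'   `G`, `mafs`, `m_loci`, `total_allele_count`), ordered by gene id.
#'   Attribute `qc`: per-stage variant accounting (see Details).
#'
#' @details The QC attribute partitions the VCF's variants by the furthest
#' stage each reached in this mode:
#' `n_variants = retained + dropped_small_bin + dropped_by_maf +
#' dropped_monomorphic + dropped_by_category + dropped_by_region`.
#' A variant annotated against several genes is counted once, by its most
#' advanced outcome.
#' @export
bin_by_gene <- function(annotations, geno, config = bin_config()) {
  stopifnot(inherits(config, "sre_bin_config"))
  cats_wanted <- mode_categories(config$category_mode)
  dos <- geno$dosages
  keys <- colnames(dos)

  mafs <- apply(dos, 2, compute_maf)
  # fold to minor-allele coding
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  flip <- alt_freq > 0.5
  dos[, flip] <- 2L - dos[, flip]

  ann <- annotations[annotations$key %in% keys, , drop = FALSE]
  cat_list <- strsplit(ann$categories, ",", fixed = TRUE)
  ann_match <- vapply(cat_list, function(x) any(x %in% cats_wanted), logical(1))

  # stage per (variant, gene) row, then per variant take the furthest
  stage <- rep("dropped_by_region", length(keys))
  names(stage) <- keys
  rank_of <- c(dropped_by_region = 0, dropped_by_category = 1,
               dropped_monomorphic = 2, dropped_by_maf = 3,
               dropped_small_bin = 4, retained = 5)
  row_stage <- ifelse(is.na(ann$gene_id) | ann$region == "intergenic",
                      "dropped_by_region",
               ifelse(!ann_match, "dropped_by_category",
               ifelse(mafs[ann$key] == 0, "dropped_monomorphic",
               ifelse(mafs[ann$key] >= config$maf_threshold,
                      "dropped_by_maf", "dropped_small_bin"))))
  # "dropped_small_bin" is provisional: promoted to "retained" per gene below

  qualifies <- row_stage == "dropped_small_bin" & !is.na(ann$gene_id)
  bins <- list()
  for (g in sort(unique(ann$gene_id[qualifies]))) {
    rows <- which(qualifies & ann$gene_id == g)
    k <- unique(ann$key[rows])
    k <- k[order(match(k, keys))]
    G <- dos[, k, drop = FALSE]
    gm <- mafs[k]
    total <- sum(G, na.rm = TRUE)
    size <- if (config$size_rule == "allele_count") total else length(k)
    if (size < config$min_bin_size) next
    for (j in seq_along(k)) {        # mean-impute missing genotypes
      miss <- is.na(G[, j])
      if (any(miss)) G[miss, j] <- 2 * gm[j]
    }
    rsid <- ann$rsid[match(k, ann$key)]
    bins[[g]] <- structure(list(
      gene_id = g, loci = k, rsids = rsid, G = G, mafs = unname(gm),
      m_loci = length(k), total_allele_count = total),
      class = "gene_bin")
  }
  # collapse row stages to variant stages (furthest stage across genes),
  # then mark variants that made it into a surviving bin
  for (i in seq_along(row_stage)) {
    k <- ann$key[i]
    if (rank_of[row_stage[i]] > rank_of[stage[k]]) stage[k] <- row_stage[i]
  }
  retained_keys <- unique(unlist(lapply(bins, `[[`, "loci")))
  stage[names(stage) %in% retained_keys] <- "retained"

  if (!length(bins))
    warning("no gene bin passed the filters in mode '",
            config$category_mode, "'")
  qc <- as.list(table(factor(stage, levels = names(rank_of))))
  qc <- c(list(n_variants = length(keys), mode = config$category_mode), qc)
  attr(bins, "qc") <- qc
  bins
}

#' Bin manifest in the per-mode results layout
#'
#' @param bins List of `gene_bin` objects from [bin_by_gene()].
#' @return Data frame: `gene_id`, `unique_loci`, `variants_across_cohort`.
#' @export
bin_manifest <- function(bins) {
  if (!length(bins))
    return(data.frame(gene_id = character(0), unique_loci = integer(0),
                      variants_across_cohort = integer(0)))
  data.frame(
    gene_id = vapply(bins, `[[`, character(1), "gene_id"),
    unique_loci = vapply(bins, `[[`, integer(1), "m_loci"),
    variants_across_cohort = vapply(bins, function(b)
      as.integer(b$total_allele_count), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.gene_bin <- function(x, ...) {
  cat(sprintf("Gene bin %s: %d loci, %d minor alleles across cohort\n",
              x$gene_id, x$m_loci, x$total_allele_count))
  invisible(x)
}
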