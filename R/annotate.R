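#' Annotate variants with SRE categories
#'
#' For each variant, extracts the 11-mer reference window, classifies the
#' position as exonic/intronic/intergenic against the gene models, and
#' scans the window against the motif catalogs appropriate to the region:
#' ESE and ESS for exonic positions (coding SREs), ISE for intronic ones.
#' Variants matching no motif are retained with empty `categories` so
#' downstream selection (and QC accounting) can see them.
#'
#' Windows are taken from the reference sequence; the alternate allele is
#' not substituted unless `scan_alt = TRUE`, in which case a variant is
#' also annotated if the alt-substituted window matches. Motifs are matched
#' on the forward strand; `stranded = TRUE` scans the reverse complement
#' of the window for genes on the minus strand instead.
#'
#' @param variants Data frame with columns `contig`, `pos`, `ref`, `alt`
#'   and optionally `rsid` (see [read_vcf_dosages()]).
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param models An [gene_models()] object.
#' @param motif_sets Named list with elements `ESE`, `ESS`, `ISE`
#'   ([read_motif_sets()]).
#' @param flank Bases each side of the SNP (window length `2*flank + 1`).
#' @param scan_alt Also scan the window with the alternate allele
#'   substituted at the centre.
#' @param stranded Reverse-complement windows for minus-strand genes.
#' @return Data frame of class `sre_annotation`: one row per
#'   (variant, overlapping gene) plus one row per intergenic variant, with
#'   columns `key` (`contig:pos`), `contig`, `pos`, `rsid`, `gene_id`,
#'   `region`, `categories` (comma-joined, `""` if none), `window`.
#'   Attribute `ref_mismatch`: number of variants whose VCF ref allele
#'   disagreed with the FASTA base (also raised as a warning).
#' @export
annotate_variants <- function(variants, genome, models, motif_sets,
                              flank = 5L, scan_alt = FALSE, stranded = FALSE) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)),
            all(c("ESE", "ESS", "ISE") %in% names(motif_sets)))
  if (is.null(variants$rsid)) variants$rsid <- NA_character_

  windows <- character(nrow(variants))
  for (ctg in unique(variants$contig)) {
    i <- which(variants$contig == ctg)
    windows[i] <- extract_window(genome, ctg, variants$pos[i], flank)
  }
  centre <- flank + 1L
  ref_obs <- substring(windows, centre, centre)
  mism <- which(ref_obs != toupper(variants$ref))
  if (length(mism))
    warning(length(mism), " variant(s) with VCF ref allele differing from ",
            "the FASTA base (FASTA kept), e.g. ",
            paste(utils::head(paste0(variants$contig[mism], ":",
                                     variants$pos[mism]), 3), collapse = ", "))

  regions <- classify_region(variants, models)
  # classify_region returns rows keyed by (contig, pos); map back to rows
  vkey <- paste0(variants$contig, ":", variants$pos)
  rkey <- paste0(regions$contig, ":", regions$pos)
  idx <- match(rkey, vkey)

  win_r <- windows[idx]
  if (stranded && nrow(regions)) {
    on_minus <- !is.na(regions$gene_id) &
      regions$gene_id %in% models$genes$gene_id[models$genes$strand == "-"]
    if (any(on_minus))
      win_r[on_minus] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(win_r[on_minus])))
  }
  alt_win <- NULL
  if (scan_alt) {
    alt_win <- win_r
    substring(alt_win, centre, centre) <- toupper(variants$alt[idx])
  }

  cats <- character(nrow(regions))
  exo <- regions$region == "exonic"
  intr <- regions$region == "intronic"
  if (any(exo)) {
    h_ese <- scan_sre(win_r[exo], motif_sets$ESE)
    h_ess <- scan_sre(win_r[exo], motif_sets$ESS)
    if (scan_alt) {
      h_ese <- h_ese | scan_sre(alt_win[exo], motif_sets$ESE)
      h_ess <- h_ess | scan_sre(alt_win[exo], motif_sets$ESS)
    }
    cc <- character(sum(exo))
    cc[h_ese & h_ess] <- "ESE,ESS"
    cc[h_ese & !h_ess] <- "ESE"
    cc[!h_ese & h_ess] <- "ESS"
    cats[exo] <- cc
  }
  if (any(intr)) {
    h_ise <- scan_sre(win_r[intr], motif_sets$ISE)
    if (scan_alt) h_ise <- h_ise | scan_sre(alt_win[intr], motif_sets$ISE)
    cats[intr] <- ifelse(h_ise, "ISE", "")
  }

  out <- data.frame(
    key = rkey,
    contig = regions$contig,
    pos = regions$pos,
    rsid = variants$rsid[idx],
    gene_id = regions$gene_id,
    region = regions$region,
    categories = cats,
    window = win_r,
    stringsAsFactors = FALSE)
  attr(out, "ref_mismatch") <- length(mism)
  class(out) <- c("sre_annotation", "data.frame")
  out
}
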