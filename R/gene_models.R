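#' Construct gene models from an exon table
#'
#' @param exons Data frame with columns `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based closed exon intervals).
#' @return An object of class `sre_gene_models`: the validated exon table
#'   (sorted by gene and start) plus a per-gene span table.
#' @export
gene_models <- function(exons) {
  stopifnot(is.data.frame(exons),
            all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(exons)))
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  if (any(exons$end < exons$start))
    stop("exon with end < start")
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    if (length(unique(e$contig)) != 1L)
      stop("gene ", g, " spans multiple contigs")
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("gene ", g, " has overlapping or unsorted exons")
  }
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], contig = e$contig[1],
               strand = e$strand[1], start = min(e$start), end = max(e$end),
               n_exons = nrow(e), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(exons = exons, genes = genes), class = "sre_gene_models")
}

#' Read gene models from a BED12 file
#'
#' BED blocks (0-based half-open) are converted to 1-based closed exon
#' intervals at this boundary; all internal interval logic is 1-based.
#'
#' @param path Path to a BED12 file.
#' @return An [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stop("gene model file has no block (exon) structure; BED12 required")
  blk <- rtracklayer::blocks(gr)   # absolute 1-based exon coordinates
  names(blk) <- gr$name
  exons <- do.call(rbind, lapply(seq_along(blk), function(i) {
    b <- blk[[i]]
    data.frame(gene_id = gr$name[i],
               contig = as.character(GenomicRanges::seqnames(gr))[i],
               strand = as.character(GenomicRanges::strand(gr))[i],
               start = GenomicRanges::start(b),
               end = GenomicRanges::end(b),
               stringsAsFactors = FALSE)
  }))
  gene_models(exons)
}

#' Classify variant positions against gene models
#'
#' A position is exonic for a gene if it lies in one of its exons, intronic
#' if it lies strictly between two consecutive exons of that gene (the gene
#' owning both bordering exons), and intergenic if it overlaps no gene.
#' A variant overlapping several genes yields one row per gene.
#'
#' @param variants Data frame with columns `contig` and `pos` (1-based).
#' @param models An [gene_models()] object.
#' @return Data frame: `contig`, `pos`, `region`
#'   (`"exonic"`/`"intronic"`/`"intergenic"`), `gene_id` (`NA` for
#'   intergenic). One row per (variant, overlapping gene), a single
#'   intergenic row otherwise.
#' @export
classify_region <- function(variants, models) {
  stopifnot(inherits(models, "sre_gene_models"),
            all(c("contig", "pos") %in% names(variants)))
  v_gr <- GenomicRanges::GRanges(variants$contig,
                                 IRanges::IRanges(variants$pos, variants$pos))
  e <- models$exons
  e_gr <- GenomicRanges::GRanges(e$contig, IRanges::IRanges(e$start, e$end))
  g <- models$genes
  g_gr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end))

  span_hits <- GenomicRanges::findOverlaps(v_gr, g_gr, ignore.strand = TRUE)
  exon_hits <- GenomicRanges::findOverlaps(v_gr, e_gr, ignore.strand = TRUE)
  exonic_gene <- unique(data.frame(
    v = S4Vectors::queryHits(exon_hits),
    gene_id = e$gene_id[S4Vectors::subjectHits(exon_hits)],
    stringsAsFactors = FALSE))

  out <- data.frame(
    v = S4Vectors::queryHits(span_hits),
    gene_id = g$gene_id[S4Vectors::subjectHits(span_hits)],
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    key_out <- paste(out$v, out$gene_id)
    key_ex <- paste(exonic_gene$v, exonic_gene$gene_id)
    out$region <- ifelse(key_out %in% key_ex, "exonic", "intronic")
  } else {
    out$region <- character(0)
  }
  missing_v <- setdiff(seq_len(nrow(variants)), out$v)
  if (length(missing_v))
    out <- rbind(out, data.frame(v = missing_v, gene_id = NA_character_,
                                 region = "intergenic",
                                 stringsAsFactors = FALSE))
  out <- out[order(out$v, out$gene_id), , drop = FALSE]
  data.frame(contig = variants$contig[out$v], pos = variants$pos[out$v],
             region = out$region, gene_id = out$gene_id,
             stringsAsFactors = FALSE)
}
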