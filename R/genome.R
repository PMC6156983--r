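#' Load a reference genome from FASTA
#'
#' @param path Path to a (optionally indexed) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-
#'   delimited token of each header.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract the reference window around a SNP
#'
#' Returns the uppercase reference sequence covering `flank` bases on each
#' side of the position — the 11-mer for the default `flank = 5` used in
#' SRE motif scanning.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param contig Contig name.
#' @param pos Integer vector of 1-based positions.
#' @param flank Bases on each side of the position.
#' @return Character vector of windows of length `2 * flank + 1`.
#' @export
extract_window <- function(genome, contig, pos, flank = 5L) {
  if (!contig %in% names(genome))
    stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  oob <- pos - flank < 1L | pos + flank > len
  if (any(oob))
    stop(sprintf("window out of bounds for variant %s:%d (contig length %d)",
                 contig, pos[which(oob)[1]], len))
  seq_chr <- as.character(genome[[contig]])
  toupper(substring(seq_chr, pos - flank, pos + flank))
}

#' Scan a window for SRE hexamer motifs
#'
#' An SRE is called when any hexamer of the motif set matches any part of
#' the window: for an 11-mer, the six length-6 substrings at offsets 0-5.
#' Substrings containing `N` never match.
#'
#' @param window Character vector of 11-mer windows (uppercase ACGTN).
#' @param motifs An [motif_set()].
#' @return Logical vector: `TRUE` where any motif matches.
#' @export
scan_sre <- function(window, motifs) {
  stopifnot(inherits(motifs, "sre_motif_set"))
  nc <- nchar(window)
  if (any(nc != 11L))
    stop("window must be an 11-mer (got length ", nc[which(nc != 11L)[1]], ")")
  if (any(grepl("[^ACGTN]", window)))
    stop("window contains characters outside {A,C,G,T,N}")
  hit <- rep(FALSE, length(window))
  for (off in 0:5) {
    hit <- hit | substring(window, off + 1L, off + 6L) %in% motifs$hexamers
  }
  hit
}
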