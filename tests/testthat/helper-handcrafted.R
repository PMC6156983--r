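# A fully deterministic 20-variant fixture: one contig, two genes, motif
# catalogs of one hexamer each, and hand-assigned genotypes, so every
# filter-stage count can be derived by hand.
#
# Contig cA (800 bp, repeating ACGT background, free of the three motifs):
#   gA: exons [101,200], [301,400]   (intron 201-300)
#   gB: exons [501,560], [601,660]   (intron 561-600)
# Variants (n = 200 samples, so 1 allele = MAF 0.0025; "het k" = k
# heterozygote carriers):
#   v1  cA:50   intergenic                         -> region
#   v2  cA:700  intergenic                         -> region
#   v3  cA:120  exonic gA, no motif                -> category
#   v4  cA:250  intronic gA, no motif              -> category
#   v5  cA:150  exonic gA, ESE, no carriers        -> monomorphic
#   v6  cA:135  exonic gA, ESE, het 8 (MAF 0.02)   -> maf
#   v7  cA:165  exonic gA, ESE, het 1              -> gA coding bin
#   v8  cA:180  exonic gA, ESS, het 2              -> gA coding bin
#   v9  cA:320  exonic gA, ESE, hom 1              -> gA coding bin
#   v10 cA:340  exonic gA, ESE, het 1              -> gA coding bin (6 alleles)
#   v11 cA:260  intronic gA, ISE, het 1            -> coding: category
#   v12 cA:280  intronic gA, ISE, het 1               (gA ISE: 2 alleles)
#   v13 cA:520  exonic gB, ESE, het 1              -> gB coding: 3 alleles
#   v14 cA:540  exonic gB, ESS, het 1
#   v15 cA:620  exonic gB, ESE, het 1
#   v16 cA:580  intronic gB, ISE, het 1
#   v17 cA:640  exonic gB, no motif                -> category
#   v18 cA:110  exonic gA, ESE, het 4 (MAF exactly 0.01) -> maf (strict <)
#   v19 cA:360  exonic gA, no motif                -> category
#   v20 cA:440  intergenic (between genes)         -> region
make_handcrafted_fixture <- function(dir = tempfile("handcrafted")) {
  dir.create(dir, showWarnings = FALSE)
  n <- 200L
  seqv <- rep(c("A", "C", "G", "T"), 200)

  plant_at <- function(seqv, pos, motif)
    `[<-`(seqv, pos:(pos + 5L), strsplit(motif, "")[[1]])
  for (p in c(150, 135, 165, 320, 340, 110)) seqv <- plant_at(seqv, p, "AAAAAA")
  for (p in c(180, 540)) seqv <- plant_at(seqv, p, "CCCCCC")
  for (p in c(260, 280, 580)) seqv <- plant_at(seqv, p, "GGGGGG")
  for (p in c(520, 620)) seqv <- plant_at(seqv, p, "AAAAAA")

  fasta <- file.path(dir, "genome.fa")
  g <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(g) <- "cA"
  Biostrings::writeXStringSet(g, fasta, width = 60)

  bed <- file.path(dir, "genes.bed")
  writeLines(c(
    paste("cA", 100, 400, "gA", 0, "+", 100, 400, 0, 2, "100,100", "0,200",
          sep = "\t"),
    paste("cA", 500, 660, "gB", 0, "+", 500, 660, 0, 2, "60,60", "0,100",
          sep = "\t")), bed)

  pos <- c(50, 700, 120, 250, 150, 135, 165, 180, 320, 340,
           260, 280, 520, 540, 620, 580, 640, 110, 360, 440)
  carriers <- list(integer(0), integer(0), 1L, 2L, integer(0), 1:8, 3L,
                   4:5, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15:18,
                   19L, 20L)
  hom <- c(rep(FALSE, 8), TRUE, rep(FALSE, 11))   # v9 is one homozygote

  vcf <- file.path(dir, "cohort.vcf")
  ord <- order(pos)
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=cA,length=800>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("S%04d", 1:n)),
                   collapse = "\t"))
  for (i in ord) {
    gt <- rep("0/0", n)
    gt[carriers[[i]]] <- if (hom[i]) "1/1" else "0/1"
    ref <- seqv[pos[i]]
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    lines <- c(lines, paste(c("cA", pos[i], sprintf("v%d", i), ref, alt,
                              ".", "PASS", ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, vcf)
  list(fasta = fasta, bed = bed, vcf = vcf, dir = dir)
}
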