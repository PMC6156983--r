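#' Read biallelic SNP genotypes from a VCF
#'
#' Parses the GT field into per-sample alt-allele dosage counts
#' (0/1/2, `NA` for missing). Only biallelic SNP records are kept; others
#' are dropped with a message.
#'
#' @param path Path to a VCF (v4.x) file, plain or gzipped.
#' @return List with `variants` (data frame: `key`, `contig`, `pos`,
#'   `rsid`, `ref`, `alt`), `dosages` (samples x variants integer matrix,
#'   columns named by `key`), and `samples`.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  if (!all(snp))
    message("dropping ", sum(!snp), " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  dos <- (allele1 == "1") + (allele2 == "1")
  dos[allele1 == "." | allele2 == "." | is.na(gt)] <- NA_integer_
  dos <- t(dos)   # samples x variants
  key <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  colnames(dos) <- key
  variants <- data.frame(
    key = key,
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    rsid = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]),
                  NA_character_, fix[, "ID"]),
    ref = ref[snp],
    alt = alt[snp],
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants, dosages = dos, samples = rownames(dos))
}

#' Minor allele frequency from a dosage vector
#'
#' The alt-allele frequency is `sum(d) / (2 * n_nonmissing)`; the minor
#' allele frequency is its fold-back `min(p, 1 - p)`.
#'
#' @param dosages Integer vector in `{0, 1, 2, NA}`.
#' @return The minor allele frequency (a single number in `[0, 0.5]`).
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all genotypes missing")
  if (any(!dosages[ok] %in% 0:2)) stop("dosages must be in {0, 1, 2, NA}")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with header `sample_id`, `phenotype`, `age`, `sex`
#' (0 = female, 1 = male).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those columns.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "age", "sex")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  ph
}
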