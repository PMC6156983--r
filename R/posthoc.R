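#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (the `"BH"`/`"fdr"` method of [stats::p.adjust()]):
#' with sorted p-values, `q_i = min_{j >= i} (m p_j / j)`, clipped at 1 and
#' returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))  # all 0.05
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-mode FDR results table
#'
#' @param results List of [skat_o()] results (one per gene in the mode's
#'   family) or a data frame with columns `gene_id`, `unique_loci`,
#'   `variants_across_cohort`, `skat_o_pvalue`.
#' @param alpha_significant,alpha_suggestive FDR thresholds for the
#'   significance calls (conventionally 0.05 and 0.1).
#' @return Data frame: `gene_id`, `unique_loci`, `variants_across_cohort`,
#'   `skat_o_pvalue`, `fdr_pvalue`, `significant`, `suggestive`, sorted by
#'   raw p. The BH family is exactly the genes in `results` — the bins that
#'   survived filtering in the current category mode.
#' @export
fdr_table <- function(results, alpha_significant = 0.05,
                      alpha_suggestive = 0.1) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    tab <- data.frame(
      gene_id = vapply(results, `[[`, character(1), "gene_id"),
      unique_loci = vapply(results, `[[`, integer(1), "m_loci"),
      variants_across_cohort = vapply(results, function(x)
        as.integer(x$total_allele_count), integer(1)),
      skat_o_pvalue = vapply(results, `[[`, numeric(1), "p_skato"),
      stringsAsFactors = FALSE)
  }
  tab$fdr_pvalue <- bh_fdr(tab$skat_o_pvalue)
  tab$significant <- tab$fdr_pvalue < alpha_significant
  tab$suggestive <- tab$fdr_pvalue < alpha_suggestive
  tab <- tab[order(tab$skat_o_pvalue), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-locus leave-one-out contribution analysis
#'
#' Reruns the gene-level test with each locus removed in turn, to gauge the
#' locus's contribution to the association: a locus whose removal makes the
#' p-value larger ("less significant") carries signal; one whose removal
#' makes it smaller absorbs noise.
#'
#' @param bin A `gene_bin` with at least 2 loci.
#' @param null The [fit_null_model()] object.
#' @param config An [assoc_config()].
#' @return Data frame of class `sre_contribution`: `gene_id`, `locus`,
#'   `rsid`, `allele_count`, `baseline_p`, `loo_p`, `direction`
#'   (`"less_significant"` / `"more_significant"` after removal).
#' @export
leave_one_out <- function(bin, null, config = assoc_config()) {
  stopifnot(inherits(bin, "gene_bin") || is.list(bin))
  m <- ncol(bin$G)
  if (m < 2L) stop("leave-one-out needs at least 2 loci (gene ",
                   bin$gene_id, " has ", m, ")")
  baseline <- skat_o(bin, null, config)$p_skato
  loo_p <- numeric(m)
  for (j in seq_len(m)) {
    sub <- bin
    sub$G <- bin$G[, -j, drop = FALSE]
    sub$mafs <- bin$mafs[-j]
    sub$loci <- bin$loci[-j]
    sub$rsids <- bin$rsids[-j]
    sub$m_loci <- m - 1L
    sub$total_allele_count <- sum(sub$G)
    loo_p[j] <- skat_o(sub, null, config)$p_skato
  }
  out <- data.frame(
    gene_id = bin$gene_id,
    locus = bin$loci,
    rsid = if (!is.null(bin$rsids)) bin$rsids else NA_character_,
    allele_count = colSums(bin$G),
    baseline_p = baseline,
    loo_p = loo_p,
    direction = ifelse(loo_p > baseline, "less_significant",
                       ifelse(loo_p < baseline, "more_significant",
                              "unchanged")),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("sre_contribution", "data.frame")
  out
}
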