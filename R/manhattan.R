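#' Gene-level Manhattan plot table
#'
#' Per-gene plotting coordinates (`-log10` raw p against genomic midpoint)
#' with the two horizontal reference values of the conventional display:
#' the nominal `p = 0.05` line and the FDR line — the largest raw p whose
#' BH-adjusted value is below 0.05.
#'
#' @param results An [fdr_table()] data frame.
#' @param gene_positions Data frame with `gene_id`, `contig`, `start`,
#'   `end` (e.g. `models$genes` from [gene_models()]).
#' @return Data frame: `gene_id`, `contig`, `midpoint`, `xpos` (cumulative
#'   coordinate across contigs), `neglog10_p`, `significant`. Attributes
#'   `line_nominal` (`-log10 0.05`) and `line_fdr` (`-log10` of the FDR
#'   cutoff in raw-p units, `NA` when no gene passes).
#' @export
manhattan_data <- function(results, gene_positions) {
  stopifnot(nrow(results) >= 1,
            all(c("gene_id", "contig", "start", "end") %in%
                  names(gene_positions)))
  idx <- match(results$gene_id, gene_positions$gene_id)
  dropped <- results$gene_id[is.na(idx)]
  if (length(dropped)) {
    warning("gene(s) missing positions dropped from plot: ",
            paste(dropped, collapse = ", "))
    results <- results[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  gp <- gene_positions[idx, , drop = FALSE]
  mid <- (gp$start + gp$end) / 2

  contigs <- unique(gene_positions$contig)
  clen <- vapply(contigs, function(ctg)
    max(gene_positions$end[gene_positions$contig == ctg]), numeric(1))
  offset <- stats::setNames(c(0, cumsum(clen))[seq_along(contigs)], contigs)

  out <- data.frame(
    gene_id = results$gene_id,
    contig = gp$contig,
    midpoint = mid,
    xpos = offset[gp$contig] + mid,
    neglog10_p = -log10(results$skat_o_pvalue),
    significant = results$significant,
    row.names = NULL, stringsAsFactors = FALSE)

  passing <- results$skat_o_pvalue[results$fdr_pvalue < 0.05]
  attr(out, "line_nominal") <- -log10(0.05)
  attr(out, "line_fdr") <- if (length(passing)) -log10(max(passing)) else NA_real_
  out
}

#' Render the Manhattan plot
#'
#' Thin ggplot2 wrapper over [manhattan_data()]; the data table is the
#' tested artifact, the rendering is cosmetic.
#'
#' @param results An [fdr_table()] data frame.
#' @param gene_positions See [manhattan_data()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, gene_positions) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  md <- manhattan_data(results, gene_positions)
  gg <- ggplot2::ggplot(md, ggplot2::aes(x = xpos, y = neglog10_p,
                                         colour = contig)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(md, "line_nominal"),
                        colour = "blue", linetype = 2) +
    ggplot2::labs(x = "gene position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (is.finite(attr(md, "line_fdr")))
    gg <- gg + ggplot2::geom_hline(yintercept = attr(md, "line_fdr"),
                                   colour = "red", linetype = 2)
  gg
}
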