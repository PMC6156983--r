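# srevar

Gene-based association testing of **rare variants in splicing regulatory
elements (SREs)** against a continuous phenotype.

## The problem

Alternative splicing is steered by short sequence elements — exonic
splicing enhancers (ESE), exonic splicing silencers (ESS), intronic
splicing enhancers (ISE) — commonly catalogued as hexamer motifs. Rare
SNPs that fall in such elements are natural candidates for functional
effects, but individually they are far too rare to test. The standard
remedy is gene-level collapsing: group a gene's rare variants
(cohort MAF < 0.01) into one bin and test the bin jointly. `srevar`
implements that analysis end to end for quantitative endophenotypes
(for example, an FDG-PET-derived global measure of cortical glucose
metabolism) with age and sex adjustment, for cohorts of WGS-genotyped,
unrelated samples.

Who it is for: statistical geneticists and imaging-genetics analysts who
want a self-contained, tested implementation of SRE-restricted
rare-variant association — including the test itself, not a wrapper.

## The method

* **Annotation** — for each SNP the 11-mer reference window (±5 bp) is
  scanned against the three hexamer catalogs; a match of any hexamer to
  any part of the window calls the category. ESE/ESS apply to exonic
  SNPs, ISE to intronic SNPs (assigned to the gene owning both bordering
  exons).
* **Binning** — rare (MAF < 0.01, cohort-internal, minor-allele folded)
  SRE variants are grouped per gene under a category mode — *coding*
  (ESE+ESS), *intronic* (ISE), or *combined* — and a bin is tested only
  if it carries ≥ 5 minor alleles cohort-wide.
* **SKAT-O** — with weighted genotypes `Z = G diag(w)`,
  `w_j = dbeta(MAF_j; 1, 25)`, residuals `r` of phenotype on
  `[1, age, sex]`, and score `S = Z'r`, the statistic family
  `Q_rho = (1-rho) Σ S_j² + rho (Σ S_j)²` spans the variance-component
  (`rho = 0`) and burden (`rho = 1`) tests over the grid
  `rho ∈ {0, 0.1², …, 0.5², 0.5, 1}`. Per-rho tails are
  mixtures of chi-squares evaluated by Davies' method; the combined
  p-value of the grid minimum is computed by an exact conditional
  construction (see the methods vignette). Cohorts under 200 samples
  automatically get an exact finite-sample null that accounts for the
  estimated residual variance.
* **FDR** — Benjamini–Hochberg within each mode; FDR < 0.05 significant,
  FDR < 0.1 suggestive.
* **Leave-one-out** — per-locus contribution analysis: each locus removed
  in turn, the bin retested, and the direction of the p-value change
  reported.

A synthetic cohort generator (`simulate_cohort()`) produces FASTA, BED12
gene models, motif catalogs, VCF and phenotype tables with planted causal
genes and a truth table, so the entire pipeline is testable without any
restricted data.

## Worked example

```r
library(srevar)

cfg <- sim_config(n_samples = 500, n_genes = 8, n_variants_per_gene = 12,
                  maf_range = c(0.001, 0.01),
                  causal_genes = "gene03", causal_variants_per_gene = 4,
                  effect_size = 0.8, seed = 7002)
cohort <- simulate_cohort(cfg, dir = "example_cohort")

pc <- pipeline_config(cohort$fasta_path, cohort$vcf_path,
                      cohort$gene_model_path, cohort$phenotype_path,
                      cohort$motif_paths, out_dir = "example_out")
res <- run_pipeline(pc)
res
#> SRE rare-variant association pipeline result
#>   coding      8 gene bins tested, 1 significant (FDR<0.05), 1 suggestive (FDR<0.1)
#>   intronic    8 gene bins tested, 0 significant (FDR<0.05), 0 suggestive (FDR<0.1)
#>   combined    8 gene bins tested, 0 significant (FDR<0.05), 0 suggestive (FDR<0.1)

head(res$results$coding, 3)
#>   gene_id unique_loci variants_across_cohort skat_o_pvalue fdr_pvalue significant suggestive
#> 1  gene03           4                     19   0.002880071 0.02304057        TRUE       TRUE
#> 2  gene05           4                     25   0.110090492 0.44036197       FALSE      FALSE
#> 3  gene08           4                     16   0.410022646 0.78124351       FALSE      FALSE

res$contributions$coding[, c("rsid", "allele_count", "baseline_p", "loo_p", "direction")]
#>      rsid allele_count  baseline_p        loo_p        direction
#> 1 sv00026            8 0.002880071 0.0059900110 less_significant
#> 2 sv00028            3 0.002880071 0.0374441611 less_significant
#> 3 sv00035            5 0.002880071 0.0309857660 less_significant
#> 4 sv00036            3 0.002880071 0.0003461766 more_significant
```

The planted causal gene (`gene03`, four causal ESE/ESS loci, β = 0.8 per
minor allele, 19 minor alleles across the cohort) is recovered as the only
FDR-significant gene in the coding-mode scan at FDR = 0.023. The per-locus
leave-one-out table reads the association apart: removing any of three of
the loci makes the gene's p-value *less* significant (they carry signal),
while the fourth locus absorbs variation — removing it strengthens the
association. `example_out/` holds the
per-mode results TSVs, the contribution table, a QC summary with exact
per-stage variant accounting, and a run manifest with input checksums.
`plot_manhattan(res$results$coding, read_gene_models(cohort$gene_model_path)$genes)`
draws the gene-level Manhattan plot with the nominal-0.05 and FDR-0.05
reference lines.

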