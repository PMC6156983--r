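---
title: "Rare-variant association testing for splicing regulatory elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant association testing for splicing regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srevar)
```

## The analysis

`srevar` implements a gene-based rare-variant association analysis focused
on splicing regulatory elements (SREs). The motivating setting is an
imaging-genetics cohort: whole-genome SNP genotypes for a few hundred
unrelated subjects and a continuous, approximately Gaussian endophenotype
(for instance a global cortical glucose-metabolism SUVR from FDG-PET),
with age and sex as covariates. The hypothesis is that rare variants that
disturb splicing-regulatory sequence — exonic splicing enhancers (ESE),
exonic splicing silencers (ESS) and intronic splicing enhancers (ISE) —
carry phenotypic signal that genome-wide rare-variant scans dilute, and
that restricting the gene-level tests to SRE sites therefore gains power
and interpretability.

The pipeline has five stages:

1. **SRE annotation.** For each biallelic SNP the 11-mer reference window
   (5 bp each side) is extracted and scanned against hexamer catalogs; a
   category is called when any catalog 6-mer matches any of the six
   offsets of the window. ESE/ESS apply to exonic SNPs, ISE to intronic
   SNPs; an intronic SNP belongs to the gene owning both exons bordering
   its intron.
2. **Binning.** Variants with cohort minor allele frequency (MAF)
   strictly below 0.01 whose categories match the chosen mode (coding =
   ESE+ESS, intronic = ISE, combined = all) are grouped by gene. A bin
   enters testing only if its total minor-allele count across the cohort
   is at least 5.
3. **Association.** Each bin is tested with SKAT-O against the phenotype
   residualized on intercept, age and sex.
4. **Multiple testing.** Benjamini–Hochberg FDR within each category
   mode, over exactly the genes that survived binning in that mode;
   FDR < 0.05 is significant, FDR < 0.1 suggestive.
5. **Contribution analysis.** For genes of interest, each locus is
   removed in turn and the test rerun; removals that make the p-value
   larger mark loci that carry the signal.

## The test statistic

Let $G$ be the $n \times m$ matrix of minor-allele dosages for a gene's
bin, $w_j = \mathrm{dbeta}(\hat{\mathrm{MAF}}_j; 1, 25)$ the usual
rare-variant up-weighting, $Z = G\,\mathrm{diag}(w)$, and $r$ the OLS
residuals of the phenotype on $X = [1, \text{age}, \text{sex}]$ with
$\hat\sigma^2 = r^\top r/(n-3)$. With the score vector $S = Z^\top r$,
the family

$$Q_\rho = (1-\rho)\sum_j S_j^2 + \rho\Big(\sum_j S_j\Big)^2,
  \qquad \rho \in \{0, 0.1^2, \ldots, 0.5^2, 0.5, 1\},$$

interpolates between the variance-component (SKAT, $\rho = 0$) and
burden ($\rho = 1$) statistics. Under the null, $Q_\rho/\hat\sigma^2$ is
asymptotically a positive mixture of 1-df chi-squares with coefficients
the eigenvalues of $R_\rho^{1/2} Z^\top P_0 Z R_\rho^{1/2}$, where $P_0$
is the projection orthogonal to $X$ and $R_\rho$ the compound-symmetry
matrix. Tail probabilities come from Davies' characteristic-function
inversion (`chi2mix_sf()`, backed by `mgcv::psum.chisq`) with a Liu
moment-matching fallback.

The reported `p_skato` is the p-value of the grid minimum
$T = \min_\rho p_{\rho}$. We compute it by an **exact conditional
construction** rather than the usual quantile-rescaling approximation:
conditioning on the burden component $\eta = \mathbf{1}^\top S$ (whose
null law is $N(0, \hat\sigma^2\,\mathbf{1}^\top K \mathbf{1})$,
$K = Z^\top P_0 Z$), the event "accept at every $\rho$" is

$$\eta^2 < q_1 \quad\text{and}\quad
  |S|^2 < \min_{\rho<1}\frac{q_\rho - \rho\,\eta^2}{1-\rho},$$

one-dimensional in $|S|^2$, whose conditional law is a noncentral
chi-square mixture — again a Davies computation, with the per-$\rho$
quantiles $q_\rho$ obtained by numerically inverting the Davies tail
instead of a moment-matched approximation. The outer integral over
$\eta^2/\tau^2 \sim \chi^2_1$ has a finite upper limit, so no truncation
heuristics are involved. The result is clamped to the
$[\min_\rho p_\rho,\ |grid| \cdot \min_\rho p_\rho]$ bounds that hold for
any min-p combination.

### Small cohorts: the exact finite-sample null

The chi-square mixture treats $\hat\sigma^2$ as fixed. For cohorts of a
few dozen samples the dependence between $S$ and $\hat\sigma^2$ is not
negligible: in a residual-permutation experiment at $n = 50$ the plug-in
p deviates by up to ~0.02 — two orders of magnitude above Monte-Carlo
noise at 200,000 permutations. Under Gaussian residuals, however, the
event $Q_\rho/\hat\sigma^2 > q$ is a sign condition on a single quadratic
form,

$$\sum_k (\lambda_k - q/\nu)\,\chi^2_{1,k} \;-\; (q/\nu)\,\chi^2_{\nu - m}
  \;>\; 0, \qquad \nu = n - 3,$$

so the per-$\rho$ tails have an exact mixed-sign Davies evaluation (an
F-ratio-type null), and the optimal-$\rho$ combination is evaluated on
the exact joint law of $(S, \hat\sigma^2)$ — the shared component
$S^\top K^{-1} S \sim \chi^2_m$ plus an independent
$\chi^2_{\nu-m}$ — by a seeded Monte-Carlo integration over the
$m{+}1$-dimensional sufficient statistic (4 million draws by default;
the global RNG state is saved and restored, so results are deterministic
and independent of the caller's seed). `skat_o()` switches to this path
automatically below 200 samples (`assoc_config(small_sample=)`); at
cohort scale the plug-in asymptotic path is used, where the correction is
negligible and speed matters. In our permutation experiments the exact
path agrees with a 200,000-permutation rank-based min-p oracle within
two Monte-Carlo standard errors on every instance tried.

### Numerical choices

* Davies inversion is run at absolute accuracy $10^{-6}$ inside the
  association test (and $10^{-9}$ in the standalone `chi2mix_sf()`
  default); failures fall back to Liu moment matching and are flagged in
  the result's diagnostics.
* Kernel eigenvalues below $10^{-10} \times \lambda_{\max}$ are dropped
  (numerical rank).
* A single-locus bin short-circuits: all $\rho$ coincide and the result
  is the single-variant score test.
* Duplicated genotype columns are retained (weights can still differ via
  MAF) with a warning naming the correlated columns.
* Probabilities are clipped to $(10^{-300}, 1]$.

## Binning conventions

"Minimum bin size of five variants across samples" is read as a total
minor-allele-count threshold ($\geq 5$ carriers' alleles cohort-wide),
which matches results tables in this literature where a
"variants across cohort" column exceeds the "unique loci" column; a
locus-count reading is available via
`bin_config(size_rule = "locus_count")`. MAF is computed within the
analyzed cohort, folded to the minor allele (columns whose alt allele is
major are re-coded), with strict inequality at the 0.01 threshold;
monomorphic sites are excluded. Missing genotypes count as non-carriers
in the allele totals and are mean-imputed ($2 \times$ MAF) in the
association matrix. A variant overlapping several genes is annotated once
per gene and may enter several bins; the QC accounting then classifies
each variant by the furthest stage it reached across genes, so the
per-stage counts always sum to the VCF's variant total.

Windows are scanned on the forward reference strand without substituting
the alternate allele — the motif catalogs describe reference sequence
context, and this matches how such annotation is done upstream of
BioBin-style binning; `scan_alt = TRUE` and `stranded = TRUE` are
available for exploration. When the VCF ref allele disagrees with the
FASTA base the FASTA is kept, a warning is raised, and the count is
reported in the QC summary.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the package ships a
generator (`simulate_cohort()`) that emulates the statistical structure
the analysis assumes, with a truth table for testing:

* one contig per gene region, named `gene<k>`; gene models written as
  BED12 (0-based, half-open) and converted to 1-based closed intervals at
  the parsing boundary — the conversion is covered by explicit
  off-by-one tests;
* genotypes i.i.d. Binomial(2, MAF) — Hardy–Weinberg, no linkage
  disequilibrium, since the association model treats loci within a bin
  exchangeably and LD is out of scope;
* phenotype $y_i = 0.02\,\mathrm{age}_i + 0.1\,\mathrm{sex}_i +
  \sum_{j \in \text{causal}} \beta g_{ij} + \varepsilon_i$ with
  $\varepsilon \sim N(0, \mathrm{noise\_sd}^2)$; demographics default to
  age $\sim N(72.95, 7.05^2)$ and 56% male, matching the cohort
  composition this design emulates; sex is coded 0 = female, 1 = male;
* three disjoint hexamer catalogs (40 motifs each by default) drawn
  without replacement from the 4096 hexamers, so category assignment in
  tests is never ambiguous;
* causal variants are exonic, rare (MAF drawn below 0.01) and always get
  an ESE or ESS hexamer planted in their 11-mer window, so the
  annotation stage must recover them before they can contribute signal;
* a fraction `sre_density` (default 0.8) of the remaining variants get a
  category-appropriate motif planted. This emulates the *post-selection*
  variant stream the association stage consumes — the real analysis
  filters to SRE sites before binning — while leaving enough unannotated
  variants to exercise the category filter;
* variants are spaced at least 12 bp apart so planted 11-mers cannot
  overwrite each other.

The default MAF spectrum is uniform on $[1/(2n), 0.05]$, rare-heavy but
with a common tail so the MAF filter is exercised. The generator is fully
deterministic given `seed` (byte-identical files).

**What passing tests do not show.** The generator has no LD, no
population structure, no genotyping error, no indels or multi-allelic
sites, and Gaussian phenotype noise. Calibration and power results on it
validate the statistical machinery, not robustness to those real-data
features.

## Simulation studies in the test suite

Problem sizes were chosen to give the studies stable behaviour while
keeping a default test run comfortable on a laptop:

* *Type-I error*: null cohorts of $n = 695$, 40 genes each, all variants
  rare (MAF $\sim U(0.001, 0.01)$), until 2,000 gene tests accumulate;
  the 5% rejection rate is required to sit in the 99% binomial band and
  the p-values to pass a Kolmogorov–Smirnov uniformity check.
* *Permutation agreement*: 20 small instances ($n = 50$, $m \in
  \{2,3,5\}$, common MAFs so the score is in its Gaussian regime, null
  phenotypes so the observed p is moderate) against a 200,000-permutation
  rank-based min-p oracle, within 3 Monte-Carlo SE.
* *Power / recovery*: 50 replicates at $n = 500$, $\beta = 0.8$,
  noise SD 1, 12 variants per gene. With four causal loci the causal
  gene is top-ranked in a clear majority of replicates (0.76 in the
  design pilot); with a single causal locus the leave-one-out analysis
  ranks its removal most p-increasing in a clear majority (0.77 in the
  pilot). The per-gene variant count matters: with 30 variants per gene
  the causal signal is diluted across many null loci and the top-rank
  fraction drops toward a bare majority.

## Open design points, resolved

* **Overlapping genes** (a SNP exonic for one gene, intronic for
  another): both annotations are kept, one row per gene; nothing is
  silently resolved.
* **BH family size**: FDR is adjusted within each category mode over
  exactly the bins tested in that mode. Published analyses of this type
  do not report their family sizes, so no attempt is made to reproduce
  any specific FDR value.
* **Leave-one-out granularity**: a *locus* is removed (all carriers at
  that position), not individual carriers.
* **Category overlap across modes**: combined-mode loci counts are
  asserted to be at least the per-mode maximum, not the per-mode sum — a
  locus can carry both a coding and (for another gene) an intronic
  annotation, and exonic windows can match both ESE and ESS.

## Limitations

Binary phenotypes, kinship adjustment, dosage uncertainty, X-chromosome
handling and indels are out of scope. The exact small-sample path costs a
few seconds per gene (Monte-Carlo integration) and is therefore reserved
for small cohorts, where it matters. P-values from the asymptotic path at
very sparse bins (a handful of carriers) inherit the usual score-test
discreteness; the bin-size filter is the guard against the worst of it.
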