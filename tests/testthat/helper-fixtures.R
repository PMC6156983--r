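# Shared fixture builders; everything generated in code under fixed seeds.

# covariates + null phenotype + fitted null model
make_null_data <- function(n, seed = 1, noise_sd = 1) {
  set.seed(seed)
  cov <- data.frame(age = rnorm(n, 73, 7), sex = rbinom(n, 1, 0.55))
  y <- 0.02 * cov$age + 0.1 * cov$sex + rnorm(n, 0, noise_sd)
  list(cov = cov, y = y, null = fit_null_model(y, cov))
}

# polymorphic dosage matrix + gene_bin-shaped list
make_toy_bin <- function(n, m, maf_range = c(0.05, 0.3), seed = 1,
                         gene_id = "gTOY") {
  set.seed(seed)
  repeat {
    mafs <- runif(m, maf_range[1], maf_range[2])
    G <- sapply(mafs, function(p) rbinom(n, 2, p))
    G <- matrix(G, nrow = n)
    if (all(apply(G, 2, var) > 0)) break
  }
  emp <- colMeans(G) / 2
  structure(list(gene_id = gene_id, loci = sprintf("c1:%d", seq_len(m) * 20),
                 rsids = sprintf("rs%03d", seq_len(m)), G = G,
                 mafs = emp, m_loci = m, total_allele_count = sum(G)),
            class = "gene_bin")
}

# weighted burden score-test p, written independently of skat_o
burden_score_p <- function(G, mafs, null) {
  w <- dbeta(mafs, 1, 25)
  b <- as.vector(G %*% w)
  S <- sum(b * null$residuals)
  b1 <- null$project(b)
  pchisq(S^2 / (null$sigma2 * sum(b1^2)), df = 1, lower.tail = FALSE)
}

# default small synthetic cohort used by several annotation/binning tests
default_test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 150, n_genes = 5,
                        causal_genes = "gene02", effect_size = 0.5,
                        maf_range = c(0.002, 0.03), seed = 42)
      cache <<- simulate_cohort(cfg, dir = file.path(tempdir(), "tc42"))
    }
    cache
  }
})
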