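#' Configuration for the gene-level association test
#'
#' @param rho_grid Mixing weights between the variance-component kernel
#'   statistic (`rho = 0`) and the burden statistic (`rho = 1`). The default
#'   grid `(0, 0.1^2, ..., 0.5^2, 0.5, 1)` is the standard choice for the
#'   optimal test.
#' @param weight_beta Length-2 vector `(a1, a2)` of Beta-density parameters
#'   for the per-variant MAF weights `w_j = dbeta(MAF_j, a1, a2)`; the
#'   default `(1, 25)` up-weights the rarest variants.
#' @param tol Absolute accuracy requested from the mixture-tail routine.
#' @param small_sample `"auto"` (exact finite-sample null below
#'   `small_n_cutoff` samples), `"always"`, or `"never"`. The exact path
#'   accounts for the dependence between the score statistic and the
#'   estimated residual variance (an F-ratio-type null instead of the
#'   plug-in chi-square mixture), which matters for cohorts of a few dozen
#'   samples and is negligible at biobank scale.
#' @param small_n_cutoff Sample-size threshold for `small_sample = "auto"`.
#' @param mc_iter Monte-Carlo size for the exact small-sample optimal-rho
#'   combination (the per-rho tails stay fully analytic).
#' @param mc_seed Fixed internal seed for that Monte-Carlo step; the global
#'   RNG state is saved and restored around it.
#' @return An object of class `sre_assoc_config`.
#' @export
assoc_config <- function(rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2,
                                      0.5^2, 0.5, 1),
                         weight_beta = c(1, 25),
                         tol = 1e-6,
                         small_sample = c("auto", "always", "never"),
                         small_n_cutoff = 200L,
                         mc_iter = 4e6,
                         mc_seed = 101L) {
  stopifnot(is.numeric(rho_grid), all(rho_grid >= 0), all(rho_grid <= 1),
            0 %in% rho_grid, 1 %in% rho_grid,
            length(weight_beta) == 2, all(weight_beta > 0))
  structure(list(rho_grid = sort(unique(rho_grid)),
                 weight_beta = weight_beta,
                 tol = tol,
                 small_sample = match.arg(small_sample),
                 small_n_cutoff = as.integer(small_n_cutoff),
                 mc_iter = as.integer(mc_iter),
                 mc_seed = as.integer(mc_seed)),
            class = "sre_assoc_config")
}

#' SKAT-O test of a gene bin against the null model
#'
#' Optimal sequence kernel association test for a continuous phenotype.
#' With weighted genotypes `Z = G W` (`W = diag(dbeta(MAF; a1, a2))`) and
#' null residuals `r`, the score vector is `S = Z' r` and the statistic
#' family is
#' \deqn{Q_\rho = (1-\rho)\sum_j S_j^2 + \rho (\sum_j S_j)^2,}
#' interpolating between the variance-component kernel statistic and the
#' squared burden score. Each `Q_rho` is referred to its null law, a positive
#' mixture of 1-df chi-squares with coefficients the eigenvalues of
#' `R_rho^{1/2} Z' P_0 Z R_rho^{1/2} / sigma^2` (`P_0` the residual
#' projection, `R_rho` compound symmetry). The reported p-value combines the
#' grid by the one-dimensional integration over the common chi-square
#' component of the minimum-p statistic.
#'
#' @param bin A `gene_bin` (see [bin_by_gene()]) or any list with elements
#'   `gene_id`, `G` (n-by-m minor-allele dosage matrix, missing values
#'   imputed), `mafs` (per-column MAF) and optionally `loci`,
#'   `total_allele_count`.
#' @param null An [fit_null_model()] object for the same samples, same order.
#' @param config An [assoc_config()].
#' @return An object of class `sre_assoc_result`: list with `gene_id`,
#'   `p_skato`, `per_rho_p` (named by rho), `Q` (per-rho statistics, on the
#'   scale of the standardized mixture), `m_loci`, `total_allele_count`, and
#'   `diagnostics` (kernel eigenvalues, tail-method flags, correlated-column
#'   warnings).
#' @export
skat_o <- function(bin, null, config = assoc_config()) {
  stopifnot(inherits(null, "sre_null_model"), inherits(config, "sre_assoc_config"))
  G <- as.matrix(bin$G)
  mafs <- bin$mafs
  stopifnot(nrow(G) == null$n, length(mafs) == ncol(G))
  m <- ncol(G)
  if (m < 1L) stop("empty bin for gene ", bin$gene_id)

  poly <- apply(G, 2, function(g) stats::var(g) > 0)
  if (!any(poly)) stop("bin for gene ", bin$gene_id,
                       " contains no polymorphic variant")
  dup <- duplicated(t(G)) | duplicated(t(G), fromLast = TRUE)
  correlated <- if (any(dup) && m > 1L) which(dup) else integer(0)
  if (length(correlated))
    warning("gene ", bin$gene_id, ": perfectly duplicated genotype columns: ",
            paste(correlated, collapse = ", "))

  w <- stats::dbeta(mafs, config$weight_beta[1], config$weight_beta[2])
  Z <- G * rep(w, each = nrow(G))
  r <- null$residuals
  sigma2 <- null$sigma2
  S <- as.vector(crossprod(Z, r))
  Zs <- null$project(Z)   # score covariance = sigma2 * Zs'Zs; statistics are
                          # divided by sigma2 so the mixture uses Zs'Zs itself
  K <- crossprod(Zs)
  df_resid <- null$n - ncol(null$X)
  use_exact <- switch(config$small_sample,
                      auto = null$n < config$small_n_cutoff,
                      always = TRUE,
                      never = FALSE)
  if (use_exact && m >= df_resid) {
    warning("more loci than residual degrees of freedom; ",
            "using the asymptotic null")
    use_exact <- FALSE
  }

  rhos <- config$rho_grid
  Q <- numeric(length(rhos))
  per_rho_p <- numeric(length(rhos))
  lam_list <- vector("list", length(rhos))
  methods <- character(length(rhos))
  sumS2 <- sum(S^2); sumS <- sum(S)
  for (i in seq_along(rhos)) {
    rho <- rhos[i]
    Q[i] <- ((1 - rho) * sumS2 + rho * sumS^2) / sigma2
    lam <- kernel_eigen(K, rho, m)
    if (!length(lam)) stop("degenerate kernel for gene ", bin$gene_id)
    lam_list[[i]] <- lam
    if (use_exact) {
      per_rho_p[i] <- ratio_sf(Q[i], lam, df_resid, tol = config$tol)
      methods[i] <- "davies_ratio"
    } else {
      p <- chi2mix_sf(Q[i], lam, tol = config$tol)
      per_rho_p[i] <- p
      methods[i] <- attr(p, "method")
    }
  }
  names(Q) <- names(per_rho_p) <- format(rhos)

  if (m == 1L) {
    # all rho coincide: p is the single-variant score-test p
    p_skato <- per_rho_p[1]
    diag_flags <- list(lambda = lam_list[[1]], tail_method = methods,
                       correlated_columns = correlated, omnibus = "degenerate_m1")
  } else {
    pmin_obs <- min(per_rho_p)
    om <- if (use_exact) {
      skato_omnibus_exact(K, rhos, lam_list, pmin_obs, df_resid, config)
    } else {
      skato_omnibus(K, rhos, lam_list, pmin_obs, config$tol)
    }
    p_skato <- if (is.na(om$p)) pmin_obs else om$p
    # grid-minimum bounds (Bonferroni above, trivial below)
    p_skato <- min(p_skato, pmin_obs * length(rhos), 1)
    p_skato <- max(p_skato, pmin_obs, 1e-300)
    diag_flags <- list(lambda = lam_list, tail_method = methods,
                       correlated_columns = correlated, omnibus = om$flag)
  }

  structure(list(
    gene_id = bin$gene_id,
    p_skato = as.numeric(p_skato),
    per_rho_p = per_rho_p,
    Q = Q,
    rho_grid = rhos,
    m_loci = m,
    total_allele_count = bin$total_allele_count %||% sum(G),
    diagnostics = diag_flags
  ), class = "sre_assoc_result")
}

#' @export
print.sre_assoc_result <- function(x, ...) {
  cat(sprintf("SKAT-O: gene %s  (m = %d loci, %s minor alleles)\n",
              x$gene_id, x$m_loci, format(x$total_allele_count)))
  cat(sprintf("  p_skato = %.3g\n", x$p_skato))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# eigenvalues of R_rho^{1/2} K R_rho^{1/2}; compound symmetry gives the
# closed-form square root a*J/m + b*(I - J/m)
kernel_eigen <- function(K, rho, m, drop_tol = 1e-10) {
  if (m == 1L) {
    lam <- as.numeric(K)
    return(lam[lam > 0])
  }
  a <- sqrt(1 - rho + m * rho)
  b <- sqrt(1 - rho)
  Rh <- matrix((a - b) / m, m, m)
  diag(Rh) <- diag(Rh) + b
  Krho <- Rh %*% K %*% Rh
  lam <- eigen((Krho + t(Krho)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam[lam > drop_tol * max(lam, 0)]
}

# Quantile of the chi-square mixture at upper-tail probability p: Davies
# tail inverted numerically, bracketed around the Liu moment-matched start.
qmix_sf <- function(p_upper, lambdas, tol = 1e-6) {
  if (p_upper >= 1) return(0)
  q0 <- max(liu_qmix(p_upper, lambdas), sum(lambdas) * 1e-8)
  if (!is.finite(q0)) q0 <- sum(lambdas)
  f <- function(q) as.numeric(chi2mix_sf(q, lambdas, tol = tol)) - p_upper
  lo <- q0; hi <- q0
  while (f(lo) < 0 && lo > 1e-12) lo <- lo / 2      # f decreasing in q
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (lo >= hi) return(max(q0, 0))
  stats::uniroot(f, c(lo, hi), tol = max(q0, 1) * 1e-9)$root
}

# Optimal-rho combined p-value, exact given the Gaussian score asymptotics.
# With S ~ N(0, K) (statistic units Q_rho = (1-rho)|S|^2 + rho (1'S)^2),
# condition on the burden component eta = 1'S ~ N(0, tau2), tau2 = 1'K1:
# the grid acceptance region {Q_rho < q_rho for all rho} becomes
#   eta^2 < q_1   and   |S|^2 < c(eta) = min_{rho<1} (q_rho - rho eta^2)/(1-rho),
# and |S|^2 | eta is a noncentral mixture of chi-squares (mean K1 eta/tau2,
# covariance K - K11'K/tau2), evaluated by Davies' method with
# noncentralities. The outer integral over eta^2/tau2 ~ chi^2_1 is finite
# (upper limit q_1/tau2), so no truncation is needed.
skato_omnibus <- function(K, rhos, lam_list, pmin_obs, tol) {
  m <- ncol(K)
  if (pmin_obs >= 1) return(list(p = 1, flag = "ok"))
  tau2 <- sum(K)
  if (tau2 <= 1e-12 * sum(diag(K)))
    return(list(p = NA_real_, flag = "degenerate_burden_direction"))

  q_rho <- vapply(seq_along(rhos),
                  function(i) qmix_sf(pmin_obs, lam_list[[i]], tol = tol),
                  numeric(1))
  b <- rowSums(K)                       # K 1
  C <- K - tcrossprod(b) / tau2         # conditional covariance; C 1 = 0
  ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
  keep <- ec$values > 1e-12 * max(ec$values, 0)
  lam_c <- ec$values[keep]
  if (!length(lam_c)) {
    # rank-one kernel: every rho is the same (burden) test
    return(list(p = NA_real_, flag = "rank_one_kernel"))
  }
  U <- ec$vectors[, keep, drop = FALSE]
  mu_unit <- b / tau2                   # conditional mean of S per unit eta
  a <- as.vector(crossprod(U, mu_unit))
  mu_perp2 <- sum((mu_unit - U %*% a)^2)    # fixed offset per unit eta^2
  nc_unit <- a^2 / lam_c                    # noncentrality per unit eta^2

  i_lt1 <- which(rhos < 1)
  has_rho1 <- any(rhos >= 1)
  x_max <- if (has_rho1) q_rho[which(rhos >= 1)[1]] / tau2 else Inf

  inner <- function(x) {   # x = eta^2 / tau2
    eta2 <- tau2 * x
    cmin <- min((q_rho[i_lt1] - rhos[i_lt1] * eta2) / (1 - rhos[i_lt1]))
    thr <- cmin - mu_perp2 * eta2
    if (thr <= 0) return(0)
    as.numeric(mgcv::psum.chisq(thr, lb = lam_c, df = rep(1, length(lam_c)),
                                nc = nc_unit * eta2, lower.tail = TRUE,
                                tol = tol, nlim = 1e6))
  }
  integrand <- function(x) vapply(x, inner, numeric(1)) * stats::dchisq(x, df = 1)
  upper <- if (is.finite(x_max)) x_max else 200
  int <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = upper,
                     subdivisions = 2000L, abs.tol = 1e-10),
    error = function(e) NULL)
  if (is.null(int))
    return(list(p = min(pmin_obs * length(rhos), 1), flag = "integration_failed"))
  list(p = 1 - int$value, flag = "ok")
}

# Exact finite-sample survival of Q / sigma2hat under Gaussian residuals.
# With r = P0 eps, sigma2hat = r'r / df and Q = S' R S the event
# Q/sigma2hat > q is a sign condition on one quadratic form:
#   sum_k (lambda_k - q/df) chi2_1(k)  -  (q/df) chi2_{df - m'}  >  0,
# so the tail is a mixed-sign Davies computation. This accounts for the
# dependence between score and variance estimate that the plug-in
# chi-square mixture ignores (an F-versus-chi-square distinction).
ratio_sf <- function(q, lambdas, df_resid, tol = 1e-7) {
  if (q <= 0) return(1)
  s <- q / df_resid
  lb <- c(lambdas - s, -s)
  df <- c(rep(1L, length(lambdas)), df_resid - length(lambdas))
  keep <- abs(lb) > 1e-14 * max(lambdas) & df > 0
  lb <- lb[keep]; df <- df[keep]
  if (!length(lb)) return(1)
  if (all(lb < 0)) return(1e-300)
  if (all(lb > 0)) return(1)
  p <- tryCatch(
    as.numeric(mgcv::psum.chisq(0, lb = lb, df = df, tol = tol, nlim = 1e6)),
    warning = function(w) NA_real_, error = function(e) NA_real_)
  if (!is.finite(p) || p < 0 || p > 1) {
    # moment-matching fallback on the shifted form
    mu <- sum(lb * df); v <- 2 * sum(lb^2 * df)
    p <- stats::pnorm(0, mean = mu, sd = sqrt(v), lower.tail = FALSE)
  }
  min(max(p, 1e-300), 1)
}

# quantile of the exact ratio null at upper-tail probability p
ratio_qmix <- function(p_upper, lambdas, df_resid, tol = 1e-7) {
  if (p_upper >= 1) return(0)
  q0 <- max(liu_qmix(p_upper, lambdas), sum(lambdas) * 1e-8)
  if (!is.finite(q0)) q0 <- sum(lambdas)
  f <- function(q) ratio_sf(q, lambdas, df_resid, tol = tol) - p_upper
  lo <- q0; hi <- q0
  while (f(lo) < 0 && lo > 1e-12) lo <- lo / 2
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (lo >= hi) return(max(q0, 0))
  stats::uniroot(f, c(lo, hi), tol = max(q0, 1) * 1e-8)$root
}

# Exact small-sample optimal-rho combination by Monte-Carlo integration of
# the joint null law of (S, sigma2hat). With S = K^{1/2} z, z ~ N(0, I_r)
# (r = rank K), the shared part of the variance estimate is S' K^- S = |z|^2
# ~ chi^2_r, and the remainder is an independent chi^2_{df - r}; the grid
# rejection region {any rho: Q_rho >= q_rho * sigma2hat} is evaluated
# directly. The internal RNG stream is fixed and the global state restored.
skato_omnibus_exact <- function(K, rhos, lam_list, pmin_obs, df_resid, config) {
  if (pmin_obs >= 1) return(list(p = 1, flag = "ok"))
  m <- ncol(K)
  q_rho <- vapply(seq_along(rhos),
                  function(i) ratio_qmix(pmin_obs, lam_list[[i]], df_resid,
                                         tol = config$tol),
                  numeric(1))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- ev$values > 1e-12 * max(ev$values, 0)
  r <- sum(keep)
  if (r == 0L) return(list(p = NA_real_, flag = "rank_zero_kernel"))
  root <- ev$vectors[, keep, drop = FALSE] *
    rep(sqrt(ev$values[keep]), each = m)           # m x r; S = root %*% z

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$mc_seed)

  N <- config$mc_iter
  chunk <- 1e6L
  n_reject <- 0
  done <- 0L
  while (done < N) {
    nb <- min(chunk, N - done)
    z <- matrix(stats::rnorm(nb * r), nb, r)
    Smat <- z %*% t(root)                          # nb x m
    Q0 <- rowSums(Smat^2)
    Q1 <- rowSums(Smat)^2
    denom <- (rowSums(z^2) +
                stats::rchisq(nb, df = df_resid - r)) / df_resid
    rej <- rep(FALSE, nb)
    for (i in seq_along(rhos))
      rej <- rej | (((1 - rhos[i]) * Q0 + rhos[i] * Q1) >= q_rho[i] * denom)
    n_reject <- n_reject + sum(rej)
    done <- done + nb
  }
  list(p = n_reject / N, flag = "ok_exact_mc")
}
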