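#' Fit the covariate-only null model for a continuous phenotype
#'
#' Ordinary least squares of the phenotype on an intercept, age and sex.
#' The residual vector and residual variance parameterize the null
#' distribution of every gene-level score statistic; the projection onto the
#' orthogonal complement of the covariate space is exposed so kernels can be
#' centred without forming an n-by-n matrix.
#'
#' @param phenotype Numeric vector, one value per sample.
#' @param covariates Data frame with numeric columns `age` and `sex`
#'   (sex coded 0 = female, 1 = male), rows aligned with `phenotype`.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `sre_null_model`: list with `residuals`,
#'   design matrix `X`, `sigma2` (residual variance, denominator n - 3),
#'   `n`, `sample_ids`, and `project(M)` applying `I - X (X'X)^-1 X'`.
#' @examples
#' cov <- data.frame(age = rnorm(100, 73, 7), sex = rbinom(100, 1, 0.5))
#' y <- 0.02 * cov$age + 0.1 * cov$sex + rnorm(100)
#' nm <- fit_null_model(y, cov)
#' max(abs(crossprod(nm$X, nm$residuals)))  # ~0: residuals orthogonal to X
#' @export
fit_null_model <- function(phenotype, covariates, sample_ids = NULL) {
  stopifnot(is.numeric(phenotype),
            is.data.frame(covariates),
            all(c("age", "sex") %in% names(covariates)),
            nrow(covariates) == length(phenotype))
  keep <- is.finite(phenotype) & is.finite(covariates$age) &
    is.finite(covariates$sex)
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with missing phenotype/covariates",
                    sum(!keep)))
    phenotype <- phenotype[keep]
    covariates <- covariates[keep, , drop = FALSE]
    if (!is.null(sample_ids)) sample_ids <- sample_ids[keep]
  }
  n <- length(phenotype)
  if (n < ncol(covariates) + 3L)
    stop("too few samples to fit the covariate model")

  X <- cbind(`(Intercept)` = 1, age = covariates$age, sex = covariates$sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, phenotype)
  r <- fit$residuals
  sigma2 <- sum(r^2) / (n - ncol(X))
  if (sigma2 <= 0) stop("degenerate phenotype: zero residual variance")

  XtX_inv <- chol2inv(qr.R(qrX))
  structure(list(
    residuals = r,
    X = X,
    XtX_inv = XtX_inv,
    sigma2 = sigma2,
    n = n,
    coefficients = fit$coefficients,
    sample_ids = sample_ids,
    project = function(M) M - X %*% (XtX_inv %*% crossprod(X, M))
  ), class = "sre_null_model")
}

#' @export
print.sre_null_model <- function(x, ...) {
  cat("Null model: phenotype ~ intercept + age + sex\n")
  cat(sprintf("  n = %d, residual variance = %.4g\n", x$n, x$sigma2))
  cat("  coefficients:",
      paste(sprintf("%s=%.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}
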