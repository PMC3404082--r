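#' Per-SNP dosage logistic association scan
#'
#' For each SNP, fits phenotype ~ dosage + covariates by maximum-likelihood
#' logistic regression (IRLS, gradient tolerance 1e-8, at most 50
#' iterations) and reports the per-dosage-unit log-odds, Wald p-value and
#' 95\% confidence interval \code{exp(beta +/- 1.96 se)}.  Degenerate SNPs
#' (constant dosage), non-convergent or separated fits are flagged with
#' missing estimates.
#'
#' @param dset a QC'd \linkS4class{DosageSet} with binary phenotype.
#' @param covariates optional samples x k numeric matrix (typically the
#'   first two MDS components); rows must align with the samples.
#' @param k_covariates number of leading covariate columns to use.
#' @return data.frame per SNP: \code{snp}, \code{chrom}, \code{bp},
#'   \code{beta}, \code{se}, \code{or_}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{n_used}, \code{flagged}.
#' @seealso [genomicLambda()], [flagGenomewide()]
#' @export
logisticDosageScan <- function(dset, covariates = NULL, k_covariates = 2L) {
  y <- as.integer(.caseMask(dset@samples))
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nSamples(dset))
    C <- covariates[, seq_len(min(k_covariates, ncol(covariates))), drop = FALSE]
  }
  m <- nSNPs(dset)
  beta <- se <- p <- rep(NA_real_, m)
  n_used <- integer(m); flagged <- logical(m)
  for (j in seq_len(m)) {
    d <- dset@dosages[, j]
    ok <- !is.na(d)
    n_used[j] <- sum(ok)
    if (stats::var(d[ok]) == 0 || length(unique(y[ok])) < 2L) {
      flagged[j] <- TRUE
      next
    }
    X <- cbind(dose = d[ok], C[ok, , drop = FALSE])
    fit <- .logisticFit(y[ok], X)
    if (fit$flagged) { flagged[j] <- TRUE; next }
    beta[j] <- fit$beta; se[j] <- fit$se; p[j] <- fit$p
  }
  data.frame(snp = dset@snps$id, chrom = dset@snps$chrom, bp = dset@snps$bp,
             beta = beta, se = se, or_ = exp(beta),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             p = p, n_used = n_used, flagged = flagged,
             stringsAsFactors = FALSE)
}

# Logistic fit of y on X (first column is the predictor of interest).
.logisticFit <- function(y, X) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
  cf <- fit$coefficients
  if (!fit$converged || anyNA(cf))
    return(list(flagged = TRUE))
  # observed-information covariance from the final IRLS weights
  Xd <- cbind(1, X)
  W <- fit$weights
  XtWX <- crossprod(Xd * sqrt(W))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(list(flagged = TRUE))
  b <- cf[2]; s <- sqrt(cov[2, 2])
  # separation check on the per-SD scale so covariate units do not matter
  sd1 <- stats::sd(X[, 1])
  if (!is.finite(s) || s * max(sd1, .Machine$double.xmin) > 100)
    return(list(flagged = TRUE))
  z <- b / s
  list(flagged = FALSE, beta = b, se = s,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Genomic inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and reports
#' \code{lambda = median(chi-square) / 0.4549364} (the null median).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return lambda (1 under the null; > 1 indicates inflation).
#' @examples genomicLambda(rep(0.5, 10))
#' @export
genomicLambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied", call. = FALSE)
  stopifnot(all(p_values > 0), all(p_values <= 1))
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Flag genome-wide-significant SNPs
#'
#' @param results a [logisticDosageScan()] table.
#' @param alpha significance threshold (default 5e-8).
#' @return Character vector of SNP ids with p < alpha.
#' @export
flagGenomewide <- function(results, alpha = 5e-8) {
  results$snp[!is.na(results$p) & results$p < alpha]
}

#' Write an association table as TSV
#' @param results a [logisticDosageScan()] table.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeAssocResults <- function(results, path) {
  out <- data.frame(SNP = results$snp, CHR = results$chrom, BP = results$bp,
                    OR = results$or_, L95 = results$ci_low,
                    U95 = results$ci_high, P = results$p, N = results$n_used)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
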