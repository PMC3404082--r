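#' Bundled Parkinson's disease risk-locus table
#'
#' Thirteen SNPs from published genome-wide meta-analyses of Parkinson's
#' disease risk (IPDGC), with the minor allele, its frequency, the
#' replication-phase odds ratio and genomic position.  Used as input to the
#' cumulative risk-profile machinery and as effect sizes for the cohort
#' simulator.
#'
#' @param path TSV with columns \code{SNP}, \code{risk_allele},
#'   \code{other_allele}, \code{freq}, \code{published_OR}, \code{chrom},
#'   \code{bp}; defaults to the bundled table.
#' @return data.frame of the table, one row per locus.
#' @export
pdRiskLoci <- function(path = system.file("extdata", "pd_risk_loci.tsv",
                                          package = "founderscan")) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Risk-locus specs from a risk table
#'
#' @param tab a table in the [pdRiskLoci()] layout.
#' @return List of [riskLocus()] specifications.
#' @export
riskLociFromTable <- function(tab) {
  lapply(seq_len(nrow(tab)), function(k)
    riskLocus(tab$SNP[k], tab$risk_allele[k], tab$published_OR[k], tab$freq[k]))
}

#' Cumulative risk-allele scores
#'
#' Per-sample unweighted sum of risk-allele dosages over the supplied loci.
#' The published odds ratio orients the allele: when \code{OR >= 1} the
#' stated allele's dosage is summed; when \code{OR < 1} the stated allele
#' is protective, so the other allele is the risk allele and the dosage is
#' flipped \code{2 - d} before summing.  A missing dosage is replaced by
#' that locus's mean dosage (flagged in the result attributes).  Setting
#' \code{weighted = TRUE} multiplies each oriented dosage by
#' \code{|log(OR)|}.
#'
#' @param dset a \linkS4class{DosageSet} containing every risk locus.
#' @param risk_loci list of [riskLocus()] specs.
#' @param weighted logical; default \code{FALSE} (plain allele-count sum).
#' @return Named numeric vector of per-sample scores; attribute
#'   \code{n_imputed} counts mean-substituted entries.
#' @export
computeScores <- function(dset, risk_loci, weighted = FALSE) {
  n <- nSamples(dset)
  score <- rep(0, n)
  n_imputed <- 0L
  for (rl in risk_loci) {
    j <- match(rl$snp_id, dset@snps$id)
    if (is.na(j)) stop("risk locus absent from dosage set: ", rl$snp_id,
                       call. = FALSE)
    d <- dset@dosages[, j]
    a1 <- dset@snps$a1[j]; a2 <- dset@snps$a2[j]
    d_allele <- if (rl$risk_allele == a1) d
                else if (rl$risk_allele == a2) 2 - d
                else stop(sprintf("risk allele %s matches neither allele (%s/%s) at %s",
                                  rl$risk_allele, a1, a2, rl$snp_id),
                          call. = FALSE)
    if (rl$odds_ratio < 1) d_allele <- 2 - d_allele
    if (anyNA(d_allele)) {
      n_imputed <- n_imputed + sum(is.na(d_allele))
      d_allele[is.na(d_allele)] <- mean(d_allele, na.rm = TRUE)
    }
    w <- if (weighted) abs(log(rl$odds_ratio)) else 1
    score <- score + w * d_allele
  }
  structure(stats::setNames(score, dset@samples$id), n_imputed = n_imputed)
}

#' Assign risk quintiles
#'
#' Samples are ranked by score (ties broken by stable input order) and the
#' ranked list split into 5 contiguous groups with sizes as equal as
#' possible; when the count is not divisible by 5 the larger groups come
#' first from the bottom.  Quintile 1 holds the lowest scores.
#'
#' @param scores numeric vector (>= 5 values).
#' @return Integer vector of quintiles 1-5, same order and names as input.
#' @export
assignQuintiles <- function(scores) {
  n <- length(scores)
  stopifnot(n >= 5L)
  sizes <- rep(n %/% 5L, 5L)
  r <- n %% 5L
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  q_by_rank <- rep.int(1:5, sizes)
  o <- order(scores)  # stable
  out <- integer(n)
  out[o] <- q_by_rank
  stats::setNames(out, names(scores))
}

#' Per-quintile odds ratios
#'
#' Logistic regression of phenotype on quintile indicator variables
#' (quintile 1 = reference) plus covariates; reports OR and 95\% CI per
#' quintile > 1.  Quintiles in which one outcome class is absent are
#' flagged (their CI is unbounded).
#'
#' @param quintiles integer vector from [assignQuintiles()].
#' @param phenotype "case"/"control" vector aligned with quintiles.
#' @param covariates optional samples x k matrix (typically 2 MDS
#'   components).
#' @return data.frame per quintile: \code{quintile}, \code{or_},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{n_case}, \code{n_control},
#'   \code{flagged}; quintile 1 has OR fixed at 1.
#' @export
quintileAssociation <- function(quintiles, phenotype, covariates = NULL) {
  y <- as.integer(phenotype == "case")
  qf <- factor(quintiles, levels = 1:5)
  X <- stats::model.matrix(~qf)[, -1, drop = FALSE]
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, X), y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
  cf <- fit$coefficients
  W <- fit$weights
  cov <- tryCatch(solve(crossprod(cbind(1, X) * sqrt(W))),
                  error = function(e) matrix(NA, length(cf), length(cf)))
  out <- data.frame(quintile = 1:5, or_ = 1, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_,
                    n_case = as.vector(table(qf[y == 1])),
                    n_control = as.vector(table(qf[y == 0])),
                    flagged = FALSE)
  for (q in 2:5) {
    k <- q - 1L  # indicator column index (after intercept)
    b <- cf[1L + k]; s <- sqrt(cov[1L + k, 1L + k])
    bad <- out$n_case[q] == 0 || out$n_control[q] == 0 || !is.finite(s) || s > 100
    out$or_[q] <- exp(b)
    if (!bad) {
      out$ci_low[q] <- exp(b - 1.96 * s)
      out$ci_high[q] <- exp(b + 1.96 * s)
      out$p[q] <- 2 * stats::pnorm(-abs(b / s))
    } else out$flagged[q] <- TRUE
  }
  out
}

#' Score trend test and concordance (c-index)
#'
#' Fits the adjusted logistic model phenotype ~ score + covariates and
#' reports the Wald p-value for the continuous score (\code{trend_p}), the
#' concordance (Mann-Whitney AUC) of the model's fitted probabilities
#' against phenotype (\code{auc}), and the concordance of the raw score
#' alone (\code{auc_score}).
#'
#' @inheritParams quintileAssociation
#' @param scores numeric per-sample scores.
#' @return list(trend_p, auc, auc_score, flagged).
#' @export
trendAndAuc <- function(scores, phenotype, covariates = NULL) {
  y <- as.integer(phenotype == "case")
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  if (stats::var(scores) == 0)
    return(list(trend_p = NA_real_, auc = NA_real_,
                auc_score = 0.5, flagged = TRUE))
  X <- cbind(score = scores)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- .logisticFit(y, X)
  fitted <- if (!fit$flagged) {
    full <- suppressWarnings(stats::glm.fit(
      cbind(1, X), y, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
    full$fitted.values
  } else scores
  list(trend_p = if (fit$flagged) NA_real_ else fit$p,
       auc = concordanceIndex(fitted, y),
       auc_score = concordanceIndex(scores, y),
       flagged = fit$flagged)
}

#' Concordance index (Mann-Whitney AUC)
#'
#' Probability that a randomly chosen case scores higher than a randomly
#' chosen control, ties counted one half; computed from midranks.
#'
#' @param score numeric predictions.
#' @param y 0/1 outcome.
#' @return c-index in [0, 1].
#' @export
concordanceIndex <- function(score, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full risk-profile analysis
#'
#' Scores, quintiles, per-quintile ORs, trend p and c-index in one call,
#' mirroring the standard cumulative risk-profile workflow.
#'
#' @inheritParams computeScores
#' @param covariates optional covariate matrix.
#' @return list(scores, quintiles, quintile_or, trend_p, auc, auc_score).
#' @export
riskProfile <- function(dset, risk_loci, covariates = NULL, weighted = FALSE) {
  sc <- computeScores(dset, risk_loci, weighted = weighted)
  q <- assignQuintiles(sc)
  ph <- dset@samples$phenotype
  qa <- quintileAssociation(q, ph, covariates)
  ta <- trendAndAuc(as.numeric(sc), ph, covariates)
  list(scores = sc, quintiles = q, quintile_or = qa,
       trend_p = ta$trend_p, auc = ta$auc, auc_score = ta$auc_score)
}
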