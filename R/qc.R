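#' Quality-control thresholds
#'
#' Defaults follow standard SNP-array case-control practice for isolate
#' cohorts: per-sample call rate >= 0.95; per-SNP call rate >= 0.95; MAF >=
#' 0.01; Hardy-Weinberg exact p >= 1e-4 in controls and >= 1e-7 in cases;
#' differential (case vs control) and haplotype-conditional missingness
#' chi-square p >= 1e-5; relatedness pruning at pi-hat > 0.15; imputed-SNP
#' RSQR >= 0.30.
#'
#' @param min_sample_call_rate,min_snp_call_rate,min_maf,hwe_p_controls,hwe_p_cases,diff_missing_p,mishap_p,pi_hat_max,dosage_min_rsq thresholds.
#' @return A list of class \code{"QCThresholds"}.
#' @export
qcThresholds <- function(min_sample_call_rate = 0.95, min_snp_call_rate = 0.95,
                         min_maf = 0.01, hwe_p_controls = 1e-4,
                         hwe_p_cases = 1e-7, diff_missing_p = 1e-5,
                         mishap_p = 1e-5, pi_hat_max = 0.15,
                         dosage_min_rsq = 0.30) {
  th <- list(min_sample_call_rate = min_sample_call_rate,
             min_snp_call_rate = min_snp_call_rate, min_maf = min_maf,
             hwe_p_controls = hwe_p_controls, hwe_p_cases = hwe_p_cases,
             diff_missing_p = diff_missing_p, mishap_p = mishap_p,
             pi_hat_max = pi_hat_max, dosage_min_rsq = dosage_min_rsq)
  stopifnot(all(unlist(th) > 0), all(unlist(th) <= 1))
  class(th) <- "QCThresholds"
  th
}

.qcReport <- function(...) {
  rules <- list(...)
  structure(list(rules = rules), class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report:\n")
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    cat(sprintf("  %-24s removed %d (threshold %s)\n", nm, length(r$ids),
                format(r$threshold)))
  }
  invisible(x)
}

#' Serialise a QC report as TSV
#' @param report a QC report.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeQCReport <- function(report, path) {
  rows <- vapply(names(report$rules), function(nm) {
    r <- report$rules[[nm]]
    sprintf("%s\t%s\t%d\t%s", nm, format(r$threshold), length(r$ids),
            paste(r$ids, collapse = ","))
  }, "")
  writeLines(c("rule\tthreshold\tn_removed\tids", rows), path)
  invisible(path)
}

#' Per-sample call-rate filter
#'
#' Removes samples whose genome-wide genotyping call rate falls below the
#' threshold (default 0.95); samples exactly at the threshold are retained.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param thresholds a [qcThresholds()].
#' @return \code{list(panel, report)}.
#' @export
sampleQC <- function(panel, thresholds = qcThresholds()) {
  cr <- rowMeans(!is.na(panel@genotypes))
  drop <- cr < thresholds$min_sample_call_rate
  if (all(drop)) stop("all samples fail the call-rate filter", call. = FALSE)
  report <- .qcReport(sample_call_rate = list(
    threshold = thresholds$min_sample_call_rate,
    ids = panel@samples$id[drop]))
  list(panel = panel[!drop, ], report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: with the allele counts fixed, the
#' probability of every admissible heterozygote count (same parity as the
#' observed one) is computed and those no more probable than the observed
#' table are summed.  Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @examples hweExactTest(25, 50, 25)
#' @export
hweExactTest <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("empty genotype table", call. = FALSE)
  n_a <- 2L * n_hom1 + n_het          # rarer-or-not allele count, fixed margin
  n_b <- 2L * n_hom2 + n_het
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Per-SNP quality-control filters
#'
#' Removes SNPs failing call rate (< 0.95), minor allele frequency (< 0.01,
#' computed on non-missing calls across all samples), or Hardy-Weinberg
#' equilibrium, tested separately in controls (exact p < 1e-4) and cases
#' (exact p < 1e-7).
#'
#' @inheritParams sampleQC
#' @return \code{list(panel, report)}.
#' @export
snpQC <- function(panel, thresholds = qcThresholds()) {
  G <- panel@genotypes
  cr <- colMeans(!is.na(G))
  p1 <- .alleleFreq(G)
  maf <- pmin(p1, 1 - p1)
  ph <- panel@samples$phenotype
  hwe_p <- function(sub) {
    if (!nrow(sub)) return(rep(1, ncol(G)))
    vapply(seq_len(ncol(G)), function(j) {
      g <- sub[, j]
      hweExactTest(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 0L, na.rm = TRUE))
    }, 0)
  }
  p_ctrl <- hwe_p(G[!is.na(ph) & ph == "control", , drop = FALSE])
  p_case <- hwe_p(G[!is.na(ph) & ph == "case", , drop = FALSE])
  fail_cr <- cr < thresholds$min_snp_call_rate
  fail_maf <- maf < thresholds$min_maf
  fail_hwe_c <- p_ctrl < thresholds$hwe_p_controls
  fail_hwe_a <- p_case < thresholds$hwe_p_cases
  drop <- fail_cr | fail_maf | fail_hwe_c | fail_hwe_a
  ids <- panel@snps$id
  report <- .qcReport(
    snp_call_rate = list(threshold = thresholds$min_snp_call_rate,
                         ids = ids[fail_cr]),
    maf = list(threshold = thresholds$min_maf, ids = ids[fail_maf]),
    hwe_controls = list(threshold = thresholds$hwe_p_controls,
                        ids = ids[fail_hwe_c]),
    hwe_cases = list(threshold = thresholds$hwe_p_cases,
                     ids = ids[fail_hwe_a]))
  list(panel = panel[, !drop], report = report)
}

#' Differential case/control missingness test
#'
#' Per SNP, a 1-df chi-square test (no continuity correction) on the 2x2
#' table (missing vs observed) x (case vs control).  SNPs with no missing
#' calls return p = 1.
#'
#' @param panel a phenotyped \linkS4class{GenotypePanel}.
#' @return Named numeric vector of p-values, one per SNP.
#' @export
diffMissingnessTest <- function(panel) {
  is_case <- .caseMask(panel@samples)
  if (!any(is_case) || all(is_case))
    stop("both phenotype classes must be non-empty", call. = FALSE)
  M <- is.na(panel@genotypes)
  m_case <- colSums(M[is_case, , drop = FALSE])
  m_ctrl <- colSums(M[!is_case, , drop = FALSE])
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  a <- m_case; b <- n_case - m_case; c <- m_ctrl; d <- n_ctrl - m_ctrl
  N <- n_case + n_ctrl
  num <- N * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi <- ifelse(den > 0, num / den, 0)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  p[m_case + m_ctrl == 0] <- 1
  stats::setNames(p, panel@snps$id)
}

#' Haplotype-conditional (mishap) missingness test
#'
#' Chi-square test of independence between missingness at a focal SNP and
#' the joint genotype configuration of its two immediate flanking SNPs on
#' the same chromosome (the minimal flanking-haplotype window).  SNPs at a
#' chromosome edge are not testable and return p = 1 with attribute
#' \code{skipped = TRUE}; so do SNPs with no missing calls.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param snp_index focal SNP column index.
#' @return p-value with attribute \code{skipped}.
#' @export
mishapTest <- function(panel, snp_index) {
  sn <- panel@snps
  j <- as.integer(snp_index)
  stopifnot(j >= 1L, j <= nrow(sn))
  edge <- j == 1L || j == nrow(sn) ||
    sn$chrom[j - 1L] != sn$chrom[j] || sn$chrom[j + 1L] != sn$chrom[j]
  if (edge) return(structure(1, skipped = TRUE))
  miss <- is.na(panel@genotypes[, j])
  if (!any(miss)) return(structure(1, skipped = FALSE))
  gl <- panel@genotypes[, j - 1L]
  gr <- panel@genotypes[, j + 1L]
  ok <- !is.na(gl) & !is.na(gr)
  if (!any(ok) || !any(miss[ok]) || all(miss[ok]))
    return(structure(1, skipped = TRUE))
  config <- factor(paste(gl[ok], gr[ok]))
  tab <- table(config, miss[ok])
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) return(structure(1, skipped = FALSE))
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  structure(if (is.na(p)) 1 else p, skipped = FALSE)
}

#' Missingness filters applied panel-wide
#'
#' Applies [diffMissingnessTest()] to every SNP and [mishapTest()] to every
#' interior SNP, removing SNPs below the configured p thresholds.
#'
#' @inheritParams sampleQC
#' @return \code{list(panel, report)}.
#' @export
missingnessQC <- function(panel, thresholds = qcThresholds()) {
  p_diff <- diffMissingnessTest(panel)
  has_miss <- colSums(is.na(panel@genotypes)) > 0
  p_mishap <- rep(1, nSNPs(panel))
  for (j in which(has_miss)) p_mishap[j] <- as.numeric(mishapTest(panel, j))
  fail_diff <- p_diff < thresholds$diff_missing_p
  fail_mishap <- p_mishap < thresholds$mishap_p
  ids <- panel@snps$id
  report <- .qcReport(
    diff_missingness = list(threshold = thresholds$diff_missing_p,
                            ids = ids[fail_diff]),
    mishap = list(threshold = thresholds$mishap_p, ids = ids[fail_mishap]))
  list(panel = panel[, !(fail_diff | fail_mishap)], report = report)
}

#' Imputed-dosage quality control
#'
#' Removes SNPs with imputation RSQR below 0.30 (values exactly at 0.30 are
#' retained) or dosage-based minor allele frequency (mean dosage / 2) below
#' 0.01.
#'
#' @param dset a \linkS4class{DosageSet}.
#' @param thresholds a [qcThresholds()].
#' @return \code{list(dosages, report)}.
#' @export
dosageQC <- function(dset, thresholds = qcThresholds()) {
  q <- dset@snps$quality
  p1 <- colMeans(dset@dosages, na.rm = TRUE) / 2
  maf <- pmin(p1, 1 - p1)
  fail_q <- q < thresholds$dosage_min_rsq
  fail_maf <- maf < thresholds$min_maf
  ids <- dset@snps$id
  report <- .qcReport(
    imputation_rsq = list(threshold = thresholds$dosage_min_rsq,
                          ids = ids[fail_q]),
    dosage_maf = list(threshold = thresholds$min_maf, ids = ids[fail_maf]))
  list(dosages = dset[, !(fail_q | fail_maf)], report = report)
}
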