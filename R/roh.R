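#' Call runs of homozygosity
#'
#' Per sample and chromosome, reports every maximal contiguous SNP interval
#' that simultaneously satisfies the segment criteria: span of at least
#' \code{min_len_bp} (first to last SNP, default 1 Mb), at least
#' \code{min_snps} SNPs (default 50), at most \code{max_missing} missing
#' calls (default 2) and at most \code{max_het} heterozygous calls (default
#' 1), beginning and ending on a homozygous call.  Maximal means the
#' interval is not contained in any other qualifying interval; runs never
#' cross chromosome boundaries.  Staggered overlapping maximal runs are
#' each reported.
#'
#' The direct maximal-interval definition is used (testable against an
#' exhaustive interval oracle) rather than a scanning-window proportion
#' heuristic.
#'
#' @param panel a sorted, typically LD-pruned \linkS4class{GenotypePanel}.
#' @param min_len_bp,min_snps,max_missing,max_het segment criteria.
#' @return data.frame of segments: \code{sample_id}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{n_snps}, \code{n_het},
#'   \code{n_missing}.
#' @seealso [rohBurden()], [consensusRegions()]
#' @export
callROH <- function(panel, min_len_bp = 1000000L, min_snps = 50L,
                    max_missing = 2L, max_het = 1L) {
  sn <- panel@snps
  if (is.unsorted(order(sn$chrom, sn$bp)))
    stop("panel SNPs must be sorted by (chrom, bp)", call. = FALSE)
  out <- list()
  for (ch in unique(sn$chrom)) {
    cols <- which(sn$chrom == ch)
    bp <- sn$bp[cols]
    for (r in seq_len(nSamples(panel))) {
      g <- panel@genotypes[r, cols]
      segs <- .rohScanOne(g, bp, min_len_bp, min_snps, max_missing, max_het)
      if (nrow(segs)) {
        segs$sample_id <- panel@samples$id[r]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0)))
  res <- do.call(rbind, out)
  res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps", "n_het",
          "n_missing")]
}

# Maximal qualifying intervals for one sample on one chromosome.
# For each homozygous start s, the largest end e*(s) keeping het <= max_het
# and missing <= max_missing is non-decreasing in s, and every qualifying
# interval starting at s is contained in [s, last hom <= e*(s)].  e*(s) is
# one position before the (max_het+1)-th heterozygote / (max_missing+1)-th
# missing call after s, whichever comes first.  Keeping the first start per
# distinct end and filtering the thresholds yields exactly the maximal
# qualifying set.
.rohScanOne <- function(g, bp, min_len_bp, min_snps, max_missing, max_het) {
  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0))
  m <- length(g)
  is_het <- !is.na(g) & g == 1L
  is_mis <- is.na(g)
  is_hom <- !is_het & !is_mis
  hs <- which(is_hom)
  if (!length(hs)) return(empty)
  cum_het <- cumsum(is_het); cum_mis <- cumsum(is_mis)
  het_pos <- which(is_het); mis_pos <- which(is_mis)
  hb <- c(0L, cum_het)[hs]  # hets strictly before each start
  mb <- c(0L, cum_mis)[hs]
  lim_h <- hb + max_het + 1L
  lim_m <- mb + max_missing + 1L
  e_het <- rep.int(m, length(hs))
  in_range <- lim_h <= length(het_pos)
  e_het[in_range] <- het_pos[lim_h[in_range]] - 1L
  e_mis <- rep.int(m, length(hs))
  in_range <- lim_m <= length(mis_pos)
  e_mis[in_range] <- mis_pos[lim_m[in_range]] - 1L
  e_star <- pmin(e_het, e_mis)
  last_hom <- cummax(ifelse(is_hom, seq_len(m), 0L))
  eh <- last_hom[e_star]  # >= s because the start itself is homozygous
  new_max <- eh > c(0L, cummax(eh)[-length(eh)])
  starts <- hs[new_max]; ends <- eh[new_max]
  keep <- (bp[ends] - bp[starts] >= min_len_bp) &
    (ends - starts + 1L >= min_snps)
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  pre_het <- c(0L, cum_het)[starts]; pre_mis <- c(0L, cum_mis)[starts]
  data.frame(start_bp = bp[starts], end_bp = bp[ends],
             n_snps = ends - starts + 1L,
             n_het = cum_het[ends] - pre_het,
             n_missing = cum_mis[ends] - pre_mis)
}

#' Per-sample ROH burden
#'
#' Genome fraction (summed segment lengths over the autosomal genome
#' length) and segment count per sample; samples with no segments get
#' (0, 0).
#'
#' @param segments a [callROH()] table.
#' @param samples sample table ([sampleInfo()]); every sample appears in
#'   the output.
#' @param genome_length_bp autosomal genome length (default
#'   [autosomeGenomeLength()], 2,645 Mb).
#' @return data.frame per sample: \code{id}, \code{genome_fraction},
#'   \code{n_segments}.
#' @export
rohBurden <- function(segments, samples, genome_length_bp = autosomeGenomeLength()) {
  len <- segments$end_bp - segments$start_bp
  tot <- tapply(as.numeric(len), segments$sample_id, sum)
  cnt <- table(segments$sample_id)
  data.frame(
    id = samples$id,
    genome_fraction = as.numeric(ifelse(is.na(tot[samples$id]), 0,
                                        tot[samples$id])) / genome_length_bp,
    n_segments = as.integer(ifelse(is.na(cnt[samples$id]), 0L,
                                   cnt[samples$id])),
    stringsAsFactors = FALSE)
}

#' Method-of-moments inbreeding coefficient (Fhat)
#'
#' Per sample, \code{F = (O_hom - E_hom) / (L - E_hom)} with \code{O_hom}
#' the observed homozygous count over the sample's \code{L} non-missing
#' SNPs and \code{E_hom} the sum over those SNPs of
#' \code{1 - 2 p (1 - p) * 2n / (2n - 1)} using cohort allele frequencies
#' \code{p} (the \code{2n / (2n - 1)} factor is the standard small-sample
#' correction on the expected heterozygosity).  SNPs monomorphic in the
#' cohort are excluded from both O and E.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @return Named numeric vector of per-sample Fhat values.
#' @export
fhat <- function(panel) {
  G <- panel@genotypes
  p <- .alleleFreq(G)
  n_chr <- 2 * colSums(!is.na(G))
  poly <- p > 0 & p < 1 & n_chr >= 2
  G <- G[, poly, drop = FALSE]
  p <- p[poly]; n_chr <- n_chr[poly]
  e_hom_snp <- 1 - 2 * p * (1 - p) * n_chr / (n_chr - 1)
  obs <- !is.na(G)
  O <- rowSums(G == 0L | G == 2L, na.rm = TRUE)
  E <- as.numeric(obs %*% e_hom_snp)
  L <- rowSums(obs)
  f <- (O - E) / (L - E)
  f[L == 0] <- NA
  stats::setNames(f, panel@samples$id)
}

#' ROH burden logistic regression
#'
#' Two logistic fits of phenotype on a burden metric plus birth year and
#' the first two MDS components: one for the genome fraction in ROH, one
#' for the ROH count.  Covariates without variation are dropped with a
#' warning; a constant burden metric is flagged.
#'
#' @param burden a [rohBurden()] table.
#' @param samples sample table with \code{id}, \code{phenotype},
#'   \code{birth_year}.
#' @param covariates optional samples x k matrix of MDS components.
#' @return data.frame with one row per metric: \code{metric}, \code{or_},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{flagged}.
#' @export
burdenRegression <- function(burden, samples, covariates = NULL) {
  y <- as.integer(.caseMask(samples))
  b <- burden[match(samples$id, burden$id), , drop = FALSE]
  covs <- cbind(birth_year = as.numeric(samples$birth_year))
  if (!is.null(covariates)) covs <- cbind(covs, as.matrix(covariates))
  keep <- apply(covs, 2, function(x) !anyNA(x) && stats::var(x) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping constant/missing covariate(s): %s",
                    paste(colnames(covs)[!keep], collapse = ", ")))
    covs <- covs[, keep, drop = FALSE]
  }
  one <- function(metric, x) {
    if (stats::var(x) == 0)
      return(data.frame(metric = metric, or_ = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, flagged = TRUE))
    X <- cbind(x, covs)
    fit <- .logisticFit(y, X)
    if (fit$flagged)
      return(data.frame(metric = metric, or_ = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, flagged = TRUE))
    data.frame(metric = metric, or_ = exp(fit$beta),
               ci_low = exp(fit$beta - 1.96 * fit$se),
               ci_high = exp(fit$beta + 1.96 * fit$se), p = fit$p,
               flagged = FALSE)
  }
  rbind(one("genome_fraction", b$genome_fraction),
        one("n_segments", as.numeric(b$n_segments)))
}

#' Extract consensus ROH regions
#'
#' The genome is partitioned at all segment breakpoints; maximal intervals
#' over which the carrier set is constant, carried by at least
#' \code{min_carriers} samples, containing at least \code{min_snps} SNPs
#' and spanning at least \code{min_len_bp}, become consensus regions.  A
#' carrier of a region is a sample with a called segment fully covering it
#' (set \code{partial = TRUE} to accept any overlap).  Output is invariant
#' under the order in which segments are supplied.
#'
#' @param segments a [callROH()] table.
#' @param snp_map SNP map ([snpInfo()]) used to count SNPs per region.
#' @param samples sample table used to classify carriers.
#' @param min_snps,min_len_bp,min_carriers region criteria (defaults 3,
#'   100 kb, 3).
#' @param partial carrier semantics (default full coverage).
#' @return data.frame per region: \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{n_snps}, \code{carriers_case},
#'   \code{carriers_control}, plus a \code{carrier_ids} list column.
#' @export
consensusRegions <- function(segments, snp_map, samples, min_snps = 3L,
                             min_len_bp = 100000L, min_carriers = 3L,
                             partial = FALSE) {
  empty <- data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      carriers_case = integer(0), carriers_control = integer(0))
  empty$carrier_ids <- list()
  if (!nrow(segments)) return(empty)
  segments <- segments[order(segments$chrom, segments$start_bp,
                             segments$end_bp, segments$sample_id), ]
  is_case <- stats::setNames(!is.na(samples$phenotype) &
                             samples$phenotype == "case", samples$id)
  out <- list()
  for (ch in sort(unique(segments$chrom))) {
    sg <- segments[segments$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(sg$start_bp, sg$end_bp + 1L)))
    if (length(cuts) < 2L) next
    iv_start <- cuts[-length(cuts)]
    iv_end <- cuts[-1L] - 1L
    bp_ch <- snp_map$bp[snp_map$chrom == ch]
    carriers <- lapply(seq_along(iv_start), function(k) {
      cover <- if (partial)
        sg$start_bp <= iv_end[k] & sg$end_bp >= iv_start[k]
      else
        sg$start_bp <= iv_start[k] & sg$end_bp >= iv_end[k]
      sort(unique(sg$sample_id[cover]))
    })
    key <- vapply(carriers, paste, "", collapse = ";")
    # merge adjacent elementary intervals with identical carrier sets
    grp <- cumsum(c(TRUE, key[-1] != key[-length(key)] |
                      iv_start[-1] != iv_end[-length(iv_end)] + 1L))
    for (g in unique(grp)) {
      rows <- which(grp == g)
      ids <- carriers[[rows[1]]]
      if (length(ids) < min_carriers) next
      s <- iv_start[rows[1]]; e <- iv_end[rows[length(rows)]]
      n_snps <- sum(bp_ch >= s & bp_ch <= e)
      if (e - s < min_len_bp || n_snps < min_snps) next
      row <- data.frame(chrom = ch, start_bp = s, end_bp = e, n_snps = n_snps,
                        carriers_case = sum(is_case[ids]),
                        carriers_control = sum(!is_case[ids]))
      row$carrier_ids <- list(ids)
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' maxT permutation test for consensus regions
#'
#' Per-region statistic: one-sided z for an excess case carrier proportion,
#' \code{z = (p_case - p_control) / sqrt(p(1-p)(1/n_case + 1/n_control))}
#' with \code{p} the pooled carrier proportion (\code{statistic =
#' "count"} uses the raw case carrier count instead).  Each permutation
#' redraws the case labels preserving the case count and records the
#' maximum statistic over all regions; the family-wise corrected p-value of
#' a region is \code{(1 + #\{max* >= stat\}) / (1 + n_perm)}.  A pointwise
#' empirical p-value is reported alongside; \code{p_corrected >=
#' p_empirical} always.
#'
#' @param regions a [consensusRegions()] table.
#' @param samples sample table with phenotypes.
#' @param n_perm permutations (default 50,000).
#' @param seed integer seed.
#' @param statistic \code{"proportion_z"} (default) or \code{"count"}.
#' @return \code{regions} with \code{stat}, \code{p_empirical},
#'   \code{p_corrected} appended.
#' @export
maxtRegionTest <- function(regions, samples, n_perm = 50000L, seed = 1L,
                           statistic = c("proportion_z", "count")) {
  statistic <- match.arg(statistic)
  if (!nrow(regions)) stop("no regions to test", call. = FALSE)
  is_case <- .caseMask(samples)
  n <- length(is_case); n1 <- sum(is_case); n0 <- n - n1
  if (n1 == 0L || n0 == 0L)
    stop("both cases and controls required", call. = FALSE)
  Cmat <- vapply(regions$carrier_ids, function(ids)
    samples$id %in% ids, logical(n)) * 1  # n x R carrier indicators
  tot <- colSums(Cmat)
  zstat <- function(x1) {
    # x1 = case carrier count per region (vector or R x B matrix)
    if (statistic == "count") return(x1)
    x0 <- tot - x1
    phat <- (x1 + x0) / n
    den <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n0))
    z <- (x1 / n1 - x0 / n0) / den
    z[!is.finite(z)] <- 0
    z
  }
  obs <- zstat(as.numeric(crossprod(Cmat, is_case * 1)))
  live <- tot > 0
  count_ge <- rep(0, nrow(regions))
  max_null <- numeric(n_perm)
  .withSeed(seed, {
    chunk <- 500L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      L <- vapply(seq_len(nb), function(k) {
        lab <- logical(n); lab[sample.int(n, n1)] <- TRUE; lab
      }, logical(n)) * 1
      x1 <- crossprod(Cmat, L)            # R x nb
      zs <- zstat(x1)
      count_ge <- count_ge + rowSums(zs >= obs - 1e-12)
      max_null[done + seq_len(nb)] <-
        apply(zs[live, , drop = FALSE], 2, max)
      done <- done + nb
    }
  })
  regions$stat <- obs
  regions$p_empirical <- (1 + count_ge) / (1 + n_perm)
  regions$p_corrected <- vapply(obs, function(s)
    (1 + sum(max_null >= s - 1e-12)) / (1 + n_perm), 0)
  regions$p_empirical[!live] <- NA
  regions$p_corrected[!live] <- NA
  regions
}

#' Write ROH segments / consensus regions as TSV
#'
#' @param segments a [callROH()] table.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeROHSegments <- function(segments, path) {
  out <- data.frame(IID = segments$sample_id, CHR = segments$chrom,
                    BP1 = segments$start_bp, BP2 = segments$end_bp,
                    NSNP = segments$n_snps, NHET = segments$n_het,
                    NMISS = segments$n_missing,
                    KB = round((segments$end_bp - segments$start_bp) / 1000, 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeROHSegments
#' @param regions a tested [consensusRegions()] table.
#' @export
writeConsensusRegions <- function(regions, path) {
  n <- nrow(regions)
  out <- data.frame(CHR = regions$chrom, BP1 = regions$start_bp,
                    BP2 = regions$end_bp, NSNP = regions$n_snps,
                    AFF = regions$carriers_case,
                    UNAFF = regions$carriers_control,
                    STAT = if (!is.null(regions$stat)) regions$stat
                           else rep(NA, n),
                    EMP2 = if (!is.null(regions$p_corrected)) regions$p_corrected
                           else rep(NA, n))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
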