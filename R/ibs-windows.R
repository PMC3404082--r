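#' Pairwise identity-by-state matrix
#'
#' For each sample pair, proportional allele sharing
#' \code{(IBS2 + 0.5 IBS1) / n} over jointly non-missing SNPs, where IBS2
#' counts identical genotypes and IBS1 genotypes differing by one allele
#' copy.  Diagonal is 1.  Pairs with no jointly non-missing SNP get
#' \code{NA}.
#'
#' @param panel a (typically LD-pruned) \linkS4class{GenotypePanel}.
#' @param snp_subset optional SNP indices or ids restricting the
#'   computation.
#' @return Symmetric n x n matrix of shares in [0, 1].
#' @export
pairwiseIBS <- function(panel, snp_subset = NULL) {
  G <- panel@genotypes
  if (!is.null(snp_subset)) {
    if (is.character(snp_subset)) snp_subset <- match(snp_subset, panel@snps$id)
    G <- G[, snp_subset, drop = FALSE]
  }
  cnt <- .ibsCounts(G)
  share <- 1 - (0.5 * cnt$ibs1 + cnt$ibs0) / cnt$joint
  share[cnt$joint == 0] <- NA
  diag(share) <- 1
  dimnames(share) <- list(panel@samples$id, panel@samples$id)
  share
}

#' Tile the genome into sliding windows
#'
#' Per chromosome, windows of \code{size_bp} start at bp 0, 1*step, 2*step,
#' ... up to \code{ceil(span / step) - 1} steps, truncated at the
#' chromosome end.  The window origin is bp 0 on every chromosome (not the
#' first SNP), which makes the window count over a genome of total length
#' \code{S} exactly \code{sum(ceil(span_c / step))} and reproducible across
#' SNP panels: 22 autosomes totalling 2,645 Mb at 500 kb / 250 kb give
#' 10,580 windows.  Windows are [start, end) half-open in the table but
#' reported 1-based (\code{start_bp} = start + 1).  Windows holding fewer
#' than \code{min_snps} SNPs are emitted but flagged untestable.
#'
#' @param snp_map data.frame with \code{id}, \code{chrom}, \code{bp}
#'   (sorted), e.g. [snpInfo()].
#' @param size_bp,step_bp window size and step (defaults 500 kb / 250 kb).
#' @param chrom_lengths named chromosome spans; defaults to
#'   [defaultChromLengths()] entries for the chromosomes present in the map.
#' @param min_snps minimum SNP count for a testable window (default 10).
#' @return data.frame per window: \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{n_snps}, \code{first_snp}, \code{last_snp}
#'   (column index range into the map, NA if empty), \code{testable}.
#' @export
makeWindows <- function(snp_map, size_bp = 500000L, step_bp = 250000L,
                        chrom_lengths = NULL, min_snps = 10L) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- defaultChromLengths()[as.character(unique(snp_map$chrom))]
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    span <- as.numeric(chrom_lengths[[ch]])
    n_win <- max(ceiling(span / step_bp), 1L)
    starts <- (seq_len(n_win) - 1) * step_bp
    ends <- pmin(starts + size_bp, span)
    in_ch <- which(snp_map$chrom == as.integer(ch))
    bp <- snp_map$bp[in_ch]
    # SNP index range per window on the sorted map: bp in (start, end]
    lo <- findInterval(starts, bp) + 1L
    hi <- findInterval(ends, bp)
    n_snps <- pmax(hi - lo + 1L, 0L)
    out[[ch]] <- data.frame(
      chrom = as.integer(ch), start_bp = as.integer(starts) + 1L,
      end_bp = as.integer(ends), n_snps = n_snps,
      first_snp = ifelse(n_snps > 0, in_ch[pmin(lo, length(in_ch))], NA),
      last_snp = ifelse(n_snps > 0, in_ch[pmax(hi, 1L)], NA),
      testable = n_snps >= min_snps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-pair IBS accumulators on non-overlapping step segments, so that any
# window (= consecutive steps) and the genome-wide statistic are sums of
# segment counts.  Returns list(dist = n_pairs x n_seg weighted-difference
# sums (0.5 per IBS1, 1 per IBS0), joint = matching joint-call counts,
# seg = segment table).
.segmentPairCounts <- function(panel, step_bp, chrom_lengths) {
  sn <- panel@snps
  n <- nSamples(panel)
  pr <- .pairIndices(n)
  idx <- cbind(pr$i, pr$j)
  segs <- list(); dist <- list(); joint <- list()
  for (ch in names(chrom_lengths)) {
    span <- as.numeric(chrom_lengths[[ch]])
    n_seg <- max(ceiling(span / step_bp), 1L)
    in_ch <- which(sn$chrom == as.integer(ch))
    seg_of <- if (length(in_ch))
      pmin(pmax(ceiling(sn$bp[in_ch] / step_bp), 1L), n_seg) else integer(0)
    D <- matrix(0, length(pr$i), n_seg)
    J <- matrix(0, length(pr$i), n_seg)
    for (s in unique(seg_of)) {
      cols <- in_ch[seg_of == s]
      cnt <- .ibsCounts(panel@genotypes[, cols, drop = FALSE])
      D[, s] <- (0.5 * cnt$ibs1 + cnt$ibs0)[idx]
      J[, s] <- cnt$joint[idx]
    }
    segs[[ch]] <- data.frame(chrom = as.integer(ch), seg = seq_len(n_seg))
    dist[[ch]] <- D; joint[[ch]] <- J
  }
  list(pairs = pr, seg = do.call(rbind, segs),
       dist = do.call(cbind, dist), joint = do.call(cbind, joint))
}

# Map each window to its step-segment columns in the .segmentPairCounts
# layout (window k covers segments k and k+1 when size = 2 * step).
.windowSegCols <- function(windows, seg_table, size_bp, step_bp) {
  n_per <- ceiling(size_bp / step_bp)
  lapply(seq_len(nrow(windows)), function(w) {
    ch <- windows$chrom[w]
    first_seg <- (windows$start_bp[w] - 1L) %/% step_bp + 1L
    segs <- first_seg + seq_len(n_per) - 1L
    which(seg_table$chrom == ch & seg_table$seg %in% segs)
  })
}

#' Window IBS statistics
#'
#' Per window, the pairwise shares restricted to the window's SNPs,
#' averaged over case-case pairs and over control-control pairs
#' (case-control pairs are excluded), and their difference
#' \code{delta = case_ibs - control_ibs}.
#'
#' @param panel a phenotyped, LD-pruned \linkS4class{GenotypePanel}.
#' @param windows a [makeWindows()] table (built from the panel's map if
#'   omitted).
#' @param size_bp,step_bp window geometry (must match \code{windows}).
#' @param chrom_lengths named chromosome spans.
#' @return \code{windows} with columns \code{case_ibs}, \code{control_ibs},
#'   \code{delta} appended (NA for untestable windows).
#' @export
windowIBS <- function(panel, windows = NULL, size_bp = 500000L,
                      step_bp = 250000L, chrom_lengths = NULL) {
  prep <- .prepareWindowIBS(panel, windows, size_bp, step_bp, chrom_lengths)
  obs <- .windowMeansForLabels(prep, .caseMask(panel@samples))
  cbind(prep$windows, obs)
}

.prepareWindowIBS <- function(panel, windows, size_bp, step_bp, chrom_lengths) {
  if (is.null(chrom_lengths))
    chrom_lengths <- defaultChromLengths()[as.character(unique(panel@snps$chrom))]
  if (is.null(windows))
    windows <- makeWindows(panel@snps, size_bp, step_bp, chrom_lengths)
  sc <- .segmentPairCounts(panel, step_bp, chrom_lengths)
  segcols <- .windowSegCols(windows, sc$seg, size_bp, step_bp)
  n_pairs <- length(sc$pairs$i)
  W <- nrow(windows)
  dist <- matrix(0, n_pairs, W); joint <- matrix(0, n_pairs, W)
  for (w in seq_len(W)) {
    cl <- segcols[[w]]
    if (length(cl)) {
      dist[, w] <- rowSums(sc$dist[, cl, drop = FALSE])
      joint[, w] <- rowSums(sc$joint[, cl, drop = FALSE])
    }
  }
  share <- 1 - dist / pmax(joint, 1)
  valid <- joint > 0
  share[!valid] <- 0
  list(windows = windows, pairs = sc$pairs, share = share,
       valid = valid * 1, sc = sc)
}

# Case-case and control-control pair means per window for one labelling.
.windowMeansForLabels <- function(prep, is_case) {
  cc <- as.numeric(is_case[prep$pairs$i] & is_case[prep$pairs$j])
  uu <- as.numeric(!is_case[prep$pairs$i] & !is_case[prep$pairs$j])
  num_c <- crossprod(prep$share, cc); den_c <- crossprod(prep$valid, cc)
  num_u <- crossprod(prep$share, uu); den_u <- crossprod(prep$valid, uu)
  case_ibs <- as.numeric(num_c) / pmax(as.numeric(den_c), 1e-300)
  control_ibs <- as.numeric(num_u) / pmax(as.numeric(den_u), 1e-300)
  bad <- !prep$windows$testable | as.numeric(den_c) == 0 | as.numeric(den_u) == 0
  case_ibs[bad] <- NA; control_ibs[bad] <- NA
  data.frame(case_ibs = case_ibs, control_ibs = control_ibs,
             delta = case_ibs - control_ibs)
}

#' Window IBS permutation test
#'
#' Label-swap permutation test of the one-sided hypothesis that case-pair
#' IBS exceeds control-pair IBS per window.  Per-pair window share sums are
#' precomputed once; each permutation only redraws the case labels
#' (preserving the case count, one shared label stream across all windows)
#' and re-averages the pair groups.  Pointwise empirical p-values use
#' add-one smoothing, \code{p = (1 + #\{delta* >= delta\}) / (1 + n_perm)},
#' so they are never 0; a family-wise maxT p-value from the per-permutation
#' maximum delta over testable windows is reported alongside.
#'
#' @inheritParams windowIBS
#' @param n_perm number of permutations (default 10,000; < 100 warns).
#' @param seed integer seed for the label stream.
#' @param two_sided if \code{TRUE}, use |delta| (default one-sided).
#' @return \code{windows} with \code{case_ibs}, \code{control_ibs},
#'   \code{delta}, \code{p_empirical}, \code{p_maxt}.
#' @export
windowPermutationTest <- function(panel, windows = NULL, n_perm = 10000L,
                                  seed = 1L, size_bp = 500000L,
                                  step_bp = 250000L, chrom_lengths = NULL,
                                  two_sided = FALSE) {
  if (n_perm < 100L) warning("fewer than 100 permutations: p resolution is coarse")
  is_case <- .caseMask(panel@samples)
  n <- length(is_case); n_case <- sum(is_case)
  if (n_case == 0L || n_case == n)
    stop("permutation needs both cases and controls", call. = FALSE)
  prep <- .prepareWindowIBS(panel, windows, size_bp, step_bp, chrom_lengths)
  obs <- .windowMeansForLabels(prep, is_case)
  W <- nrow(prep$windows)
  stat <- function(d) if (two_sided) abs(d) else d
  obs_stat <- stat(obs$delta)
  count_ge <- rep(0, W)
  max_null <- numeric(n_perm)
  testable <- !is.na(obs$delta)
  .withSeed(seed, {
    chunk <- 250L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      # one label redraw per permutation, shared across windows
      perm_stats <- matrix(NA_real_, W, nb)
      L <- vapply(seq_len(nb), function(k) {
        lab <- logical(n); lab[sample.int(n, n_case)] <- TRUE; lab
      }, logical(n))
      cc <- (L[prep$pairs$i, , drop = FALSE] & L[prep$pairs$j, , drop = FALSE]) * 1
      uu <- ((!L)[prep$pairs$i, , drop = FALSE] & (!L)[prep$pairs$j, , drop = FALSE]) * 1
      num_c <- crossprod(prep$share, cc); den_c <- crossprod(prep$valid, cc)
      num_u <- crossprod(prep$share, uu); den_u <- crossprod(prep$valid, uu)
      d <- num_c / pmax(den_c, 1e-300) - num_u / pmax(den_u, 1e-300)
      perm_stats <- stat(d)
      ge <- perm_stats >= matrix(obs_stat, W, nb) - 1e-12
      ge[!testable, ] <- FALSE
      count_ge <- count_ge + rowSums(ge, na.rm = TRUE)
      max_null[done + seq_len(nb)] <-
        apply(perm_stats[testable, , drop = FALSE], 2, max)
      done <- done + nb
    }
  })
  p_emp <- (1 + count_ge) / (1 + n_perm)
  p_emp[!testable] <- NA
  p_maxt <- vapply(seq_len(W), function(w) {
    if (!testable[w]) return(NA_real_)
    (1 + sum(max_null >= obs_stat[w] - 1e-12)) / (1 + n_perm)
  }, 0)
  out <- cbind(prep$windows, obs)
  out$p_empirical <- p_emp
  out$p_maxt <- p_maxt
  out
}

#' Genome-wide IBS comparison
#'
#' The window statistic computed over all (pruned) SNPs at once: mean
#' case-pair share, mean control-pair share, and a one-sided label-swap
#' empirical p-value for \code{delta > 0}.
#'
#' @inheritParams windowPermutationTest
#' @return list(case_ibs, control_ibs, delta, p).
#' @export
genomewideIBSTest <- function(panel, n_perm = 10000L, seed = 1L) {
  is_case <- .caseMask(panel@samples)
  n <- length(is_case); n_case <- sum(is_case)
  if (n_case == 0L || n_case == n)
    stop("both cases and controls required", call. = FALSE)
  share_m <- pairwiseIBS(panel)
  pr <- .pairIndices(n)
  s <- share_m[cbind(pr$i, pr$j)]
  valid <- !is.na(s)
  s[!valid] <- 0
  means <- function(lab) {
    cc <- lab[pr$i] & lab[pr$j] & valid
    uu <- !lab[pr$i] & !lab[pr$j] & valid
    c(sum(s[cc]) / sum(cc), sum(s[uu]) / sum(uu))
  }
  obs <- means(is_case)
  delta_obs <- obs[1] - obs[2]
  .withSeed(seed, {
    cnt <- 0L
    for (k in seq_len(n_perm)) {
      lab <- logical(n); lab[sample.int(n, n_case)] <- TRUE
      mm <- means(lab)
      if (mm[1] - mm[2] >= delta_obs - 1e-12) cnt <- cnt + 1L
    }
    list(case_ibs = obs[1], control_ibs = obs[2], delta = delta_obs,
         p = (1 + cnt) / (1 + n_perm))
  })
}

#' Write window IBS results as TSV
#'
#' @param results a [windowPermutationTest()] table.
#' @param path output file.
#' @param bed if \code{TRUE}, also writes \code{<path>.bed} with 0-based
#'   half-open coordinates.
#' @return Invisibly, \code{path}.
#' @export
writeWindowResults <- function(results, path, bed = FALSE) {
  out <- data.frame(CHR = results$chrom, START = results$start_bp,
                    END = results$end_bp, NSNP = results$n_snps,
                    IBS_CASE = results$case_ibs, IBS_CTRL = results$control_ibs,
                    DELTA = results$delta,
                    EMP_P = if (!is.null(results$p_empirical)) results$p_empirical else NA,
                    MAXT_P = if (!is.null(results$p_maxt)) results$p_maxt else NA)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed)
    utils::write.table(
      data.frame(paste0("chr", results$chrom), results$start_bp - 1L,
                 results$end_bp),
      paste0(path, ".bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}
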