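# Small panels built in code for unit tests.

tinyPanel <- function() {
  GenotypePanel(
    samples = data.frame(id = c("s1", "s2", "s3", "s4"),
                         phenotype = c("case", "case", "control", "control"),
                         birth_year = c(1960L, 1955L, 1902L, 1904L)),
    snps = data.frame(id = paste0("rs", 1:6), chrom = c(1L, 1L, 1L, 2L, 2L, 2L),
                      bp = c(100L, 200L, 300L, 150L, 250L, 350L),
                      a1 = c("A", "C", "G", "T", "A", "C"),
                      a2 = c("G", "T", "A", "C", "G", "A")),
    genotypes = rbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                      c(2L, 1L, 0L, 2L, 1L, 0L),
                      c(1L, NA, 1L, 1L, NA, 1L),
                      c(0L, 0L, 0L, 0L, 0L, 0L)))
}

# independent-SNP cohort (blocks shorter than spacing): for IBD, Fhat, MDS
indepCohort <- function(n_cases = 100, n_controls = 100, span = 25e6,
                        n_chrom = 2, spacing = 10000, seed = 1,
                        missing_rate = 0.005, fst = 0, maf = c(0.1, 0.5)) {
  lens <- stats::setNames(rep(span, n_chrom), as.character(seq_len(n_chrom)))
  cfg <- simulationConfig(
    n_cases = n_cases, n_controls = n_controls, chrom_lengths = lens,
    snp_spacing_mean = spacing, block_length_mean = spacing / 2,
    haplotypes_per_block = 8L, maf_range = maf,
    missing_rate = missing_rate, fst = fst, seed = seed)
  p <- simulateBasePanel(cfg)
  assignPhenotypes(p, list(), n_cases, n_controls, rng_seed = seed + 1L)
}

# dense common-SNP cohort for the window IBS scan (see methods vignette)
scanCohort <- function(seed, n_cases = 100, n_controls = 100) {
  cfg <- simulationConfig(
    n_cases = n_cases, n_controls = n_controls,
    chrom_lengths = c("1" = 12500000, "2" = 12500000),
    snp_spacing_mean = 2500, block_length_mean = 2000,
    haplotypes_per_block = 8L, maf_range = c(0.2, 0.5),
    missing_rate = 0.005, seed = seed)
  p <- simulateBasePanel(cfg)
  list(panel = assignPhenotypes(p, list(), n_cases, n_controls,
                                rng_seed = seed + 1L),
       chrom_lengths = cfg$chrom_lengths)
}

# long-block small-pool cohort: plenty of background ROH under the null
rohCohort <- function(seed, n_cases = 50, n_controls = 50,
                      span = 10e6, spacing = 10000) {
  cfg <- simulationConfig(
    n_cases = n_cases, n_controls = n_controls,
    chrom_lengths = stats::setNames(rep(span, 2), c("1", "2")),
    snp_spacing_mean = spacing, block_length_mean = 500000,
    haplotypes_per_block = 2L, maf_range = c(0.1, 0.5),
    missing_rate = 0.002, seed = seed)
  p <- simulateBasePanel(cfg)
  assignPhenotypes(p, list(), n_cases, n_controls, rng_seed = seed + 1L)
}

# moderate-LD cohort for planted recessive signals: background ROH is rare
# (autozygosity needs ~20 consecutive coincident blocks), so a planted
# segment stands out the way a founder mutation would
rohSignalCohort <- function(seed, n_cases = 100, n_controls = 100,
                            span = 10e6) {
  cfg <- simulationConfig(
    n_cases = n_cases, n_controls = n_controls,
    chrom_lengths = stats::setNames(rep(span, 2), c("1", "2")),
    snp_spacing_mean = 10000, block_length_mean = 50000,
    haplotypes_per_block = 6L, maf_range = c(0.1, 0.5),
    missing_rate = 0.005, seed = seed)
  p <- simulateBasePanel(cfg)
  assignPhenotypes(p, list(), n_cases, n_controls, rng_seed = seed + 1L)
}

# intermediate background: enough autozygosity that both arms carry some
# ROH (keeps burden regressions identifiable), signals still visible
midRohCohort <- function(seed, n_cases = 100, n_controls = 100, span = 10e6) {
  cfg <- simulationConfig(
    n_cases = n_cases, n_controls = n_controls,
    chrom_lengths = stats::setNames(rep(span, 2), c("1", "2")),
    snp_spacing_mean = 10000, block_length_mean = 200000,
    haplotypes_per_block = 4L, maf_range = c(0.1, 0.5),
    missing_rate = 0.002, seed = seed)
  p <- simulateBasePanel(cfg)
  assignPhenotypes(p, list(), n_cases, n_controls, rng_seed = seed + 1L)
}

# exhaustive interval oracle for the ROH caller
rohOracle <- function(g, bp, min_len = 10, min_snps = 3, max_mis = 2,
                      max_het = 1) {
  m <- length(g)
  qual <- list()
  for (s in seq_len(m)) {
    if (is.na(g[s]) || g[s] == 1L) next
    for (e in s:m) {
      if (is.na(g[e]) || g[e] == 1L) next
      seg <- g[s:e]
      if (sum(seg == 1L, na.rm = TRUE) > max_het) next
      if (sum(is.na(seg)) > max_mis) next
      if (bp[e] - bp[s] < min_len) next
      if (e - s + 1L < min_snps) next
      qual[[length(qual) + 1L]] <- c(s, e)
    }
  }
  if (!length(qual)) return(matrix(integer(0), 0, 2))
  q <- do.call(rbind, qual)
  maximal <- vapply(seq_len(nrow(q)), function(i)
    !any(q[, 1] <= q[i, 1] & q[, 2] >= q[i, 2] &
           (q[, 1] != q[i, 1] | q[, 2] != q[i, 2])), TRUE)
  q <- q[maximal, , drop = FALSE]
  q[order(q[, 1]), , drop = FALSE]
}
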