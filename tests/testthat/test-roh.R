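test_that("whole-chromosome homozygosity yields one spanning segment", {
  m <- 80
  bp <- seq(1L, by = 25000L, length.out = m)   # ~2 Mb
  g <- matrix(rep(c(0L, 2L), length.out = m), 1, m)
  p <- GenotypePanel(
    samples = data.frame(id = "hom1", phenotype = "case"),
    snps = data.frame(id = paste0("r", 1:m), chrom = 3L, bp = bp,
                      a1 = "A", a2 = "G"),
    genotypes = g)
  segs <- callROH(p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_bp, bp[1])
  expect_equal(segs$end_bp, bp[m])
  expect_equal(segs$n_snps, m)
  # two heterozygotes in the middle break the single qualifying run
  g2 <- g
  g2[1, 40:41] <- 1L
  p2 <- p
  p2@genotypes <- g2
  segs2 <- callROH(p2)
  expect_true(all(segs2$n_het <= 1))
  expect_true(!any(segs2$start_bp <= bp[40] & segs2$end_bp >= bp[41]) ||
                nrow(segs2) == 0)
})

test_that("ROH caller equals the exhaustive interval oracle on random instances", {
  set.seed(31)
  for (trial in 1:120) {
    m <- sample(10:200, 1)
    g <- sample(c(0L, 1L, 2L, NA), m, TRUE, prob = c(.35, .12, .43, .10))
    bp <- sort(sample.int(m * 12L, m))
    mine <- founderscan:::.rohScanOne(g, bp, 10, 3, 2, 1)
    got <- cbind(match(mine$start_bp, bp), match(mine$end_bp, bp))
    oracle <- rohOracle(g, bp, 10, 3, 2, 1)
    expect_identical(unname(got), unname(oracle))
  }
})

test_that("every reported segment is maximal and satisfies all criteria", {
  co <- rohCohort(seed = 33)
  segs <- callROH(co)
  expect_gt(nrow(segs), 0)
  sn <- snpInfo(co)
  G <- genotypes(co)
  for (k in sample(nrow(segs), min(nrow(segs), 40))) {
    s <- segs[k, ]
    cols <- which(sn$chrom == s$chrom & sn$bp >= s$start_bp & sn$bp <= s$end_bp)
    g <- G[s$sample_id, cols]
    expect_gte(s$end_bp - s$start_bp, 1e6)
    expect_gte(length(cols), 50)
    expect_lte(sum(g == 1L, na.rm = TRUE), 1)
    expect_lte(sum(is.na(g)), 2)
    expect_true(g[1] != 1L && !is.na(g[1]))
    expect_true(g[length(g)] != 1L && !is.na(g[length(g)]))
    # extending one SNP left or right violates a criterion or hits the end
    chrom_cols <- which(sn$chrom == s$chrom)
    lo <- cols[1]; hi <- cols[length(cols)]
    if (lo > chrom_cols[1]) {
      gx <- G[s$sample_id, (lo - 1):hi]
      viol <- is.na(G[s$sample_id, lo - 1]) || G[s$sample_id, lo - 1] == 1L ||
        sum(gx == 1L, na.rm = TRUE) > 1 || sum(is.na(gx)) > 2
      expect_true(viol)
    }
    if (hi < chrom_cols[length(chrom_cols)]) {
      gx <- G[s$sample_id, lo:(hi + 1)]
      viol <- is.na(G[s$sample_id, hi + 1]) || G[s$sample_id, hi + 1] == 1L ||
        sum(gx == 1L, na.rm = TRUE) > 1 || sum(is.na(gx)) > 2
      expect_true(viol)
    }
  }
})

test_that("burden accounting is exact and planted recessives raise case burden", {
  samples <- data.frame(id = c("a", "b"), phenotype = c("case", "control"),
                        birth_year = c(1960L, 1900L))
  segs <- data.frame(sample_id = "a", chrom = 1L, start_bp = 1000L,
                     end_bp = 2646000L, n_snps = 60L, n_het = 0L,
                     n_missing = 0L)
  b <- rohBurden(segs, samples)
  expect_equal(b$genome_fraction[b$id == "a"], 0.001)
  expect_equal(b$n_segments[b$id == "b"], 0L)
  expect_equal(b$genome_fraction[b$id == "b"], 0)
  # planted recessive: mean case fraction exceeds mean control fraction
  co <- rohSignalCohort(seed = 35)
  sig <- plantedSignal("recessive_segment", 2, 2e6, 4e6, 0.3)
  ps <- plantSignal(co, sig, rng_seed = 36)
  bb <- rohBurden(callROH(ps), sampleInfo(ps))
  is_case <- sampleInfo(ps)$phenotype == "case"
  expect_gt(mean(bb$genome_fraction[is_case]),
            mean(bb$genome_fraction[!is_case]))
})

test_that("Fhat hits its closed-form anchors", {
  co <- indepCohort(n_cases = 60, n_controls = 60, span = 10e6, n_chrom = 1,
                    spacing = 10000, seed = 37, missing_rate = 0.005)
  f <- fhat(co)
  # panmictic cohort: mean F near 0
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(length(f)) + 0.01)
  # fully homozygous sample
  co2 <- co
  co2@genotypes[1, ] <- ifelse(is.na(co2@genotypes[1, ]), NA_integer_,
                               2L * (co2@genotypes[1, ] > 0L))
  f2 <- fhat(co2)
  expect_equal(unname(f2[1]), 1)
  # all-het sample has negative F
  co3 <- co
  co3@genotypes[2, ] <- 1L
  expect_lt(fhat(co3)[2], 0)
})

test_that("burden regression is calibrated under the null and powered when real", {
  covered <- vapply(1:30, function(s) {
    co <- rohCohort(seed = 400 + s)
    bb <- rohBurden(callROH(co), sampleInfo(co))
    br <- suppressWarnings(burdenRegression(bb, sampleInfo(co)))
    row <- br[br$metric == "genome_fraction", ]
    is.na(row$p) || (row$ci_low <= 1 & row$ci_high >= 1)
  }, TRUE)
  expect_gte(mean(covered), 0.9)
  # planted recessive in cases drives the fraction OR above 1
  up <- vapply(1:15, function(s) {
    co <- midRohCohort(seed = 500 + s)
    ps <- plantSignal(co, plantedSignal("recessive_segment", 1, 3e6, 6.5e6,
                                        0.35), rng_seed = s)
    bb <- rohBurden(callROH(ps), sampleInfo(ps))
    br <- suppressWarnings(burdenRegression(bb, sampleInfo(ps)))
    br$or_[br$metric == "genome_fraction"] > 1
  }, TRUE)
  expect_gte(mean(up), 0.9)
  # constant birth year: covariate dropped with a warning, fit proceeds
  co <- rohCohort(seed = 600)
  co@samples$birth_year <- 1950L
  bb <- rohBurden(callROH(co), sampleInfo(co))
  expect_warning(br <- burdenRegression(bb, sampleInfo(co)), "constant")
  expect_equal(nrow(br), 2)
})

test_that("consensus regions follow the breakpoint partition exactly", {
  samples <- data.frame(id = letters[1:5],
                        phenotype = c("case", "case", "case", "control",
                                      "control"),
                        birth_year = 1950L)
  snp_map <- data.frame(id = sprintf("c%03d", 1:100), chrom = 1L,
                        bp = seq(10000L, by = 10000L, length.out = 100))
  seg <- function(id, s, e) data.frame(sample_id = id, chrom = 1L,
                                       start_bp = s, end_bp = e,
                                       n_snps = 10L, n_het = 0L,
                                       n_missing = 0L)
  # three identical segments -> one region equal to their span
  segs3 <- rbind(seg("a", 100000, 400000), seg("b", 100000, 400000),
                 seg("c", 100000, 400000))
  r3 <- consensusRegions(segs3, snp_map, samples)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$start_bp, 100000L)
  expect_equal(r3$end_bp, 400000L)
  expect_equal(r3$carriers_case, 3L)
  # two carriers only: no region
  expect_equal(nrow(consensusRegions(segs3[1:2, ], snp_map, samples)), 0L)
  # staggered overlap: region = the stretch covered by all three
  stag <- rbind(seg("a", 100000, 500000), seg("b", 200000, 600000),
                seg("c", 300000, 700000))
  rs <- consensusRegions(stag, snp_map, samples)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$start_bp, 300000L)
  expect_equal(rs$end_bp, 500000L)
  # brute-force check over every breakpoint interval
  cuts <- sort(unique(c(stag$start_bp, stag$end_bp + 1L)))
  for (k in seq_len(length(cuts) - 1)) {
    iv <- c(cuts[k], cuts[k + 1] - 1L)
    n_cov <- sum(stag$start_bp <= iv[1] & stag$end_bp >= iv[2])
    inside <- iv[1] >= rs$start_bp & iv[2] <= rs$end_bp
    expect_equal(n_cov >= 3, inside)
  }
  # supply order must not matter
  rs2 <- consensusRegions(stag[c(3, 1, 2), ], snp_map, samples)
  expect_equal(rs$start_bp, rs2$start_bp)
  expect_equal(rs$end_bp, rs2$end_bp)
})

test_that("maxT correction controls the family-wise error and ranks planted regions", {
  co <- rohCohort(seed = 39)
  segs <- callROH(co)
  regs <- consensusRegions(segs, snpInfo(co), sampleInfo(co))
  expect_gt(nrow(regs), 0)
  tst <- maxtRegionTest(regs, sampleInfo(co), n_perm = 1500, seed = 40)
  expect_true(all(tst$p_corrected >= tst$p_empirical - 1e-12, na.rm = TRUE))
  # single region: corrected equals pointwise
  one <- maxtRegionTest(regs[1, , drop = FALSE], sampleInfo(co),
                        n_perm = 1000, seed = 41)
  expect_equal(one$p_corrected, one$p_empirical)
  # planted recessive carried by 25% of cases, 0 controls: minimum p
  cs <- rohSignalCohort(seed = 44)
  ps <- plantSignal(cs, plantedSignal("recessive_segment", 1, 4e6, 6e6, 0.25),
                    rng_seed = 42)
  regs2 <- consensusRegions(callROH(ps), snpInfo(ps), sampleInfo(ps))
  tst2 <- maxtRegionTest(regs2, sampleInfo(ps), n_perm = 1500, seed = 43)
  planted <- tst2[tst2$chrom == 1 & tst2$start_bp <= 6e6 & tst2$end_bp >= 4e6, ]
  expect_gt(nrow(planted), 0)
  expect_equal(min(planted$p_corrected), 1 / 1501)
})
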