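test_that("sample call-rate filter applies the 95% boundary correctly", {
  n <- 2; m <- 100
  g <- matrix(0L, 3, m)
  g[1, 1:4] <- NA   # 96% call rate: retained
  g[2, 1:6] <- NA   # 94%: removed
  p <- GenotypePanel(
    samples = data.frame(id = c("keep96", "drop94", "full")[c(1, 2, 3)],
                         phenotype = c("case", "case", "control")),
    snps = data.frame(id = sprintf("s%03d", 1:m), chrom = 1L,
                      bp = seq_len(m) * 10L, a1 = "A", a2 = "G"),
    genotypes = g)
  res <- sampleQC(p)
  expect_equal(res$report$rules$sample_call_rate$ids, "drop94")
  expect_equal(sampleInfo(res$panel)$id, c("keep96", "full"))
  # hand-computed removal set on a random fixture
  set.seed(3)
  g2 <- matrix(sample(c(0:2, NA), 50 * 40, TRUE, prob = c(.3, .3, .3, .1)),
               50, 40)
  p2 <- GenotypePanel(
    samples = data.frame(id = sprintf("i%02d", 1:50), phenotype = "control"),
    snps = data.frame(id = sprintf("s%02d", 1:40), chrom = 1L,
                      bp = seq_len(40) * 5L, a1 = "A", a2 = "G"),
    genotypes = g2)
  expected <- sprintf("i%02d", which(rowMeans(!is.na(g2)) < 0.95))
  expect_setequal(sampleQC(p2)$report$rules$sample_call_rate$ids, expected)
})

test_that("HWE exact test matches the enumeration oracle to 1e-12", {
  # independent oracle: enumerate all admissible het counts directly
  oracle <- function(h1, het, h2) {
    na <- 2 * h1 + het; nb <- 2 * h2 + het; n <- h1 + het + h2
    rare <- min(na, nb)
    hets <- seq(rare %% 2, rare, by = 2)
    pr <- vapply(hets, function(h) {
      exp(lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
            lfactorial((nb - h) / 2) + h * log(2) +
            lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
    }, 0)
    obs <- pr[hets == het]
    sum(pr[pr <= obs * (1 + 1e-9)])
  }
  expect_equal(hweExactTest(25, 50, 25), 1)       # modal table
  cases <- rbind(c(50, 0, 50), c(0, 10, 0), c(3, 5, 90), c(20, 10, 70),
                 c(1, 1, 98), c(10, 80, 10), c(0, 0, 7))
  for (k in seq_len(nrow(cases))) {
    h1 <- cases[k, 1]; het <- cases[k, 2]; h2 <- cases[k, 3]
    expect_equal(hweExactTest(h1, het, h2), oracle(h1, het, h2),
                 tolerance = 1e-12)
  }
  set.seed(8)
  for (k in 1:40) {
    n <- sample(5:100, 1)
    g <- table(factor(sample(0:2, n, TRUE), levels = 0:2))
    expect_equal(hweExactTest(g[[3]], g[[2]], g[[1]]),
                 oracle(g[[3]], g[[2]], g[[1]]), tolerance = 1e-12)
  }
  # all-het table agrees with chi-square within an order of magnitude
  p_exact <- hweExactTest(0, 10, 0)
  chi <- 10 * (4 * 0 * 0 - 5 * 5)^2 / (5 * 5 * 5 * 5)  # df 1 chi-square
  p_chi <- pchisq(10, df = 1, lower.tail = FALSE)
  expect_lt(abs(log10(p_exact) - log10(p_chi)), 1)
  expect_equal(hweExactTest(12, 0, 0), 1)  # monomorphic convention
})

test_that("SNP QC removes planted failures of each class", {
  set.seed(5)
  n <- 300; m <- 50
  # base: common SNPs in HWE
  g <- matrix(rbinom(n * m, 2, 0.3), n, m)
  g[sample(length(g), round(0.01 * length(g)))] <- NA
  # plant failures
  g[, 1] <- rbinom(n, 2, 0.004)                     # MAF < 0.01
  g[sample(n, 20), 2] <- NA                         # call rate 93%
  g[, 3] <- sample(c(0L, 2L), n, TRUE)              # no hets: HWE blowup
  p <- GenotypePanel(
    samples = data.frame(id = sprintf("i%03d", 1:n),
                         phenotype = rep(c("case", "control"), n / 2)),
    snps = data.frame(id = sprintf("s%02d", 1:m), chrom = 1L,
                      bp = seq_len(m) * 100L, a1 = "A", a2 = "G"),
    genotypes = g)
  res <- snpQC(p)
  r <- res$report$rules
  expect_true("s01" %in% r$maf$ids)
  expect_true("s02" %in% r$snp_call_rate$ids)
  expect_true("s03" %in% r$hwe_controls$ids || "s03" %in% r$hwe_cases$ids)
  expect_false("s10" %in% unlist(lapply(r, `[[`, "ids")))
  # control-HWE rule fires at 1e-4 even when cases pass:
  # plant deviation only in controls
  g2 <- g
  is_ctrl <- sampleInfo(p)$phenotype == "control"
  g2[is_ctrl, 4] <- sample(c(0L, 2L), sum(is_ctrl), TRUE)
  g2[!is_ctrl, 4] <- rbinom(sum(!is_ctrl), 2, 0.5)
  p2 <- GenotypePanel(samples = sampleInfo(p), snps = snpInfo(p), genotypes = g2)
  r2 <- snpQC(p2)$report$rules
  expect_true("s04" %in% r2$hwe_controls$ids)
})

test_that("QC filters commute with sample order", {
  co <- indepCohort(n_cases = 40, n_controls = 40, span = 1e6, n_chrom = 1,
                    spacing = 5000, seed = 71, missing_rate = 0.03)
  perm <- sample(nSamples(co))
  cop <- co[perm, ]
  a <- snpQC(co)$report$rules
  b <- snpQC(cop)$report$rules
  for (rule in names(a)) expect_setequal(a[[rule]]$ids, b[[rule]]$ids)
  expect_setequal(sampleQC(co)$report$rules$sample_call_rate$ids,
                  sampleQC(cop)$report$rules$sample_call_rate$ids)
})

test_that("differential missingness test is calibrated and detects planting", {
  # equal rates: p >= 0.05 in >= 94% of SNPs
  co <- indepCohort(n_cases = 500, n_controls = 500, span = 10e6, n_chrom = 1,
                    spacing = 10000, seed = 81, missing_rate = 0.05)
  p <- diffMissingnessTest(co)
  expect_gte(mean(p >= 0.05), 0.94)
  # missing only in cases, 50/300 vs 0/300: hand chi-square
  g <- matrix(1L, 600, 2)
  g[1:50, 1] <- NA
  pan <- GenotypePanel(
    samples = data.frame(id = sprintf("x%03d", 1:600),
                         phenotype = rep(c("case", "control"), each = 300)),
    snps = data.frame(id = c("a", "b"), chrom = 1L, bp = c(1L, 2L),
                      a1 = "A", a2 = "G"),
    genotypes = g)
  pv <- diffMissingnessTest(pan)
  chi_hand <- 600 * (50 * 300 - 250 * 0)^2 / (300 * 300 * 50 * 550)
  expect_equal(pv[["a"]], pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(pv[["a"]], 1e-5)
  expect_equal(pv[["b"]], 1)   # no missing calls
})

test_that("mishap test flags haplotype-conditional missingness only", {
  set.seed(91)
  n <- 600
  gl <- rbinom(n, 2, 0.5); gr <- rbinom(n, 2, 0.5)
  gf <- rbinom(n, 2, 0.5)
  # missing at focal SNP only when left flank is hom-alt
  gf[gl == 2L & runif(n) < 0.8] <- NA
  pan <- GenotypePanel(
    samples = data.frame(id = sprintf("m%03d", 1:n), phenotype = "control"),
    snps = data.frame(id = c("L", "F", "R"), chrom = 1L, bp = c(10L, 20L, 30L),
                      a1 = "A", a2 = "G"),
    genotypes = cbind(gl, gf, gr))
  p_mid <- mishapTest(pan, 2)
  expect_lt(as.numeric(p_mid), 1e-5)
  expect_false(attr(p_mid, "skipped"))
  # edge SNPs are skipped with p = 1
  p_edge <- mishapTest(pan, 1)
  expect_equal(as.numeric(p_edge), 1)
  expect_true(attr(p_edge, "skipped"))
  # no missing calls: p = 1
  pan2 <- pan
  pan2@genotypes[, 2] <- rbinom(n, 2, 0.5)
  expect_equal(as.numeric(mishapTest(pan2, 2)), 1)
  # independent missingness: p roughly uniform over replicates
  ps <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    gf2 <- rbinom(n, 2, 0.5); gf2[runif(n) < 0.05] <- NA
    pan@genotypes[, 2] <- gf2
    as.numeric(mishapTest(pan, 2))
  }, 0)
  expect_gt(mean(ps >= 0.05), 0.8)
})

test_that("pi-hat is invariant under allele-label flips", {
  co <- indepCohort(n_cases = 15, n_controls = 15, span = 5e6, n_chrom = 1,
                    spacing = 10000, seed = 95)
  co@metadata$ld_pruned <- TRUE
  k1 <- pairwiseIBD(co)
  flip <- sample(nSNPs(co), 200)
  co2 <- co
  co2@genotypes[, flip] <- 2L - co2@genotypes[, flip]
  k2 <- pairwiseIBD(co2)
  expect_equal(k1$pi_hat, k2$pi_hat, tolerance = 1e-12)
})

test_that("relatedness pruning removes the minimal greedy set", {
  co <- indepCohort(n_cases = 10, n_controls = 10, span = 2e6, n_chrom = 1,
                    spacing = 10000, seed = 101)
  kin <- data.frame(id1 = c("ind0001"), id2 = c("ind0002"), pi_hat = 0.6)
  res <- relatednessPrune(co, kin, 0.15)
  expect_length(res$report$rules$relatedness$ids, 1)
  # trio all mutually related: two removed
  kin3 <- data.frame(id1 = c("ind0001", "ind0001", "ind0002"),
                     id2 = c("ind0002", "ind0003", "ind0003"),
                     pi_hat = 0.6)
  res3 <- relatednessPrune(co, kin3, 0.15)
  expect_length(res3$report$rules$relatedness$ids, 2)
  # nothing above threshold: unchanged
  kin0 <- data.frame(id1 = "ind0001", id2 = "ind0002", pi_hat = 0.1)
  expect_equal(nSamples(relatednessPrune(co, kin0, 0.15)$panel), 20)
})

test_that("classical MDS reconstructs a hand-built Euclidean configuration", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 1))
  d <- as.matrix(dist(pts))
  ibs <- 1 - d / max(d) * 0.5      # map into IBS-like similarities
  diag(ibs) <- 1
  xy <- classicalMDS(ibs, k = 2)
  expect_equal(as.matrix(dist(xy)), as.matrix(dist(pts)) / max(d) * 0.5,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(colMeans(xy), c(C1 = 0, C2 = 0), tolerance = 1e-10)
  ev <- attr(xy, "eigenvalues")
  expect_true(all(diff(ev) <= 1e-9))
  # identical samples collapse to the origin
  same <- matrix(1, 4, 4)
  ws <- capture_warnings(xy0 <- classicalMDS(same, k = 2))
  expect_true(any(grepl("positive eigenvalue", ws)))
  expect_true(all(abs(xy0) < 1e-12))
})

test_that("dosage QC applies the RSQR boundary as strictly-less-than", {
  d <- DosageSet(
    samples = data.frame(id = c("a", "b")),
    snps = data.frame(id = c("q30", "q29", "rare"), chrom = 1L,
                      bp = 1:3, a1 = "A", a2 = "G"),
    dosages = rbind(c(1, 1, 0.01), c(0.8, 1.2, 0)),
    quality = c(0.30, 0.29, 0.9), freq = c(0.45, 0.5, 0.003))
  res <- dosageQC(d)
  expect_equal(snpInfo(res$dosages)$id, "q30")
  expect_true("q29" %in% res$report$rules$imputation_rsq$ids)
  expect_true("rare" %in% res$report$rules$dosage_maf$ids)
  # dosage MAF = mean dosage / 2, hand value
  expect_equal(unname(colMeans(dosages(d))[3] / 2), 0.0025)
})
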