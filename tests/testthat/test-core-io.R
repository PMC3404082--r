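test_that("GenotypePanel validity catches malformed input", {
  p <- tinyPanel()
  expect_s4_class(p, "GenotypePanel")
  expect_equal(nSamples(p), 4L)
  expect_equal(nSNPs(p), 6L)
  # unsorted map is re-sorted by the constructor, codes checked
  expect_error(GenotypePanel(
    samples = data.frame(id = "s1"),
    snps = data.frame(id = "x", chrom = 1L, bp = 10L, a1 = "A", a2 = "A"),
    genotypes = matrix(0L, 1, 1)), "alleles")
  expect_error(GenotypePanel(
    samples = data.frame(id = "s1"),
    snps = data.frame(id = "x", chrom = 23L, bp = 10L, a1 = "A", a2 = "G"),
    genotypes = matrix(0L, 1, 1)), "autosomal")
  expect_error(GenotypePanel(
    samples = data.frame(id = "s1"),
    snps = data.frame(id = "x", chrom = 1L, bp = 10L, a1 = "A", a2 = "G"),
    genotypes = matrix(5L, 1, 1)), "codes")
})

test_that("panel subsetting keeps tables and matrix aligned", {
  p <- tinyPanel()
  q <- p[c("s2", "s4"), c("rs1", "rs4")]
  expect_equal(sampleInfo(q)$id, c("s2", "s4"))
  expect_equal(snpInfo(q)$id, c("rs1", "rs4"))
  expect_equal(unname(genotypes(q)[, 1]), c(2L, 0L))
})

test_that("bed/bim/fam round trip is lossless, including missing codes", {
  p <- tinyPanel()
  prefix <- file.path(tempdir(), "rt_bed")
  writeGenotypes(p, prefix, "bed_bim_fam")
  q <- readGenotypes(prefix, "bed_bim_fam")
  expect_equal(genotypes(q), genotypes(p))
  expect_equal(snpInfo(q), snpInfo(p))
  expect_equal(sampleInfo(q)$phenotype, sampleInfo(p)$phenotype)
})

test_that("bed two-bit packing matches a hand-decoded byte table", {
  # 4 samples, 2 SNPs; codes per SNP: (2,1,0,NA) and (0,0,2,2)
  p <- GenotypePanel(
    samples = data.frame(id = paste0("s", 1:4)),
    snps = data.frame(id = c("a", "b"), chrom = 1L, bp = c(1L, 2L),
                      a1 = "A", a2 = "G"),
    genotypes = cbind(c(2L, 1L, 0L, NA), c(0L, 0L, 2L, 2L)))
  prefix <- file.path(tempdir(), "hand_bed")
  writeGenotypes(p, prefix, "bed_bim_fam")
  raw <- readBin(paste0(prefix, ".bed"), "raw", 5)
  expect_identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))
  # SNP 1: s1=00, s2=10, s3=11, s4=01 -> bits 01 11 10 00 = 0x78
  expect_identical(as.integer(raw[4]), strtoi("01111000", base = 2))
  # SNP 2: s1=11, s2=11, s3=00, s4=00 -> 0x0F
  expect_identical(as.integer(raw[5]), strtoi("00001111", base = 2))
})

test_that("ped/map round trip preserves genotype content", {
  p <- tinyPanel()
  prefix <- file.path(tempdir(), "rt_ped")
  writeGenotypes(p, prefix, "ped_map")
  q <- readGenotypes(prefix, "ped_map")
  # allele orientation in ped follows first observation; content matches
  # either directly or flipped, per SNP
  for (j in seq_len(nSNPs(p))) {
    g0 <- genotypes(p)[, j]; g1 <- genotypes(q)[, j]
    expect_true(identical(g0, g1) || identical(g0, 2L - g1))
  }
  # half/unknown calls read as missing
  expect_true(is.na(genotypes(q)["s3", "rs2"]))
  # write(read(.)) is byte-stable once allele orientation has been
  # normalised by one read (first-observed allele becomes a1)
  prefix2 <- file.path(tempdir(), "rt_ped2")
  prefix3 <- file.path(tempdir(), "rt_ped3")
  writeGenotypes(q, prefix2, "ped_map")
  writeGenotypes(readGenotypes(prefix2, "ped_map"), prefix3, "ped_map")
  expect_identical(readLines(paste0(prefix3, ".ped")),
                   readLines(paste0(prefix2, ".ped")))
  expect_identical(readLines(paste0(prefix3, ".map")),
                   readLines(paste0(prefix2, ".map")))
})

test_that("random panels survive both dialects (write then read)", {
  set.seed(7)
  for (trial in 1:3) {
    n <- 20; m <- 100
    g <- matrix(sample(c(0:2, NA), n * m, TRUE, prob = c(.3, .3, .3, .1)), n, m)
    p <- GenotypePanel(
      samples = data.frame(id = sprintf("i%02d", 1:n),
                           phenotype = rep(c("case", "control"), length.out = n)),
      snps = data.frame(id = sprintf("m%03d", 1:m),
                        chrom = rep(1:2, each = m / 2),
                        bp = rep(seq(1000, by = 997, length.out = m / 2), 2),
                        a1 = "A", a2 = "G"),
      genotypes = g)
    prefix <- file.path(tempdir(), paste0("rnd", trial))
    writeGenotypes(p, prefix, "bed_bim_fam")
    expect_equal(genotypes(readGenotypes(prefix, "bed_bim_fam")), genotypes(p))
  }
})

test_that("empty and all-missing panels round trip", {
  p0 <- GenotypePanel(samples = data.frame(id = c("a", "b")),
                      snps = data.frame(id = character(0), chrom = integer(0),
                                        bp = integer(0), a1 = character(0),
                                        a2 = character(0)),
                      genotypes = matrix(integer(0), 2, 0))
  prefix <- file.path(tempdir(), "empty")
  writeGenotypes(p0, prefix, "ped_map")
  q0 <- readGenotypes(prefix, "ped_map")
  expect_equal(nSNPs(q0), 0L)
  expect_equal(nSamples(q0), 2L)
  # all-missing sample writes "0 0" pairs
  p1 <- tinyPanel()
  p1@genotypes[4, ] <- NA_integer_
  writeGenotypes(p1, file.path(tempdir(), "allmiss"), "ped_map")
  line <- readLines(file.path(tempdir(), "allmiss.ped"))[4]
  expect_match(line, "( 0 0){6}$")
})

test_that("non-autosomal SNPs are dropped with a message", {
  dir <- tempdir()
  writeLines(c("1 rs1 0 100", "23 rsX 0 200", "2 rs2 0 300"),
             file.path(dir, "mix.map"))
  writeLines("f1 s1 0 0 0 2 A A G G C C", file.path(dir, "mix.ped"))
  expect_message(q <- readGenotypes(file.path(dir, "mix"), "ped_map"),
                 "non-autosomal")
  expect_equal(nSNPs(q), 2L)
  expect_equal(q@metadata$n_nonautosomal, 1L)
})

test_that("malformed ped/dosage lines raise parse errors naming the line", {
  dir <- tempdir()
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(dir, "badp.map"))
  writeLines("f1 s1 0 0 0 2 A A G", file.path(dir, "badp.ped"))
  expect_error(readGenotypes(file.path(dir, "badp"), "ped_map"), "line 1")
})

test_that("dosage reader clips, validates and attaches quality", {
  dir <- tempdir()
  writeLines(c("SNP Al1 Al2 Freq1 Rsq",
               "rs1 A G 0.30 0.95", "rs2 C T 0.10 0.29"),
             file.path(dir, "d.info"))
  writeLines(c("s1->s1 DOSE 1.37 0.50", "s2->s2 DOSE 2.0000004 0.00"),
             file.path(dir, "d.dose"))
  d <- readDosages(file.path(dir, "d.dose"), file.path(dir, "d.info"))
  expect_equal(dosages(d)[["s1", "rs1"]], 1.37)
  expect_equal(dosages(d)[["s2", "rs1"]], 2)   # clipped within tolerance
  expect_equal(snpInfo(d)$quality, c(0.95, 0.29))  # kept, not filtered here
  expect_equal(snpInfo(d)$freq, c(0.30, 0.10))
  # hard violation
  writeLines(c("s1->s1 DOSE 2.5 0.50"), file.path(dir, "d2.dose"))
  expect_error(readDosages(file.path(dir, "d2.dose"), file.path(dir, "d.info")),
               "outside")
  # column means match hand sums on a 3x5 fixture
  set.seed(1)
  dm <- matrix(round(runif(15, 0, 2), 3), 3, 5)
  writeLines(c("SNP Al1 Al2 Freq1 Rsq",
               sprintf("m%d A G 0.5 0.9", 1:5)), file.path(dir, "e.info"))
  writeLines(sprintf("p%d->p%d DOSE %s", 1:3, 1:3,
                     apply(dm, 1, function(r) paste(sprintf("%.3f", r), collapse = " "))),
             file.path(dir, "e.dose"))
  e <- readDosages(file.path(dir, "e.dose"), file.path(dir, "e.info"))
  expect_equal(unname(colMeans(dosages(e))), unname(colMeans(dm)), tolerance = 1e-12)
  # round trip through the writer
  writeDosages(e, file.path(dir, "e2.dose"), file.path(dir, "e2.info"))
  e2 <- readDosages(file.path(dir, "e2.dose"), file.path(dir, "e2.info"))
  expect_equal(dosages(e2), dosages(e), tolerance = 1e-3)
})

test_that("panel merging intersects on position and harmonises orientation", {
  a <- tinyPanel()
  # panel b: same positions for chr1 SNPs, swapped alleles at rs2-position,
  # irreconcilable at rs3-position, plus one position not in a
  b <- GenotypePanel(
    samples = data.frame(id = c("t1", "t2"),
                         phenotype = c("case", "control")),
    snps = data.frame(id = c("bx1", "bx2", "bx3", "bx4"),
                      chrom = c(1L, 1L, 1L, 1L),
                      bp = c(100L, 200L, 300L, 999L),
                      a1 = c("A", "T", "C", "A"),
                      a2 = c("G", "C", "T", "G")),
    genotypes = rbind(c(2L, 0L, 1L, 0L), c(1L, 2L, 0L, 1L)))
  m <- mergePanels(a, b)
  expect_equal(nSamples(m), 6L)
  # rs3 (G/A in a vs C/T in b) is irreconcilable and dropped
  expect_equal(snpInfo(m)$id, c("rs1", "rs2"))
  expect_equal(m@metadata$merge$n_irreconcilable, 1L)
  # rs2 is C/T in a, T/C in b: codes flip g -> 2 - g
  expect_equal(unname(genotypes(m)[c("t1", "t2"), "rs2"]), c(2L, 0L))
  # flip applied twice is the identity: merge a with itself relabelled
  expect_error(mergePanels(a, a), "duplicate")
})

test_that("strand-ambiguous SNPs are dropped at merge", {
  mk <- function(ids, a1, a2) GenotypePanel(
    samples = data.frame(id = ids),
    snps = data.frame(id = "x", chrom = 1L, bp = 50L, a1 = a1, a2 = a2),
    genotypes = matrix(1L, length(ids), 1))
  m <- mergePanels(mk("u1", "A", "T"), mk("v1", "A", "T"))
  expect_equal(nSNPs(m), 0L)
  expect_equal(m@metadata$merge$n_strand_ambiguous, 1L)
})

test_that("merge is symmetric on the SNP set and codes after orientation", {
  set.seed(11)
  base <- indepCohort(n_cases = 5, n_controls = 5, span = 1e6, n_chrom = 1,
                      spacing = 50000, seed = 40, missing_rate = 0)
  a <- base[1:5, ]
  b <- base[6:10, ]
  b@samples$id <- paste0("b_", b@samples$id)
  ab <- mergePanels(a, b)
  ba <- mergePanels(b, a)
  key <- function(x) paste(snpInfo(x)$chrom, snpInfo(x)$bp)
  expect_setequal(key(ab), key(ba))
  # orient ba to a's allele labels and compare a shared sample's codes
  sid <- sampleInfo(a)$id[1]
  ga <- genotypes(ab)[sid, ]
  gb <- genotypes(ba)[sid, ]
  flip <- snpInfo(ba)$a1[match(key(ab), key(ba))] != snpInfo(ab)$a1
  gb <- gb[match(key(ab), key(ba))]
  gb[flip] <- 2L - gb[flip]
  expect_equal(unname(ga), unname(gb))
})
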