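#' Simulation configuration
#'
#' Bundles the parameters of the synthetic case-control cohort generator.
#' Defaults emulate a population-isolate SNP-array study: ~400 cases and
#' ~500 controls, 22 model autosomes totalling 2,645 Mb, mean inter-SNP
#' spacing 8.75 kb (~302,000 autosomal SNPs), haplotype-block LD from finite
#' founder-haplotype pools, and light uniform missingness.  Tests and
#' examples shrink \code{chrom_lengths} and sample counts; the structure of
#' the data is unchanged.
#'
#' @param n_cases,n_controls sample counts per arm.
#' @param chrom_lengths named vector of chromosome lengths in bp (names are
#'   chromosome numbers 1-22).
#' @param snp_spacing_mean mean inter-SNP gap in bp (exponential gaps).
#' @param block_length_mean mean haplotype-block length in bp (exponential).
#' @param haplotypes_per_block founder-haplotype pool size per block.
#' @param maf_range range of per-SNP founder allele frequencies.
#' @param missing_rate uniform genotype missingness in [0, 1).
#' @param fst Balding-Nichols divergence between the two subpopulations
#'   (0 = panmictic).
#' @param n_related_pairs number of first-degree relatives appended.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_cases = 400L, n_controls = 500L,
                             chrom_lengths = defaultChromLengths(),
                             snp_spacing_mean = 8750,
                             block_length_mean = 100000,
                             haplotypes_per_block = 6L,
                             maf_range = c(0.01, 0.5),
                             missing_rate = 0.002,
                             fst = 0, n_related_pairs = 0L, seed = 1L) {
  chrom_lengths <- chrom_lengths[order(as.integer(names(chrom_lengths)))]
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              chrom_lengths = chrom_lengths,
              snp_spacing_mean = snp_spacing_mean,
              block_length_mean = block_length_mean,
              haplotypes_per_block = as.integer(haplotypes_per_block),
              maf_range = maf_range, missing_rate = missing_rate,
              fst = fst, n_related_pairs = as.integer(n_related_pairs),
              seed = as.integer(seed))
  stopifnot(cfg$n_cases > 0L, cfg$n_controls > 0L,
            all(cfg$chrom_lengths > 0), !is.null(names(cfg$chrom_lengths)),
            cfg$snp_spacing_mean > 0, cfg$block_length_mean > 0,
            cfg$haplotypes_per_block >= 2L,
            length(cfg$maf_range) == 2L, cfg$maf_range[1] > 0,
            cfg$maf_range[2] <= 0.5, cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$missing_rate >= 0, cfg$missing_rate < 1, cfg$fst >= 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a base genotype panel with haplotype-block LD
#'
#' The genome is partitioned into blocks of exponential length; each block
#' carries a finite pool of founder haplotypes with Dirichlet(1) frequencies,
#' and each individual draws two haplotypes per block independently.  Within
#' a block, SNPs are therefore in strong LD and autozygosity (both draws
#' landing on the same founder haplotype) arises naturally, which is what
#' the runs-of-homozygosity stage consumes.  Under \code{fst > 0}, samples
#' split evenly into two subpopulations whose block haplotype frequencies
#' are Balding-Nichols perturbations of the ancestral frequencies
#' (Dirichlet with concentration \code{f * (1 - fst) / fst}).
#'
#' Phenotypes are left unset; see [assignPhenotypes()].  Simulation
#' internals (block map, haplotype pools and per-sample draws) are kept in
#' \code{metadata$sim} so that [addRelatedPair()] can share haplotypes
#' identically by descent.
#'
#' @param config a [simulationConfig()].
#' @return A \linkS4class{GenotypePanel}; deterministic given the config seed.
#' @examples
#' cfg <- simulationConfig(n_cases = 10, n_controls = 10,
#'                         chrom_lengths = c("1" = 2e6), seed = 7)
#' simulateBasePanel(cfg)
#' @export
simulateBasePanel <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    n <- config$n_cases + config$n_controls
    pop <- if (config$fst > 0) rep_len(c(1L, 2L), n) else rep(1L, n)
    chroms <- as.integer(names(config$chrom_lengths))
    snp_list <- list(); geno_list <- list(); sim <- list()
    snp_counter <- 0L
    for (ci in seq_along(chroms)) {
      L <- config$chrom_lengths[ci]
      bp <- .snpPositions(L, config$snp_spacing_mean)
      m <- length(bp)
      if (m == 0L) next
      # block boundaries: exponential lengths, SNPs assigned by position
      ends <- .blockEnds(L, config$block_length_mean)
      block <- findInterval(bp, c(0, ends), rightmost.closed = TRUE)
      nb <- max(block)
      K <- config$haplotypes_per_block
      pools <- vector("list", nb); freqs <- vector("list", nb)
      hapA <- matrix(0L, n, nb); hapB <- matrix(0L, n, nb)
      G <- matrix(0L, n, m)
      for (b in seq_len(nb)) {
        idx <- which(block == b)
        mb <- length(idx)
        u <- stats::runif(max(mb, 1L), config$maf_range[1], config$maf_range[2])
        pool <- matrix(stats::rbinom(K * mb, 1L, rep(u, each = K)), K, mb)
        f <- .rdirichlet(rep(1, K))
        fpop <- if (config$fst > 0) {
          rbind(.rdirichlet(f * (1 - config$fst) / config$fst),
                .rdirichlet(f * (1 - config$fst) / config$fst))
        } else matrix(f, 1, K, byrow = TRUE)
        hA <- integer(n); hB <- integer(n)
        for (p in seq_len(nrow(fpop))) {
          who <- which(pop == p)
          hA[who] <- sample.int(K, length(who), replace = TRUE, prob = fpop[p, ])
          hB[who] <- sample.int(K, length(who), replace = TRUE, prob = fpop[p, ])
        }
        if (mb > 0)
          G[, idx] <- pool[hA, , drop = FALSE] + pool[hB, , drop = FALSE]
        pools[[b]] <- pool; freqs[[b]] <- fpop
        hapA[, b] <- hA; hapB[, b] <- hB
      }
      snp_list[[ci]] <- data.frame(
        id = sprintf("snp%d_%d", chroms[ci], seq_len(m) + snp_counter),
        chrom = chroms[ci], bp = bp,
        a1 = "A", a2 = "G", stringsAsFactors = FALSE)
      snp_counter <- snp_counter + m
      geno_list[[ci]] <- G
      sim[[as.character(chroms[ci])]] <- list(
        block = block, pools = pools, freqs = freqs, hapA = hapA, hapB = hapB)
    }
    samples <- data.frame(
      id = sprintf("ind%04d", seq_len(n)), phenotype = NA_character_,
      birth_year = NA_integer_, stringsAsFactors = FALSE)
    panel <- GenotypePanel(samples = samples, snps = do.call(rbind, snp_list),
                           genotypes = do.call(cbind, geno_list),
                           metadata = list(sim = sim, pop = pop,
                                           config = config))
    if (config$missing_rate > 0)
      panel <- addMissingness(panel, config$missing_rate,
                              rng_seed = config$seed + 101L)
    if (config$n_related_pairs > 0) {
      for (k in seq_len(config$n_related_pairs))
        panel <- addRelatedPair(panel, panel@samples$id[k],
                                rng_seed = config$seed + 200L + k)
    }
    panel
  })
}

.snpPositions <- function(L, spacing) {
  n_max <- ceiling(L / spacing * 1.4) + 50L
  gaps <- stats::rexp(n_max, 1 / spacing)
  bp <- cumsum(gaps)
  while (bp[length(bp)] < L) {
    gaps <- stats::rexp(n_max, 1 / spacing)
    bp <- c(bp, bp[length(bp)] + cumsum(gaps))
  }
  bp <- unique(pmax(1L, as.integer(round(bp[bp <= L]))))
  sort(bp)
}

.blockEnds <- function(L, mean_len) {
  ends <- numeric(0); at <- 0
  while (at < L) {
    at <- at + stats::rexp(1, 1 / mean_len)
    ends <- c(ends, min(at, L))
  }
  ends[length(ends)] <- L
  ends
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Specify a planted founder signal
#'
#' @param kind \code{"dominant_haplotype"} (one chromosome copy overwritten
#'   by a fixed founder haplotype in carriers) or \code{"recessive_segment"}
#'   (both copies overwritten, producing a homozygous run).
#' @param chrom,start_bp,end_bp region of the signal.
#' @param case_carrier_fraction,control_carrier_fraction fraction of cases /
#'   controls made carriers.
#' @return A list of class \code{"PlantedSignal"}.
#' @export
plantedSignal <- function(kind = c("dominant_haplotype", "recessive_segment"),
                          chrom, start_bp, end_bp,
                          case_carrier_fraction,
                          control_carrier_fraction = 0) {
  kind <- match.arg(kind)
  stopifnot(end_bp > start_bp, case_carrier_fraction > 0,
            case_carrier_fraction <= 1, control_carrier_fraction >= 0,
            control_carrier_fraction < 1)
  if (kind == "recessive_segment" && end_bp - start_bp < 1e6)
    stop("recessive segments must span at least 1 Mb to be ROH-detectable",
         call. = FALSE)
  structure(list(kind = kind, chrom = as.integer(chrom),
                 start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                 case_carrier_fraction = case_carrier_fraction,
                 control_carrier_fraction = control_carrier_fraction),
            class = "PlantedSignal")
}

#' Plant a founder signal into a panel
#'
#' Overwrites genotypes in the signal region for a seeded random subset of
#' cases (and optionally controls).  The founder haplotype is drawn once
#' from the region's allele frequencies.  For a dominant signal each
#' carrier's genotype becomes founder allele + one of the carrier's original
#' allele copies (the copy resolved at random for heterozygotes); for a
#' recessive signal both copies are overwritten, so carriers are homozygous
#' and mutually identical across the region.
#'
#' @param panel a phenotyped \linkS4class{GenotypePanel}.
#' @param signal a [plantedSignal()].
#' @param rng_seed integer seed.
#' @return The modified panel; \code{metadata$planted} accumulates the
#'   signal, its SNP range and the carrier ids.
#' @export
plantSignal <- function(panel, signal, rng_seed) {
  stopifnot(is(panel, "GenotypePanel"), inherits(signal, "PlantedSignal"))
  idx <- which(panel@snps$chrom == signal$chrom &
               panel@snps$bp >= signal$start_bp &
               panel@snps$bp <= signal$end_bp)
  if (!length(idx))
    stop("signal region contains no SNPs in the panel map", call. = FALSE)
  if (signal$kind == "recessive_segment" && length(idx) < 50L)
    stop("recessive signal region must contain at least 50 SNPs", call. = FALSE)
  .withSeed(rng_seed, {
    ph <- panel@samples$phenotype
    if (anyNA(ph)) stop("assign phenotypes before planting signals", call. = FALSE)
    p <- .alleleFreq(panel@genotypes[, idx, drop = FALSE])
    founder <- stats::rbinom(length(idx), 1L, pmin(pmax(p, 0.05), 0.95))
    pick <- function(ids, frac) {
      k <- round(frac * length(ids))
      if (k == 0) character(0) else sample(ids, k)
    }
    carriers <- c(pick(panel@samples$id[ph == "case"], signal$case_carrier_fraction),
                  pick(panel@samples$id[ph == "control"], signal$control_carrier_fraction))
    rows <- match(carriers, panel@samples$id)
    G <- panel@genotypes
    for (r in rows) {
      g <- G[r, idx]
      if (signal$kind == "recessive_segment") {
        G[r, idx] <- 2L * founder
      } else {
        # keep one original copy: 0 -> ref allele 0, 2 -> 1, het -> coin flip
        other <- ifelse(is.na(g), stats::rbinom(length(g), 1L, p),
                 ifelse(g == 0L, 0L, ifelse(g == 2L, 1L,
                        stats::rbinom(length(g), 1L, 0.5))))
        G[r, idx] <- founder + other
      }
    }
    panel@genotypes <- G
    panel@metadata$planted <- c(panel@metadata$planted, list(list(
      signal = signal, snp_idx = idx, founder = founder, carriers = carriers)))
    panel
  })
}

#' Specify a risk locus with a published odds ratio
#'
#' @param snp_id SNP identifier present in the target panel/dosage set.
#' @param risk_allele the allele the odds ratio refers to.
#' @param odds_ratio published per-allele odds ratio (> 0; values < 1 mean
#'   the named allele is protective).
#' @param risk_allele_freq population frequency of that allele.
#' @return A list of class \code{"RiskLocusSpec"}.
#' @export
riskLocus <- function(snp_id, risk_allele, odds_ratio, risk_allele_freq) {
  stopifnot(odds_ratio > 0, risk_allele_freq > 0, risk_allele_freq < 1)
  structure(list(snp_id = as.character(snp_id),
                 risk_allele = as.character(risk_allele),
                 odds_ratio = odds_ratio,
                 risk_allele_freq = risk_allele_freq),
            class = "RiskLocusSpec")
}

#' Assign case/control phenotypes by a logistic risk model
#'
#' Disease odds per sample are \code{exp(sum_j log(OR_j) * x_j)} with
#' \code{x_j} the carried copies of each risk allele (independent additive
#' loci).  Exactly \code{n_cases} samples are drawn as cases without
#' replacement with probability proportional to their odds — the
#' retrospective case-control construction, which hits the requested counts
#' exactly while preserving per-allele odds ratios; \code{n_controls}
#' controls are drawn uniformly from the remainder and any surplus samples
#' are dropped.  Birth years are then drawn from distinct case and control
#' distributions, emulating an age-discrepant design (young-onset cases,
#' elderly controls).
#'
#' @param panel a \linkS4class{GenotypePanel} with at least
#'   \code{n_cases + n_controls} samples.
#' @param risk_loci list of [riskLocus()] specs (possibly empty: labels are
#'   then assigned at random).
#' @param n_cases,n_controls requested counts.
#' @param rng_seed integer seed.
#' @return The panel restricted to the sampled cohort, phenotypes and birth
#'   years filled in.
#' @export
assignPhenotypes <- function(panel, risk_loci, n_cases, n_controls, rng_seed) {
  stopifnot(is(panel, "GenotypePanel"))
  n <- nSamples(panel)
  if (n < n_cases + n_controls)
    stop("panel has fewer samples than n_cases + n_controls", call. = FALSE)
  .withSeed(rng_seed, {
    eta <- rep(0, n)
    for (rl in risk_loci) {
      j <- match(rl$snp_id, panel@snps$id)
      if (is.na(j)) stop("risk SNP not in panel: ", rl$snp_id, call. = FALSE)
      g <- panel@genotypes[, j]
      x <- if (rl$risk_allele == panel@snps$a1[j]) g
           else if (rl$risk_allele == panel@snps$a2[j]) 2L - g
           else stop("risk allele matches neither allele at ", rl$snp_id,
                     call. = FALSE)
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      eta <- eta + log(rl$odds_ratio) * x
    }
    w <- exp(eta - max(eta))
    case_idx <- sample.int(n, n_cases, prob = w)
    rest <- setdiff(seq_len(n), case_idx)
    ctrl_idx <- if (length(rest) > n_controls) sample(rest, n_controls) else rest
    keep <- sort(c(case_idx, ctrl_idx))
    out <- panel[keep, ]
    is_case <- keep %in% case_idx
    out@samples$phenotype <- ifelse(is_case, "case", "control")
    by <- integer(length(keep))
    by[is_case] <- as.integer(round(stats::rnorm(sum(is_case), 1948, 10)))
    by[!is_case] <- as.integer(round(stats::rnorm(sum(!is_case), 1930, 10)))
    out@samples$birth_year <- pmin(pmax(by, 1851L), 2009L)
    # subset the stored haplotype draws to the sampled cohort
    if (!is.null(out@metadata$sim)) {
      out@metadata$sim <- lapply(out@metadata$sim, function(s) {
        s$hapA <- s$hapA[keep, , drop = FALSE]
        s$hapB <- s$hapB[keep, , drop = FALSE]
        s
      })
      out@metadata$pop <- out@metadata$pop[keep]
    }
    out
  })
}

#' Add genotype missingness
#'
#' Uniform missingness at \code{rate} everywhere; SNPs listed in
#' \code{differential_snps} instead get \code{case_rate} in cases (and
#' \code{rate} in controls), to exercise the differential-missingness
#' filter.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param rate uniform missing rate in [0, 1).
#' @param differential_snps character vector of SNP ids.
#' @param case_rate missing rate applied to cases at those SNPs.
#' @param rng_seed integer seed.
#' @return The panel with genotypes set to \code{NA}.
#' @export
addMissingness <- function(panel, rate, differential_snps = character(0),
                           case_rate = rate, rng_seed = 1L) {
  stopifnot(rate >= 0, rate < 1, case_rate >= 0, case_rate < 1)
  if (rate == 0 && (case_rate == 0 || !length(differential_snps))) return(panel)
  .withSeed(rng_seed, {
    G <- panel@genotypes
    n <- nrow(G); m <- ncol(G)
    R <- matrix(rate, n, m)
    if (length(differential_snps)) {
      j <- match(differential_snps, panel@snps$id)
      if (anyNA(j)) stop("unknown differential SNP id", call. = FALSE)
      is_case <- !is.na(panel@samples$phenotype) & panel@samples$phenotype == "case"
      R[is_case, j] <- case_rate
    }
    G[stats::runif(n * m) < R] <- NA_integer_
    panel@genotypes <- G
    panel
  })
}

#' Append a synthetic relative of a named sample
#'
#' Creates a new sample sharing alleles identically by descent with the
#' named sample, using the haplotype pools stored by [simulateBasePanel()]:
#' a first-degree relative shares exactly one haplotype per block (the
#' other drawn fresh from the block pool); a duplicate shares both.
#'
#' @param panel a panel produced by [simulateBasePanel()].
#' @param sample_id the existing sample to relate to.
#' @param rng_seed integer seed.
#' @param degree \code{"first"} or \code{"duplicate"}.
#' @return The panel with one appended sample (\code{<id>_rel<k>}).
#' @export
addRelatedPair <- function(panel, sample_id, rng_seed, degree = c("first", "duplicate")) {
  degree <- match.arg(degree)
  sim <- panel@metadata$sim
  if (is.null(sim))
    stop("panel lacks simulation metadata; relatives need haplotype pools",
         call. = FALSE)
  r <- match(sample_id, panel@samples$id)
  if (is.na(r)) stop("no such sample: ", sample_id, call. = FALSE)
  .withSeed(rng_seed, {
    pop <- panel@metadata$pop[r]
    newg <- integer(0)
    for (ch in names(sim)) {
      s <- sim[[ch]]
      nb <- length(s$pools)
      K <- nrow(s$pools[[1]])
      hA <- integer(nb); hB <- integer(nb)
      for (b in seq_len(nb)) {
        shareA <- if (stats::runif(1) < 0.5) s$hapA[r, b] else s$hapB[r, b]
        hA[b] <- shareA
        hB[b] <- if (degree == "duplicate") {
          if (stats::runif(1) < 0.5) s$hapA[r, b] else s$hapB[r, b]
        } else {
          f <- s$freqs[[b]][min(pop, nrow(s$freqs[[b]])), ]
          sample.int(K, 1, prob = f)
        }
      }
      if (degree == "duplicate") { hA <- s$hapA[r, ]; hB <- s$hapB[r, ] }
      gch <- integer(length(s$block))
      for (b in seq_len(nb)) {
        idx <- which(s$block == b)
        if (length(idx))
          gch[idx] <- s$pools[[b]][hA[b], ] + s$pools[[b]][hB[b], ]
      }
      sim[[ch]]$hapA <- rbind(s$hapA, hA)
      sim[[ch]]$hapB <- rbind(s$hapB, hB)
      newg <- c(newg, gch)
    }
    k <- sum(grepl(paste0("^", sample_id, "_rel"), panel@samples$id)) + 1L
    new_id <- sprintf("%s_rel%d", sample_id, k)
    samples <- rbind(panel@samples,
                     data.frame(id = new_id,
                                phenotype = panel@samples$phenotype[r],
                                birth_year = panel@samples$birth_year[r],
                                stringsAsFactors = FALSE))
    panel@metadata$sim <- sim
    panel@metadata$pop <- c(panel@metadata$pop, pop)
    GenotypePanel(samples = samples, snps = panel@snps,
                  genotypes = rbind(panel@genotypes, newg),
                  metadata = panel@metadata)
  })
}

#' Simulate a risk-locus cohort
#'
#' Generates independent genotypes at the loci of a risk table (binomial at
#' the stated allele frequencies, allele 1 = the stated allele) for a large
#' sample pool, then assigns case/control status with [assignPhenotypes()]
#' at the published per-allele odds ratios.  Returns both the hard-call
#' panel and a matching \linkS4class{DosageSet} (dosage = genotype, quality
#' 1), ready for [riskProfile()].
#'
#' @param risk_table a table in the [pdRiskLoci()] layout.
#' @param n_cases,n_controls cohort arm sizes.
#' @param seed integer seed.
#' @param pool_factor pool oversampling factor (default 2).
#' @return list(panel, dosages, risk_loci).
#' @export
simulateRiskCohort <- function(risk_table, n_cases, n_controls, seed,
                               pool_factor = 2) {
  n_pool <- ceiling(pool_factor * (n_cases + n_controls))
  m <- nrow(risk_table)
  .withSeed(seed, {
    G <- vapply(seq_len(m), function(j)
      stats::rbinom(n_pool, 2L, risk_table$freq[j]), integer(n_pool))
    panel <- GenotypePanel(
      samples = data.frame(id = sprintf("ind%05d", seq_len(n_pool)),
                           stringsAsFactors = FALSE),
      snps = data.frame(id = risk_table$SNP, chrom = risk_table$chrom,
                        bp = risk_table$bp, a1 = risk_table$risk_allele,
                        a2 = risk_table$other_allele, stringsAsFactors = FALSE),
      genotypes = G)
    loci <- riskLociFromTable(risk_table)
    panel <- assignPhenotypes(panel, loci, n_cases, n_controls,
                              rng_seed = seed + 1L)
    dset <- DosageSet(samples = panel@samples, snps = panel@snps,
                      dosages = panel@genotypes,
                      quality = rep(1, nSNPs(panel)),
                      freq = pmax(pmin(.alleleFreq(panel@genotypes), 0.999), 0.001))
    list(panel = panel, dosages = dset, risk_loci = loci)
  })
}
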