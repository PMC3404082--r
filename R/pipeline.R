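#' Pipeline configuration
#'
#' Builds and validates the configuration for [runPipeline()].  Every
#' analysis threshold is a named default here; unknown keys are rejected
#' before any stage runs.  The configuration can also be read from a YAML
#' file with [readPipelineConfig()].
#'
#' @param ... overrides of the defaults (see \code{pipelineDefaults()}).
#' @return Validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  defaults <- pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$n_perm_window >= 1, cfg$n_perm_region >= 1,
            cfg$window_bp > 0, cfg$step_bp > 0, cfg$step_bp <= cfg$window_bp,
            cfg$seed == as.integer(cfg$seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @export
pipelineDefaults <- function() {
  list(
    # cohort simulation
    n_cases = 100L, n_controls = 100L,
    chrom_lengths = defaultChromLengths()[1:2] / 20,
    snp_spacing_mean = 8750, block_length_mean = 100000,
    haplotypes_per_block = 6L, maf_range = c(0.01, 0.5),
    missing_rate = 0.002, fst = 0, n_related_pairs = 0L,
    # QC thresholds
    min_sample_call_rate = 0.95, min_snp_call_rate = 0.95, min_maf = 0.01,
    hwe_p_controls = 1e-4, hwe_p_cases = 1e-7, diff_missing_p = 1e-5,
    mishap_p = 1e-5, pi_hat_max = 0.15, dosage_min_rsq = 0.30,
    # LD pruning
    prune_window_snps = 50L, prune_step_snps = 5L, vif_max = 1.05,
    # association / profile
    gwas_alpha = 5e-8, n_mds_components = 2L, risk_table = NULL,
    # IBS windows
    window_bp = 500000L, step_bp = 250000L, n_perm_window = 10000L,
    # ROH
    roh_min_len_bp = 1000000L, roh_min_snps = 50L, roh_max_missing = 2L,
    roh_max_het = 1L, region_min_snps = 3L, region_min_len_bp = 100000L,
    region_min_carriers = 3L, n_perm_region = 50000L,
    genome_length_bp = autosomeGenomeLength(),
    # orchestration
    stages = c("simulate", "qc", "prune", "gwas", "profile", "ibs_scan",
               "roh_scan"),
    out_dir = NULL, seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of key: value overrides.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$chrom_lengths))
    raw$chrom_lengths <- unlist(raw$chrom_lengths)
  do.call(pipelineConfig, raw)
}

# Deterministic per-stage seed derived from the global seed and the stage
# name (character-code hash), so stages are independently reproducible.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) + 10007L * sum(utf8ToInt(stage))) %% 2147483587L
}

#' Run the founder-screening pipeline
#'
#' Runs the configured stages in fixed order on a simulated cohort:
#' simulate, QC (sample call rate, SNP filters, missingness tests,
#' relatedness, MDS covariates), VIF LD pruning, dosage GWAS (on hard-call
#' dosages) with genomic lambda, cumulative risk profile, sliding-window
#' IBS permutation scan, and ROH calling with consensus-region maxT
#' association.  Each stage writes its TSV outputs and a log entry with
#' input/output dimensions; a MANIFEST lists every file written.
#'
#' @param config a [pipelineConfig()]; \code{out_dir} must be set.
#' @return Invisibly, a list with the per-stage results and the log.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir must be set", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  manifest <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log <<- c(log, line)
    message(line)
  }
  emit <- function(path) manifest <<- c(manifest, basename(path))
  res <- list()

  # --- simulate -------------------------------------------------------
  cfg_sim <- simulationConfig(
    n_cases = config$n_cases, n_controls = config$n_controls,
    chrom_lengths = config$chrom_lengths,
    snp_spacing_mean = config$snp_spacing_mean,
    block_length_mean = config$block_length_mean,
    haplotypes_per_block = config$haplotypes_per_block,
    maf_range = config$maf_range, missing_rate = config$missing_rate,
    fst = config$fst, n_related_pairs = config$n_related_pairs,
    seed = .stageSeed(config$seed, "simulate"))
  panel <- simulateBasePanel(cfg_sim)
  panel <- assignPhenotypes(panel, list(), config$n_cases, config$n_controls,
                            rng_seed = .stageSeed(config$seed, "phenotype"))
  note("simulate: %d samples x %d SNPs", nSamples(panel), nSNPs(panel))
  writeGenotypes(panel, file.path(out_dir, "cohort"), "bed_bim_fam")
  emit(file.path(out_dir, "cohort.bed"))
  res$panel <- panel
  if (!"qc" %in% config$stages)
    return(invisible(.finishPipeline(res, log, manifest, out_dir)))

  # --- qc -------------------------------------------------------------
  th <- qcThresholds(
    min_sample_call_rate = config$min_sample_call_rate,
    min_snp_call_rate = config$min_snp_call_rate, min_maf = config$min_maf,
    hwe_p_controls = config$hwe_p_controls, hwe_p_cases = config$hwe_p_cases,
    diff_missing_p = config$diff_missing_p, mishap_p = config$mishap_p,
    pi_hat_max = config$pi_hat_max, dosage_min_rsq = config$dosage_min_rsq)
  sq <- sampleQC(panel, th)
  kq <- snpQC(sq$panel, th)
  mq <- missingnessQC(kq$panel, th)
  qc_panel <- mq$panel
  note("qc: %d -> %d samples, %d -> %d SNPs", nSamples(panel),
       nSamples(qc_panel), nSNPs(panel), nSNPs(qc_panel))
  report <- .qcReport()
  report$rules <- c(sq$report$rules, kq$report$rules, mq$report$rules)

  # --- prune (needed for relatedness & MDS) ---------------------------
  pr <- vifPrune(qc_panel, config$prune_window_snps, config$prune_step_snps,
                 config$vif_max)
  note("prune: kept %d of %d SNPs (VIF > %.3f removed)",
       length(pr$keep), nSNPs(qc_panel), config$vif_max)
  writeLines(pr$keep, file.path(out_dir, "prune.in"))
  writeLines(pr$remove, file.path(out_dir, "prune.out"))
  emit(file.path(out_dir, "prune.in")); emit(file.path(out_dir, "prune.out"))

  kin <- pairwiseIBD(pr$panel)
  rp <- relatednessPrune(qc_panel, kin, config$pi_hat_max)
  qc_panel <- rp$panel
  pruned <- pr$panel[match(qc_panel@samples$id, pr$panel@samples$id), ]
  report$rules <- c(report$rules, rp$report$rules)
  writeQCReport(report, file.path(out_dir, "qc_report.tsv"))
  emit(file.path(out_dir, "qc_report.tsv"))
  note("relatedness: removed %d sample(s)", length(rp$report$rules$relatedness$ids))

  mds <- classicalMDS(pairwiseIBS(pruned), k = config$n_mds_components)
  res$qc_panel <- qc_panel; res$pruned <- pruned; res$mds <- mds
  res$qc_report <- report

  # --- gwas -----------------------------------------------------------
  if ("gwas" %in% config$stages) {
    dset <- DosageSet(samples = qc_panel@samples, snps = qc_panel@snps,
                      dosages = qc_panel@genotypes,
                      quality = rep(1, nSNPs(qc_panel)),
                      freq = pmin(pmax(.alleleFreq(qc_panel@genotypes),
                                       1e-3), 1 - 1e-3))
    dq <- dosageQC(dset, th)
    scan <- logisticDosageScan(dq$dosages, mds, config$n_mds_components)
    lambda <- genomicLambda(scan$p[!is.na(scan$p)])
    hits <- flagGenomewide(scan, config$gwas_alpha)
    writeAssocResults(scan, file.path(out_dir, "gwas.tsv"))
    emit(file.path(out_dir, "gwas.tsv"))
    note("gwas: %d SNPs tested, lambda = %.4f, %d genome-wide hit(s)",
         sum(!is.na(scan$p)), lambda, length(hits))
    res$gwas <- scan; res$lambda <- lambda; res$hits <- hits
  }

  # --- profile --------------------------------------------------------
  if ("profile" %in% config$stages) {
    tab <- if (is.null(config$risk_table)) pdRiskLoci() else config$risk_table
    rc <- simulateRiskCohort(tab, config$n_cases, config$n_controls,
                             seed = .stageSeed(config$seed, "profile"))
    prof <- riskProfile(rc$dosages, rc$risk_loci)
    utils::write.table(prof$quintile_or, file.path(out_dir, "risk_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "risk_profile.tsv"))
    note("profile: trend p = %.3g, AUC = %.3f", prof$trend_p, prof$auc)
    res$profile <- prof
  }

  # --- ibs scan -------------------------------------------------------
  if ("ibs_scan" %in% config$stages) {
    win <- windowPermutationTest(
      pruned, n_perm = config$n_perm_window,
      seed = .stageSeed(config$seed, "ibs_scan"),
      size_bp = config$window_bp, step_bp = config$step_bp,
      chrom_lengths = config$chrom_lengths)
    writeWindowResults(win, file.path(out_dir, "ibs_windows.tsv"))
    emit(file.path(out_dir, "ibs_windows.tsv"))
    gw <- genomewideIBSTest(pruned, n_perm = min(config$n_perm_window, 2000L),
                            seed = .stageSeed(config$seed, "ibs_gw"))
    note("ibs: %d windows (%d testable), min empirical p = %.3g; genome-wide p = %.3g",
         nrow(win), sum(win$testable), min(win$p_empirical, na.rm = TRUE), gw$p)
    res$ibs_windows <- win; res$ibs_genomewide <- gw
  }

  # --- roh scan -------------------------------------------------------
  if ("roh_scan" %in% config$stages) {
    segs <- callROH(pruned, config$roh_min_len_bp, config$roh_min_snps,
                    config$roh_max_missing, config$roh_max_het)
    writeROHSegments(segs, file.path(out_dir, "roh_segments.tsv"))
    emit(file.path(out_dir, "roh_segments.tsv"))
    bur <- rohBurden(segs, pruned@samples, config$genome_length_bp)
    fh <- fhat(pruned)
    breg <- suppressWarnings(burdenRegression(bur, pruned@samples, mds))
    regs <- consensusRegions(segs, pruned@snps, pruned@samples,
                             config$region_min_snps, config$region_min_len_bp,
                             config$region_min_carriers)
    if (nrow(regs)) {
      regs <- maxtRegionTest(regs, pruned@samples, config$n_perm_region,
                             seed = .stageSeed(config$seed, "roh_scan"))
    }
    writeConsensusRegions(regs, file.path(out_dir, "roh_regions.tsv"))
    emit(file.path(out_dir, "roh_regions.tsv"))
    note("roh: %d segment(s), %d consensus region(s); Fhat range [%.3f, %.3f]",
         nrow(segs), nrow(regs), min(fh, na.rm = TRUE), max(fh, na.rm = TRUE))
    res$roh_segments <- segs; res$roh_burden <- bur
    res$roh_regions <- regs; res$fhat <- fh; res$burden_regression <- breg
  }

  invisible(.finishPipeline(res, log, manifest, out_dir))
}

.finishPipeline <- function(res, log, manifest, out_dir) {
  writeLines(log, file.path(out_dir, "pipeline.log"))
  writeLines(sort(unique(c(manifest, "pipeline.log", "MANIFEST"))),
             file.path(out_dir, "MANIFEST"))
  res$log <- log
  res
}
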