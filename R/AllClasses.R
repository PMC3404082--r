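#' @import methods
NULL

#' GenotypePanel: case-control SNP-array genotypes
#'
#' Container for a case-control genotype panel: a sample table, an autosomal
#' SNP map sorted by (chromosome, position), and a samples x SNPs matrix of
#' genotype codes counting copies of allele \code{a1} (0, 1, 2, or \code{NA}
#' for missing).  Missing is always \code{NA}, never 0.
#'
#' @slot samples data.frame with columns \code{id} (character, unique),
#'   \code{phenotype} (\code{"case"}, \code{"control"} or \code{NA}) and
#'   \code{birth_year} (integer or \code{NA}).
#' @slot snps data.frame with columns \code{id}, \code{chrom} (integer 1-22),
#'   \code{bp} (integer, 1-based), \code{a1}, \code{a2} (single bases,
#'   distinct), strictly sorted by (\code{chrom}, \code{bp}).
#' @slot genotypes integer matrix, samples x SNPs, values in \{0,1,2,NA\};
#'   code = copies of \code{a1}.
#' @slot metadata list of free-form provenance (simulation internals, merge
#'   reports, logs).
#'
#' @seealso [readGenotypes()], [simulateBasePanel()], [DosageSet-class]
#' @export
setClass("GenotypePanel",
  slots = c(
    samples   = "data.frame",
    snps      = "data.frame",
    genotypes = "matrix",
    metadata  = "list"
  )
)

.validSnpTable <- function(snps, require_order = TRUE) {
  need <- c("id", "chrom", "bp", "a1", "a2")
  if (!all(need %in% names(snps)))
    return(sprintf("snps must have columns %s", paste(need, collapse = ", ")))
  if (nrow(snps) == 0L) return(TRUE)
  if (anyNA(snps$chrom) || any(snps$chrom < 1L | snps$chrom > 22L))
    return("snps$chrom must be autosomal (1-22)")
  if (anyNA(snps$bp) || any(snps$bp <= 0)) return("snps$bp must be positive")
  if (any(snps$a1 == snps$a2)) return("alleles a1 and a2 must differ")
  if (require_order) {
    o <- order(snps$chrom, snps$bp)
    if (!identical(o, seq_len(nrow(snps))))
      return("snps must be sorted by (chrom, bp)")
    key <- paste(snps$chrom, snps$bp, snps$id)
    if (anyDuplicated(key)) return("duplicate (chrom, bp, id) in snps")
  }
  TRUE
}

.validSampleTable <- function(samples) {
  need <- c("id", "phenotype", "birth_year")
  if (!all(need %in% names(samples)))
    return(sprintf("samples must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(samples$id)) return("duplicate sample ids")
  ph <- samples$phenotype
  if (!all(is.na(ph) | ph %in% c("case", "control")))
    return("phenotype must be 'case', 'control' or NA")
  by <- samples$birth_year
  if (!all(is.na(by) | (by >= 1850 & by <= 2010)))
    return("birth_year outside plausible range 1850-2010")
  TRUE
}

setValidity("GenotypePanel", function(object) {
  msg <- .validSampleTable(object@samples)
  if (!isTRUE(msg)) return(msg)
  msg <- .validSnpTable(object@snps)
  if (!isTRUE(msg)) return(msg)
  g <- object@genotypes
  if (nrow(g) != nrow(object@samples) || ncol(g) != nrow(object@snps))
    return("genotype matrix dimensions do not match samples x snps")
  v <- g[!is.na(g)]
  if (length(v) && (any(v < 0L) || any(v > 2L)))
    return("genotype codes must be 0, 1, 2 or NA")
  TRUE
})

#' DosageSet: imputed allele dosages with per-SNP quality
#'
#' Non-integer expected allele counts in [0, 2] from genotype imputation
#' (MACH-style), with per-SNP imputation quality (RSQR in [0, 1]) and
#' estimated allele-1 frequency carried on the SNP map.
#'
#' @slot samples as in [GenotypePanel-class].
#' @slot snps SNP map as in [GenotypePanel-class] plus numeric columns
#'   \code{quality} (imputation RSQR, [0,1]) and \code{freq} (allele-1
#'   frequency, (0,1)).
#' @slot dosages numeric matrix, samples x SNPs, values in [0, 2] or
#'   \code{NA}; dosage = expected copies of \code{a1}.
#' @slot metadata list.
#' @seealso [readDosages()], [logisticDosageScan()], [computeScores()]
#' @export
setClass("DosageSet",
  slots = c(
    samples  = "data.frame",
    snps     = "data.frame",
    dosages  = "matrix",
    metadata = "list"
  )
)

setValidity("DosageSet", function(object) {
  msg <- .validSampleTable(object@samples)
  if (!isTRUE(msg)) return(msg)
  msg <- .validSnpTable(object@snps, require_order = FALSE)
  if (!isTRUE(msg)) return(msg)
  if (!all(c("quality", "freq") %in% names(object@snps)))
    return("snps must carry 'quality' and 'freq' columns")
  q <- object@snps$quality
  if (anyNA(q) || any(q < 0 | q > 1)) return("quality must lie in [0, 1]")
  d <- object@dosages
  if (nrow(d) != nrow(object@samples) || ncol(d) != nrow(object@snps))
    return("dosage matrix dimensions do not match samples x snps")
  v <- d[!is.na(d)]
  if (length(v) && (any(v < -1e-6) || any(v > 2 + 1e-6)))
    return("dosages must lie in [0, 2]")
  TRUE
})

#' Construct a GenotypePanel
#'
#' @param samples data.frame with \code{id}, \code{phenotype},
#'   \code{birth_year} (missing columns are added as \code{NA}).
#' @param snps data.frame with \code{id}, \code{chrom}, \code{bp}, \code{a1},
#'   \code{a2}; rows are reordered by (chrom, bp) and the genotype columns
#'   with them.
#' @param genotypes samples x SNPs matrix of codes \{0,1,2,NA\}.
#' @param metadata optional list.
#' @return A validated \linkS4class{GenotypePanel}.
#' @examples
#' p <- GenotypePanel(
#'   samples = data.frame(id = c("s1", "s2"), phenotype = c("case", "control")),
#'   snps = data.frame(id = c("rs1", "rs2"), chrom = 1L, bp = c(100L, 200L),
#'                     a1 = "A", a2 = "G"),
#'   genotypes = rbind(c(0L, 1L), c(2L, NA)))
#' nSamples(p)
#' @export
GenotypePanel <- function(samples, snps, genotypes, metadata = list()) {
  samples <- .completeSampleTable(samples)
  snps <- .normaliseSnpTable(snps)
  genotypes <- .asGenoMatrix(genotypes)
  o <- order(snps$chrom, snps$bp)
  snps <- snps[o, , drop = FALSE]
  rownames(snps) <- NULL
  genotypes <- genotypes[, o, drop = FALSE]
  dimnames(genotypes) <- list(samples$id, snps$id)
  new("GenotypePanel", samples = samples, snps = snps,
      genotypes = genotypes, metadata = metadata)
}

#' Construct a DosageSet
#'
#' @inheritParams GenotypePanel
#' @param dosages samples x SNPs numeric matrix in [0, 2].
#' @param quality,freq per-SNP numeric vectors (alternatively supplied as
#'   columns of \code{snps}).
#' @return A validated \linkS4class{DosageSet}.
#' @export
DosageSet <- function(samples, snps, dosages, quality = NULL, freq = NULL,
                      metadata = list()) {
  samples <- .completeSampleTable(samples)
  snps <- .normaliseSnpTable(snps)
  if (!is.null(quality)) snps$quality <- as.numeric(quality)
  if (!is.null(freq)) snps$freq <- as.numeric(freq)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  dosages[!is.na(dosages) & dosages < 0 & dosages > -1e-6] <- 0
  dosages[!is.na(dosages) & dosages > 2 & dosages < 2 + 1e-6] <- 2
  dimnames(dosages) <- list(samples$id, snps$id)
  new("DosageSet", samples = samples, snps = snps, dosages = dosages,
      metadata = metadata)
}

.completeSampleTable <- function(samples) {
  samples <- as.data.frame(samples)
  if (is.null(samples$phenotype)) samples$phenotype <- NA_character_
  if (is.null(samples$birth_year)) samples$birth_year <- NA_integer_
  samples$id <- as.character(samples$id)
  samples$phenotype <- as.character(samples$phenotype)
  samples$birth_year <- as.integer(samples$birth_year)
  rownames(samples) <- NULL
  samples
}

.normaliseSnpTable <- function(snps) {
  snps <- as.data.frame(snps)
  snps$id <- as.character(snps$id)
  snps$chrom <- as.integer(snps$chrom)
  snps$bp <- as.integer(snps$bp)
  snps$a1 <- as.character(snps$a1)
  snps$a2 <- as.character(snps$a2)
  rownames(snps) <- NULL
  snps
}

.asGenoMatrix <- function(g) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  g
}
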