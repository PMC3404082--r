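# Internal helpers shared across modules.

# Run code with a private RNG stream: seeds deterministically, then restores
# whatever global .Random.seed was in place.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Upper-triangle (i < j) pair index vectors for n samples.
.pairIndices <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  list(i = i, j = j)
}

# Pairwise IBS components for a genotype block G (n x m, codes 0/1/2/NA).
# Returns n x n count matrices: ibs0 (opposite homozygotes), ibs1 (one-allele
# difference), joint (jointly non-missing SNPs).  IBS2 = joint - ibs0 - ibs1.
.ibsCounts <- function(G) {
  A0 <- (!is.na(G)) & G == 0L; storage.mode(A0) <- "double"
  A1 <- (!is.na(G)) & G == 1L; storage.mode(A1) <- "double"
  A2 <- (!is.na(G)) & G == 2L; storage.mode(A2) <- "double"
  Nm <- A0 + A1 + A2
  X01 <- tcrossprod(A0, A1)
  X12 <- tcrossprod(A1, A2)
  list(
    ibs0  = tcrossprod(A0, A2) + tcrossprod(A2, A0),
    ibs1  = X01 + t(X01) + X12 + t(X12),
    joint = tcrossprod(Nm)
  )
}

# Allele-1 frequency per SNP from non-missing genotype codes.
.alleleFreq <- function(G) {
  n_ok <- colSums(!is.na(G))
  colSums(G, na.rm = TRUE) / (2 * pmax(n_ok, 1L))
}

.caseMask <- function(samples) {
  ph <- samples$phenotype
  if (anyNA(ph)) stop("all samples need a case/control phenotype", call. = FALSE)
  ph == "case"
}

#' Model autosome lengths
#'
#' Lengths of the 22 autosomes used throughout the package (window tiling,
#' genome-fraction denominators, the synthetic cohort generator).  Scaled
#' from build-36 autosome lengths, rounded to 250 kb multiples and adjusted
#' to total exactly 2,645 Mb, so a 500 kb / 250 kb sliding-window tiling of
#' the full autosomal genome yields exactly 10,580 windows.
#'
#' @return Named integer vector of length 22 (names "1".."22", units bp).
#' @examples sum(defaultChromLengths())
#' @export
defaultChromLengths <- function() {
  stats::setNames(as.integer(c(
    227750000, 224000000, 184000000, 176500000, 166750000, 157750000,
    146500000, 135000000, 129500000, 125000000, 124000000, 122000000,
    105250000,  98250000,  92500000,  82000000,  72750000,  70250000,
     58750000,  57500000,  43250000,  45750000)), as.character(1:22))
}

#' Autosomal genome length
#' @return Total model autosome length in bp (2,645,000,000).
#' @export
autosomeGenomeLength <- function() sum(as.numeric(defaultChromLengths()))
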