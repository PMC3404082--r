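#' Merge two genotyping platforms into a consensus panel
#'
#' Intersects two panels on physical position (chrom, bp), stacks their
#' samples, and harmonises allele orientation to panel \code{a}: where
#' \code{b} lists the same two alleles in swapped order its codes are flipped
#' \code{g -> 2 - g}.  SNPs whose allele pairs cannot be reconciled, and
#' strand-ambiguous pairs (A/T, C/G), are dropped and counted.
#'
#' SNP identity is (chrom, bp); ids are kept from panel \code{a} for
#' reporting only.
#'
#' @param a,b \linkS4class{GenotypePanel}s with disjoint sample ids.
#' @return A \linkS4class{GenotypePanel}; \code{metadata$merge} reports
#'   counts of position-intersected, allele-irreconcilable and
#'   strand-ambiguous SNPs.
#' @export
mergePanels <- function(a, b) {
  stopifnot(is(a, "GenotypePanel"), is(b, "GenotypePanel"))
  if (length(intersect(a@samples$id, b@samples$id)))
    stop("duplicate sample id across panels", call. = FALSE)
  key_a <- paste(a@snps$chrom, a@snps$bp)
  key_b <- paste(b@snps$chrom, b@snps$bp)
  ia <- which(key_a %in% key_b)
  ib <- match(key_a[ia], key_b)
  sa <- a@snps[ia, , drop = FALSE]
  sb <- b@snps[ib, , drop = FALSE]

  same <- sa$a1 == sb$a1 & sa$a2 == sb$a2
  swapped <- sa$a1 == sb$a2 & sa$a2 == sb$a1
  ambiguous <- (same | swapped) &
    (paste0(sa$a1, sa$a2) %in% c("AT", "TA", "CG", "GC"))
  irreconcilable <- !(same | swapped)
  keep <- !ambiguous & !irreconcilable

  gb <- b@genotypes[, ib, drop = FALSE]
  flip <- which(swapped & keep)
  gb[, flip] <- 2L - gb[, flip]

  merged <- GenotypePanel(
    samples = rbind(a@samples, b@samples),
    snps = sa[keep, , drop = FALSE],
    genotypes = rbind(a@genotypes[, ia[keep], drop = FALSE],
                      gb[, keep, drop = FALSE]),
    metadata = list(merge = list(
      n_position_shared = length(ia),
      n_irreconcilable = sum(irreconcilable),
      n_strand_ambiguous = sum(ambiguous),
      dropped_ids = sa$id[!keep])))
  merged
}
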