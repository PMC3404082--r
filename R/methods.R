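#' Accessors for GenotypePanel and DosageSet
#'
#' \code{nSamples} / \code{nSNPs} return dimensions; \code{sampleInfo} and
#' \code{snpInfo} the annotation tables; \code{genotypes} / \code{dosages}
#' the data matrix; \code{phenotype} the per-sample case/control labels.
#' Panels subset with \code{x[i, j]} (samples i, SNPs j).
#'
#' @param x a \linkS4class{GenotypePanel} or \linkS4class{DosageSet}.
#' @param value replacement phenotype vector ("case"/"control"/NA).
#' @name GenotypePanel-accessors
NULL

#' @rdname GenotypePanel-accessors
setMethod("nSamples", "GenotypePanel", function(x) nrow(x@samples))
#' @rdname GenotypePanel-accessors
setMethod("nSamples", "DosageSet", function(x) nrow(x@samples))
#' @rdname GenotypePanel-accessors
setMethod("nSNPs", "GenotypePanel", function(x) nrow(x@snps))
#' @rdname GenotypePanel-accessors
setMethod("nSNPs", "DosageSet", function(x) nrow(x@snps))
#' @rdname GenotypePanel-accessors
setMethod("sampleInfo", "GenotypePanel", function(x) x@samples)
#' @rdname GenotypePanel-accessors
setMethod("sampleInfo", "DosageSet", function(x) x@samples)
#' @rdname GenotypePanel-accessors
setMethod("snpInfo", "GenotypePanel", function(x) x@snps)
#' @rdname GenotypePanel-accessors
setMethod("snpInfo", "DosageSet", function(x) x@snps)
#' @rdname GenotypePanel-accessors
setMethod("genotypes", "GenotypePanel", function(x) x@genotypes)
#' @rdname GenotypePanel-accessors
setMethod("dosages", "DosageSet", function(x) x@dosages)
#' @rdname GenotypePanel-accessors
setMethod("phenotype", "GenotypePanel", function(x) {
  stats::setNames(x@samples$phenotype, x@samples$id)
})
#' @rdname GenotypePanel-accessors
setMethod("phenotype", "DosageSet", function(x) {
  stats::setNames(x@samples$phenotype, x@samples$id)
})
#' @rdname GenotypePanel-accessors
setReplaceMethod("phenotype", "GenotypePanel", function(x, value) {
  x@samples$phenotype <- as.character(value)
  validObject(x)
  x
})
#' @rdname GenotypePanel-accessors
setReplaceMethod("phenotype", "DosageSet", function(x, value) {
  x@samples$phenotype <- as.character(value)
  validObject(x)
  x
})

#' @param i,j sample / SNP indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; subsetting always returns the same class.
#' @rdname GenotypePanel-accessors
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nSNPs(x))
  if (is.character(i)) i <- match(i, x@samples$id)
  if (is.character(j)) j <- match(j, x@snps$id)
  s <- x@samples[i, , drop = FALSE]; rownames(s) <- NULL
  m <- x@snps[j, , drop = FALSE]; rownames(m) <- NULL
  new("GenotypePanel", samples = s, snps = m,
      genotypes = x@genotypes[i, j, drop = FALSE], metadata = x@metadata)
})

#' @rdname GenotypePanel-accessors
#' @export
setMethod("[", "DosageSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nSNPs(x))
  if (is.character(i)) i <- match(i, x@samples$id)
  if (is.character(j)) j <- match(j, x@snps$id)
  s <- x@samples[i, , drop = FALSE]; rownames(s) <- NULL
  m <- x@snps[j, , drop = FALSE]; rownames(m) <- NULL
  new("DosageSet", samples = s, snps = m,
      dosages = x@dosages[i, j, drop = FALSE], metadata = x@metadata)
})

setMethod("show", "GenotypePanel", function(object) {
  ph <- table(factor(object@samples$phenotype, c("case", "control")))
  cat(sprintf("GenotypePanel: %d samples (%d cases / %d controls) x %d SNPs\n",
              nSamples(object), ph[["case"]], ph[["control"]], nSNPs(object)))
  if (nSNPs(object) > 0) {
    ch <- range(object@snps$chrom)
    cat(sprintf("  chromosomes %d-%d; missing rate %.4f\n", ch[1], ch[2],
                mean(is.na(object@genotypes))))
  }
  invisible(NULL)
})

setMethod("show", "DosageSet", function(object) {
  cat(sprintf("DosageSet: %d samples x %d SNPs; median RSQR %.3f\n",
              nSamples(object), nSNPs(object),
              stats::median(object@snps$quality)))
  invisible(NULL)
})
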