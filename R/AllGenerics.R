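#' @rdname GenotypePanel-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("nSNPs", function(x) standardGeneric("nSNPs"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname GenotypePanel-accessors
#' @export
setGeneric("phenotype<-", function(x, value) standardGeneric("phenotype<-"))
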