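#' Read MACH-style dosage files
#'
#' Reads a whitespace-separated dosage table (one row per sample: sample id,
#' an optional \code{DOSE}/\code{ML_DOSE} tag, then one dosage in [0, 2] per
#' SNP) together with its info sidecar (columns \code{SNP}, \code{Al1},
#' \code{Al2}, \code{Freq1}, \code{Rsq}, header optional).  Dosages within
#' 1e-6 of the [0, 2] bounds are clipped; values further outside are an
#' error.  Imputation quality is attached per SNP but not filtered here
#' (see [dosageQC()]).
#'
#' @param dosage_path path to the dosage table.
#' @param info_path path to the info sidecar.
#' @param snp_map optional data.frame with \code{id}, \code{chrom}, \code{bp}
#'   to place SNPs on the genome; otherwise SNPs are laid out in file order
#'   on chromosome 1.
#' @return A \linkS4class{DosageSet}.
#' @export
readDosages <- function(dosage_path, info_path, snp_map = NULL) {
  info <- .readMapLike(info_path, 5L)
  if (identical(tolower(info[1, 1]), "snp")) info <- info[-1, , drop = FALSE]
  snp_id <- info[, 1]
  lines <- readLines(dosage_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  parse_row <- function(f, line) {
    if (length(f) >= 2L && toupper(f[2]) %in% c("DOSE", "ML_DOSE", "MLDOSE"))
      f <- f[-2]
    if (length(f) != 1L + length(snp_id))
      stop(sprintf("dosage line %d: %d dosage fields, info lists %d SNPs",
                   line, length(f) - 1L, length(snp_id)), call. = FALSE)
    f
  }
  fields <- lapply(seq_along(fields), function(k) parse_row(fields[[k]], k))
  ids <- sub("->.*$", "", vapply(fields, `[`, "", 1L))
  d <- matrix(suppressWarnings(as.numeric(
    unlist(lapply(fields, `[`, -1L), use.names = FALSE))),
    nrow = length(fields), byrow = TRUE)
  if (any(!is.na(d) & (d < -1e-6 | d > 2 + 1e-6)))
    stop("dosage outside [0, 2]", call. = FALSE)
  d[!is.na(d)] <- pmin(pmax(d[!is.na(d)], 0), 2)
  if (is.null(snp_map)) {
    snps <- data.frame(id = snp_id, chrom = 1L,
                       bp = seq_along(snp_id), stringsAsFactors = FALSE)
  } else {
    idx <- match(snp_id, snp_map$id)
    if (anyNA(idx)) stop("info SNP absent from snp_map: ",
                         snp_id[which(is.na(idx))[1]], call. = FALSE)
    snps <- snp_map[idx, c("id", "chrom", "bp"), drop = FALSE]
  }
  snps$a1 <- toupper(info[, 2]); snps$a2 <- toupper(info[, 3])
  DosageSet(samples = data.frame(id = ids, stringsAsFactors = FALSE),
            snps = snps, dosages = d,
            quality = as.numeric(info[, 5]), freq = as.numeric(info[, 4]))
}

#' Write MACH-style dosage files
#'
#' @param dset a \linkS4class{DosageSet}.
#' @param dosage_path,info_path output paths.
#' @return Invisibly, the written paths.
#' @export
writeDosages <- function(dset, dosage_path, info_path) {
  sn <- dset@snps
  writeLines(c("SNP Al1 Al2 Freq1 Rsq",
               sprintf("%s %s %s %.4f %.4f", sn$id, sn$a1, sn$a2, sn$freq,
                       sn$quality)), info_path)
  rows <- vapply(seq_len(nSamples(dset)), function(k) {
    paste(c(paste0(dset@samples$id[k], "->", dset@samples$id[k]), "DOSE",
            sprintf("%.3f", dset@dosages[k, ])), collapse = " ")
  }, "")
  writeLines(rows, dosage_path)
  invisible(c(dosage_path, info_path))
}
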