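#' Read a genotype panel from PLINK-dialect files
#'
#' Reads \code{<prefix>.ped}/\code{.map} (text) or
#' \code{<prefix>.bed}/\code{.bim}/\code{.fam} (SNP-major binary bed, magic
#' bytes \code{0x6c 0x1b 0x01}).  Non-autosomal SNPs are dropped with a
#' message; half-missing or unknown allele calls become missing.  SNPs are
#' returned sorted by (chrom, bp).
#'
#' @param prefix file path prefix (without extension).
#' @param dialect \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @return A \linkS4class{GenotypePanel}.  \code{metadata$n_nonautosomal}
#'   records the dropped-SNP count.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(prefix, dialect = c("ped_map", "bed_bim_fam")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped_map") .readPedMap(prefix) else .readBed(prefix)
}

#' Write a genotype panel to PLINK-dialect files
#'
#' Inverse of [readGenotypes()]: emits \code{.ped}/\code{.map} or
#' \code{.bed}/\code{.bim}/\code{.fam} such that reading back reproduces the
#' panel exactly.  Missing genotypes are written as \code{0 0} (ped) or the
#' \code{01} two-bit code (bed).  Phenotype is coded 1 = control, 2 = case,
#' 0 = missing.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @inheritParams readGenotypes
#' @return Invisibly, the written file paths.
#' @export
writeGenotypes <- function(panel, prefix, dialect = c("ped_map", "bed_bim_fam")) {
  dialect <- match.arg(dialect)
  stopifnot(is(panel, "GenotypePanel"))
  if (dialect == "ped_map") .writePedMap(panel, prefix) else .writeBed(panel, prefix)
}

.phenoCode <- function(ph) ifelse(is.na(ph), 0L, ifelse(ph == "case", 2L, 1L))
.phenoFromCode <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == 2] <- "case"
  out[code == 1] <- "control"
  out
}

.readMapLike <- function(path, n_fields) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != n_fields)
  if (length(bad))
    stop(sprintf("%s: line %d has %d fields, expected %d",
                 path, bad[1], lengths(fields)[bad[1]], n_fields), call. = FALSE)
  do.call(rbind, fields)
}

.dropNonAutosomal <- function(snps) {
  chrom_num <- suppressWarnings(as.integer(snps$chrom_raw))
  auto <- !is.na(chrom_num) & chrom_num >= 1L & chrom_num <= 22L
  n_dropped <- sum(!auto)
  if (n_dropped > 0)
    message(sprintf("dropping %d non-autosomal SNP(s)", n_dropped))
  list(keep = auto, n_dropped = n_dropped)
}

.readPedMap <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  m <- .readMapLike(map_path, 4L)
  snps0 <- data.frame(chrom_raw = m[, 1], id = m[, 2], bp = as.integer(m[, 4]),
                      stringsAsFactors = FALSE)
  auto <- .dropNonAutosomal(snps0)
  n_snp_all <- nrow(snps0)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  geno <- matrix(NA_integer_, n, n_snp_all)
  ids <- character(n); pheno <- integer(n)
  a_ref <- matrix(NA_character_, 2, n_snp_all)  # running a1/a2 discovery
  al1 <- matrix(NA_character_, n, n_snp_all)
  al2 <- matrix(NA_character_, n, n_snp_all)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_snp_all)
      stop(sprintf("%s: line %d has %d fields, expected %d (map has %d SNPs)",
                   ped_path, k, length(f), 6L + 2L * n_snp_all, n_snp_all),
           call. = FALSE)
    ids[k] <- f[2]
    pheno[k] <- suppressWarnings(as.integer(f[6]))
    al1[k, ] <- f[seq(7L, by = 2L, length.out = n_snp_all)]
    al2[k, ] <- f[seq(8L, by = 2L, length.out = n_snp_all)]
  }
  valid <- c("A", "C", "G", "T")
  al1[!al1 %in% valid] <- NA
  al2[!al2 %in% valid] <- NA
  half <- xor(is.na(al1), is.na(al2))
  al1[half] <- NA; al2[half] <- NA
  a1 <- character(n_snp_all); a2 <- character(n_snp_all)
  for (s in seq_len(n_snp_all)) {
    obs <- unique(c(al1[, s], al2[, s]))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2)
      stop(sprintf("%s: SNP %s has >2 alleles", ped_path, snps0$id[s]),
           call. = FALSE)
    # monomorphic/unseen SNPs get a placeholder second allele
    a1[s] <- if (length(obs) >= 1) obs[1] else "A"
    a2[s] <- if (length(obs) >= 2) obs[2] else setdiff(valid, a1[s])[1]
    g <- (al1[, s] == a1[s]) + (al2[, s] == a1[s])
    geno[, s] <- as.integer(g)
  }
  snps <- data.frame(id = snps0$id,
                     chrom = suppressWarnings(as.integer(snps0$chrom_raw)),
                     bp = snps0$bp, a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  snps <- snps[auto$keep, , drop = FALSE]
  geno <- geno[, auto$keep, drop = FALSE]
  GenotypePanel(
    samples = data.frame(id = ids, phenotype = .phenoFromCode(pheno),
                         birth_year = NA_integer_, stringsAsFactors = FALSE),
    snps = snps, genotypes = geno,
    metadata = list(n_nonautosomal = auto$n_dropped))
}

.writePedMap <- function(panel, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  sn <- panel@snps
  writeLines(sprintf("%d %s 0 %d", sn$chrom, sn$id, sn$bp), map_path)
  g <- panel@genotypes
  n <- nrow(g); m <- ncol(g)
  ph <- .phenoCode(panel@samples$phenotype)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (k in seq_len(n)) {
    al1 <- ifelse(is.na(g[k, ]), "0", ifelse(g[k, ] >= 1L, sn$a1, sn$a2))
    al2 <- ifelse(is.na(g[k, ]), "0", ifelse(g[k, ] == 2L, sn$a1, sn$a2))
    pairs <- character(2L * m)
    if (m) { pairs[seq(1L, by = 2L, length.out = m)] <- al1
             pairs[seq(2L, by = 2L, length.out = m)] <- al2 }
    writeLines(paste(c(panel@samples$id[k], panel@samples$id[k], "0", "0",
                       "0", ph[k], pairs), collapse = " "), con)
  }
  invisible(c(ped_path, map_path))
}

# bed two-bit codes (SNP-major): 00 = hom a1 (code 2), 10 = het (1),
# 11 = hom a2 (0), 01 = missing.
.bedDecodeTable <- function() {
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) for (k in 0:3) {
    two <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
    tab[b + 1L, k + 1L] <- switch(as.character(two),
                                  "0" = 2L, "1" = NA_integer_, "2" = 1L, "3" = 0L)
  }
  tab
}

.readBed <- function(prefix) {
  bim <- .readMapLike(paste0(prefix, ".bim"), 6L)
  fam <- .readMapLike(paste0(prefix, ".fam"), 6L)
  snps0 <- data.frame(chrom_raw = bim[, 1], id = bim[, 2],
                      bp = as.integer(bim[, 4]), a1 = bim[, 5], a2 = bim[, 6],
                      stringsAsFactors = FALSE)
  auto <- .dropNonAutosomal(snps0)
  n <- nrow(fam); m <- nrow(snps0)
  bpp <- ceiling(n / 4)  # bytes per SNP
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3L + bpp * m)
  if (length(raw) < 3L + bpp * m || !identical(as.integer(raw[1:3]), c(108L, 27L, 1L)))
    stop("not a SNP-major bed file (bad magic or truncated)", call. = FALSE)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpp, ncol = m)
  tab <- .bedDecodeTable()
  geno <- matrix(NA_integer_, n, m)
  for (k in 0:3) {
    rows <- seq(k + 1L, n, by = 4L)
    if (!length(rows)) next
    byte_rows <- ceiling(rows / 4)
    geno[rows, ] <- tab[cbind(as.vector(body[byte_rows, , drop = FALSE] + 1L),
                              k + 1L)]
  }
  snps <- data.frame(id = snps0$id,
                     chrom = suppressWarnings(as.integer(snps0$chrom_raw)),
                     bp = snps0$bp, a1 = snps0$a1, a2 = snps0$a2,
                     stringsAsFactors = FALSE)
  GenotypePanel(
    samples = data.frame(id = fam[, 2],
                         phenotype = .phenoFromCode(as.integer(fam[, 6])),
                         birth_year = NA_integer_, stringsAsFactors = FALSE),
    snps = snps[auto$keep, , drop = FALSE],
    genotypes = geno[, auto$keep, drop = FALSE],
    metadata = list(n_nonautosomal = auto$n_dropped))
}

.writeBed <- function(panel, prefix) {
  sn <- panel@snps
  writeLines(sprintf("%d\t%s\t0\t%d\t%s\t%s", sn$chrom, sn$id, sn$bp, sn$a1, sn$a2),
             paste0(prefix, ".bim"))
  ph <- .phenoCode(panel@samples$phenotype)
  writeLines(sprintf("%s %s 0 0 0 %d", panel@samples$id, panel@samples$id, ph),
             paste0(prefix, ".fam"))
  g <- panel@genotypes
  n <- nrow(g); m <- ncol(g)
  # code -> two-bit: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  two <- matrix(1L, n, m)
  two[!is.na(g) & g == 2L] <- 0L
  two[!is.na(g) & g == 1L] <- 2L
  two[!is.na(g) & g == 0L] <- 3L
  bpp <- ceiling(n / 4)
  pad <- bpp * 4L - n
  if (pad > 0) two <- rbind(two, matrix(0L, pad, m))
  shifts <- rep(c(0L, 2L, 4L, 6L), bpp)
  shifted <- two * as.integer(2^shifts)
  grp <- rep(seq_len(bpp), each = 4L)
  bytes <- rowsum(shifted, grp, reorder = TRUE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(108L, 27L, 1L)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
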