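#' Variance-inflation-factor LD pruning
#'
#' Slides a window of \code{window_snps} currently-kept SNPs along each
#' chromosome, advancing \code{step_snps} kept SNPs at a time.  Within a
#' window, while any SNP's variance inflation factor
#' \code{VIF = 1 / (1 - R^2)} (R^2 = squared multiple correlation of that
#' SNP's genotypes on the other kept SNPs in the window) exceeds
#' \code{vif_max}, the SNP with the highest VIF is dropped; ties are broken
#' by lower minor allele frequency, then by earlier position.  Defaults
#' (50-SNP windows, step 5, VIF > 1.05) are the standard settings for
#' producing an approximately independent marker set for IBS/IBD/ROH work.
#'
#' Missing genotypes are mean-imputed within each window for the
#' correlation computation (keeps the Gram matrix positive semidefinite);
#' a ridge of 1e-8 is added to the correlation diagonal before inversion.
#' Output is deterministic and invariant under sample permutation.
#'
#' @param panel a QC'd \linkS4class{GenotypePanel}.
#' @param window_snps,step_snps,vif_max pruning parameters.
#' @return \code{list(keep, remove)} of SNP id vectors (the
#'   \code{prune.in} / \code{prune.out} convention), plus \code{panel}: the
#'   input restricted to kept SNPs and marked \code{metadata$ld_pruned}.
#' @export
vifPrune <- function(panel, window_snps = 50L, step_snps = 5L, vif_max = 1.05) {
  stopifnot(step_snps >= 1L, step_snps <= window_snps, vif_max > 1)
  sn <- panel@snps
  G <- panel@genotypes
  p1 <- .alleleFreq(G)
  maf <- pmin(p1, 1 - p1)
  keep <- rep(TRUE, ncol(G))
  for (ch in unique(sn$chrom)) {
    cols <- which(sn$chrom == ch)
    # sweep windows over the kept list; repeat until a full sweep drops
    # nothing, so every final window satisfies the VIF bound
    repeat {
      kept_local <- cols[keep[cols]]
      n_kept <- length(kept_local)
      if (n_kept < 2L) break
      changed <- FALSE
      start <- 1L
      repeat {
        end <- min(start + window_snps - 1L, n_kept)
        win <- kept_local[start:end]
        win <- win[keep[win]]  # may have been dropped earlier this sweep
        if (length(win) >= 2L) {
          drop <- .vifEliminate(G[, win, drop = FALSE], maf[win], vif_max)
          if (length(drop)) { keep[win[drop]] <- FALSE; changed <- TRUE }
        }
        if (end >= n_kept) break
        start <- start + step_snps
      }
      if (!changed) break
    }
  }
  out <- panel[, keep]
  out@metadata$ld_pruned <- TRUE
  list(keep = sn$id[keep], remove = sn$id[!keep], panel = out)
}

# Greedy elimination inside one window.  Returns local indices to drop.
.vifEliminate <- function(Gw, maf, vif_max) {
  X <- apply(Gw, 2, function(g) {
    mu <- mean(g, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    g[is.na(g)] <- mu
    g
  })
  active <- seq_len(ncol(X))
  sds <- apply(X, 2, stats::sd)
  # zero-variance SNPs carry no LD information; they cannot inflate others
  const <- sds == 0
  dropped <- integer(0)
  repeat {
    live <- setdiff(active, which(const))
    if (length(live) < 2L) break
    R <- stats::cor(X[, live, drop = FALSE])
    Ri <- solve(R + diag(1e-8, length(live)))
    vif <- diag(Ri)
    if (max(vif) <= vif_max) break
    worst <- which(vif >= max(vif) - 1e-12)
    if (length(worst) > 1L) {
      worst <- worst[maf[live][worst] == min(maf[live][worst])]
      worst <- worst[1L]  # earliest position among remaining ties
    }
    drop_col <- live[worst]
    dropped <- c(dropped, drop_col)
    active <- setdiff(active, drop_col)
  }
  dropped
}
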