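#' Pairwise identity-by-descent estimation (method of moments)
#'
#' For every unordered sample pair, counts IBS0/1/2 over jointly non-missing
#' SNPs and solves the method-of-moments system for the IBD-state
#' probabilities z0, z1, z2, truncated to [0, 1] and renormalised;
#' \code{pi_hat = 0.5 z1 + z2}.
#'
#' Expected IBS-state probabilities under each IBD state use cohort allele
#' frequencies with the standard small-sample (finite chromosome count)
#' correction: each product of allele probabilities p^a q^b is replaced by
#' its unbiased estimator from allele counts, e.g. with X = 2N non-missing
#' chromosomes and A = X p copies of allele 1,
#'   E[p^2 q^2] -> A(A-1) B(B-1) / (X(X-1)(X-2)(X-3)),
#' and correspondingly for the third- and fourth-order terms in
#'   P(IBS0|IBD0) = 2 p^2 q^2,
#'   P(IBS1|IBD0) = 4 p^3 q + 4 p q^3,   P(IBS1|IBD1) = 2 p^2 q + 2 p q^2,
#'   P(IBS2|IBD0) = p^4 + q^4 + 4 p^2 q^2,
#'   P(IBS2|IBD1) = p^3 + q^3 + p^2 q + p q^2,   P(IBS2|IBD2) = 1.
#'
#' The panel should be LD-pruned first (a warning is issued otherwise, keyed
#' on \code{metadata$ld_pruned}).  Pairs with fewer than 100 jointly
#' non-missing SNPs are flagged unreliable.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @return data.frame with one row per pair: \code{id1}, \code{id2},
#'   \code{ibs0}, \code{ibs1}, \code{ibs2}, \code{z0}, \code{z1}, \code{z2},
#'   \code{pi_hat}, \code{n_joint}, \code{unreliable}.
#' @export
pairwiseIBD <- function(panel) {
  if (is.null(panel@metadata$ld_pruned) || !isTRUE(panel@metadata$ld_pruned))
    warning("panel not marked LD-pruned; pi-hat estimates assume independent SNPs")
  G <- panel@genotypes
  n <- nrow(G)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  p <- .alleleFreq(G)
  n_chr <- 2 * colSums(!is.na(G))
  poly <- p > 0 & p < 1 & n_chr >= 4
  G <- G[, poly, drop = FALSE]
  p <- p[poly]; X <- n_chr[poly]
  A <- p * X; B <- X - A
  f2 <- function(a) a * (a - 1)
  f3 <- function(a) a * (a - 1) * (a - 2)
  f4 <- function(a) a * (a - 1) * (a - 2) * (a - 3)
  D2 <- X * (X - 1); D3 <- D2 * (X - 2); D4 <- D3 * (X - 3)
  e00 <- 2 * f2(A) * f2(B) / D4
  e10 <- 4 * (f3(A) * B + A * f3(B)) / D4
  e20 <- (f4(A) + f4(B) + 4 * f2(A) * f2(B)) / D4
  e11 <- 2 * (f2(A) * B + A * f2(B)) / D3
  e21 <- (f3(A) + f3(B) + f2(A) * B + A * f2(B)) / D3
  # per-SNP expectations averaged over SNPs; observed counts per pair are
  # scaled to proportions over each pair's jointly non-missing SNPs
  E00 <- mean(e00); E10 <- mean(e10); E20 <- mean(e20)
  E11 <- mean(e11); E21 <- mean(e21)
  cnt <- .ibsCounts(G)
  pr <- .pairIndices(n)
  idx <- cbind(pr$i, pr$j)
  joint <- cnt$joint[idx]
  obs0 <- cnt$ibs0[idx] / pmax(joint, 1)
  obs1 <- cnt$ibs1[idx] / pmax(joint, 1)
  obs2 <- 1 - obs0 - obs1
  z0 <- obs0 / E00
  z1 <- (obs1 - z0 * E10) / E11
  z2 <- (obs2 - z0 * E20 - z1 * E21)
  z <- cbind(z0, z1, z2)
  z[z < 0] <- 0; z[z > 1] <- 1
  z <- z / rowSums(z)
  data.frame(id1 = panel@samples$id[pr$i], id2 = panel@samples$id[pr$j],
             ibs0 = cnt$ibs0[idx], ibs1 = cnt$ibs1[idx],
             ibs2 = joint - cnt$ibs0[idx] - cnt$ibs1[idx],
             z0 = z[, 1], z1 = z[, 2], z2 = z[, 3],
             pi_hat = 0.5 * z[, 2] + z[, 3],
             n_joint = joint, unreliable = joint < 100,
             stringsAsFactors = FALSE)
}

#' Prune related samples
#'
#' Greedy removal: while any pair exceeds \code{pi_hat_max}, remove the
#' member involved in more such pairs; ties are broken by lower call rate,
#' then by lexicographically smaller id.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param kinship output of [pairwiseIBD()].
#' @param pi_hat_max threshold (default 0.15).
#' @return \code{list(panel, report)}.
#' @export
relatednessPrune <- function(panel, kinship, pi_hat_max = 0.15) {
  cr <- rowMeans(!is.na(panel@genotypes))
  names(cr) <- panel@samples$id
  edges <- kinship[kinship$pi_hat > pi_hat_max, c("id1", "id2"), drop = FALSE]
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      cand <- cand[cr[cand] == min(cr[cand])]
      cand <- sort(cand)[1]
    }
    removed <- c(removed, cand)
    edges <- edges[edges$id1 != cand & edges$id2 != cand, , drop = FALSE]
  }
  report <- .qcReport(relatedness = list(threshold = pi_hat_max, ids = removed))
  list(panel = panel[!(panel@samples$id %in% removed), ], report = report)
}
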