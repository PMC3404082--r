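#' Classical multidimensional scaling of an IBS matrix
#'
#' Torgerson classical scaling of the genetic distance d = 1 - IBS:
#' double-centre the squared distances, eigendecompose, and return the top-k
#' eigenvector coordinates scaled by the root eigenvalues (delegated to
#' \code{stats::cmdscale}).  Components have zero mean across samples and
#' eigenvalues are non-increasing.  If fewer than k positive eigenvalues
#' exist, fewer components are returned with a warning.
#'
#' @param ibs_matrix symmetric pairwise IBS matrix in [0, 1] with unit
#'   diagonal (see [pairwiseIBS()]).
#' @param k number of components (default 2, the usual covariate pair).
#' @return Matrix of coordinates (samples x components) with attribute
#'   \code{eigenvalues}.
#' @export
classicalMDS <- function(ibs_matrix, k = 2L) {
  stopifnot(is.matrix(ibs_matrix), nrow(ibs_matrix) == ncol(ibs_matrix))
  if (max(abs(ibs_matrix - t(ibs_matrix))) > 1e-8)
    stop("IBS matrix must be symmetric", call. = FALSE)
  d <- 1 - ibs_matrix
  diag(d) <- 0
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  if (n_pos < k) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d component(s)",
                    n_pos, n_pos))
    pts <- pts[, seq_len(max(n_pos, 0)), drop = FALSE]
  }
  if (is.null(pts) || ncol(pts) == 0)
    pts <- matrix(0, nrow(ibs_matrix), 0)
  rownames(pts) <- rownames(ibs_matrix)
  colnames(pts) <- if (ncol(pts)) paste0("C", seq_len(ncol(pts))) else character(0)
  attr(pts, "eigenvalues") <- fit$eig[seq_len(ncol(pts))]
  pts
}

#' MDS covariates for a genotype panel
#'
#' Convenience wrapper: pairwise IBS on the (pruned) panel, then
#' [classicalMDS()].
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param k number of components.
#' @return Coordinates matrix as in [classicalMDS()].
#' @export
mdsCovariates <- function(panel, k = 2L) {
  classicalMDS(pairwiseIBS(panel), k = k)
}
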