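# Effective number of sequences of a paired complex alignment.  Each row is
# down-weighted by the count of rows whose two-chain similarity reaches the
# neighbour threshold, and the weighted sum is scaled by the complex length:
#
#   Necs = scale(L) * sum_i 1 / (1 + sum_{j != i} [S_ij >= delta])
#   S_ij = 2 / (1/S_ij^A + 1/S_ij^B)           (harmonic mean of the chains)
#
# with delta = 0.8 by default and scale(L) = 1/sqrt(L) (1/L by option).

#' Harmonic mean of the two chain identities
#'
#' Combines the chain-A and chain-B pairwise identities of two paired rows
#' into one two-chain similarity, `2 / (1/sA + 1/sB)`.  The harmonic mean is
#' dominated by the weaker chain, so a pair only counts as similar when both
#' chains agree.  If either identity is 0 the similarity is 0 (continuous
#' limit).
#'
#' @param sA,sB Chain identities in `[0, 1]` (vectorised).
#' @return Similarities in `[0, 1]`, symmetric in `sA`, `sB`, never above
#'   the arithmetic mean.
#' @export
#' @examples
#' harmonic_pair_identity(0.6, 1.0)  # 0.75
harmonic_pair_identity <- function(sA, sB) {
  if (any(sA < 0 | sA > 1 | sB < 0 | sB > 1, na.rm = TRUE))
    stop("chain identities must lie in [0, 1]")
  ifelse(sA == 0 | sB == 0, 0, 2 / (1 / sA + 1 / sB))
}

#' Neighbour indicator for the effective-sequence weighting
#'
#' @param s Two-chain similarity in `[0, 1]` (vectorised).
#' @param threshold Similarity at or above which two rows count as
#'   neighbours (default 0.8; the boundary value itself counts).
#' @return 0/1 integer vector.
#' @export
delta_indicator <- function(s, threshold = 0.8) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("similarity must lie in [0, 1]")
  as.integer(s >= threshold)
}

#' Effective number of sequences of a paired MSA
#'
#' For every ordered pair of rows the two per-chain identities (computed with
#' [pairwise_identity()] on the stage-output aligned rows) are combined by
#' [harmonic_pair_identity()]; each row's weight is one over one plus its
#' number of neighbours at the threshold, and the weighted sum is scaled by
#' `1/sqrt(L)` (default) or `1/L`.  All rows, including the query pair, are
#' counted unless `include_query = FALSE`.
#'
#' @param cpx A [cpx_msa()] object.
#' @param threshold Neighbour similarity threshold (default 0.8).
#' @param scaling `"inv_sqrt_L"` (default) or `"inv_L"`.
#' @param identity_mode Identity mode for the per-chain identities.
#' @param include_query Count the query pair as a row (default `TRUE`).
#' @return Object of class `necs_result`: list with `necs`, `N`, `L`,
#'   `threshold`, `scaling`, `weights`.
#' @export
compute_necs <- function(cpx, threshold = 0.8,
                         scaling = c("inv_sqrt_L", "inv_L"),
                         identity_mode = c("both_ungapped", "full_length"),
                         include_query = TRUE) {
  scaling <- match.arg(scaling)
  identity_mode <- match.arg(identity_mode)
  stopifnot(inherits(cpx, "cpx_msa"))
  rows <- cpx$rows
  if (!include_query) rows <- rows[rows$stage != "query", , drop = FALSE]
  n <- nrow(rows)
  if (n == 0L) stop("cannot compute effective sequences of an empty alignment")
  sA <- .chain_identity_matrix(rows$seq_A, identity_mode)
  sB <- .chain_identity_matrix(rows$seq_B, identity_mode)
  s <- matrix(harmonic_pair_identity(as.vector(sA), as.vector(sB)), n, n)
  nb <- matrix(delta_indicator(as.vector(s), threshold), n, n)
  diag(nb) <- 0L
  weights <- 1 / (1 + rowSums(nb))
  scale_fac <- if (scaling == "inv_sqrt_L") 1 / sqrt(cpx$L) else 1 / cpx$L
  structure(list(necs = scale_fac * sum(weights), N = n, L = cpx$L,
                 threshold = threshold, scaling = scaling, weights = weights),
            class = "necs_result")
}

#' @export
print.necs_result <- function(x, ...) {
  cat(sprintf("Effective sequences: Necs = %.4f  (N = %d, L = %d, threshold = %.2f, scaling = %s)\n",
              x$necs, x$N, x$L, x$threshold, x$scaling))
  invisible(x)
}
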