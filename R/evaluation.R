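# Top-k inter-chain contact precision and the relative-improvement
# arithmetic used to compare alignment construction strategies.

#' Resolve an L/k contact count
#'
#' @param L Total complex length (both chains).
#' @param divisor The divisor `k` in `L/k`.
#' @return `floor(L / divisor)`, floored at 1.
#' @export
resolve_k <- function(L, divisor) max(1L, as.integer(floor(L / divisor)))

#' Precision of the top-k predicted inter-chain contacts
#'
#' Cells of the `L_A x L_B` score matrix are ranked by decreasing score,
#' ties broken by ascending `(i, j)` position; the precision is the fraction
#' of true contacts among the `k` best-ranked cells.
#'
#' @param scores Numeric matrix of predicted inter-chain contact scores
#'   (rows = chain-A residues, columns = chain-B residues).
#' @param truth Logical (or 0/1) matrix of the same shape marking true
#'   contacts.
#' @param k Number of top-ranked cells to assess (at least 1, at most the
#'   number of cells).
#' @return Precision in `[0, 1]`.
#' @export
topk_precision <- function(scores, truth, k) {
  scores <- as.matrix(scores)
  truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth)))
    stop("scores and truth must have identical dimensions")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (k > length(scores))
    stop(sprintf("k = %d exceeds the number of score cells (%d)", k, length(scores)))
  idx <- arrayInd(seq_along(scores), dim(scores))
  ord <- order(-as.vector(scores), idx[, 1], idx[, 2])
  sum(as.logical(truth[ord[seq_len(k)]])) / k
}

#' Precision profile over the standard contact counts
#'
#' Evaluates [topk_precision()] at fixed counts and at `L/k` fractions of
#' the total complex length.
#'
#' @param scores,truth As in [topk_precision()].
#' @param ks Fixed contact counts (default 50, 20, 10, 5).
#' @param divisors `L/k` divisors (default 5, 10, 20, 50).
#' @param L Total complex length; defaults to `nrow(scores) + ncol(scores)`.
#' @return `data.frame` with columns `label`, `k`, `precision`.
#' @export
contact_precision_profile <- function(scores, truth, ks = c(50L, 20L, 10L, 5L),
                                      divisors = c(5L, 10L, 20L, 50L),
                                      L = nrow(scores) + ncol(scores)) {
  lab <- c(sprintf("L/%d", divisors), sprintf("top%d", ks))
  kk <- c(vapply(divisors, resolve_k, integer(1), L = L), as.integer(ks))
  data.frame(label = lab, k = kk,
             precision = vapply(kk, function(k) topk_precision(scores, truth, k),
                                numeric(1)),
             stringsAsFactors = FALSE)
}

#' Relative improvement of one precision over another
#'
#' @param a,b Precisions (or any positive quantities); `b` is the baseline.
#' @param digits Decimal places for the reported percentage (default 1, the
#'   usual reporting precision; `NULL` for no rounding).
#' @return `100 * (a - b) / b`, in percent.
#' @export
#' @examples
#' relative_improvement(0.673, 0.424)  # 58.7
relative_improvement <- function(a, b, digits = 1L) {
  if (any(b <= 0)) stop("the baseline must be positive")
  out <- 100 * (a - b) / b
  if (is.null(digits)) out else round(out, digits)
}

#' Published benchmark precisions shipped with the package
#'
#' Top-k inter-chain contact precisions reported for the four alignment
#' construction strategies on a 100-heterodimer benchmark (trRosettaX
#' predictor) and for the cascade versus a baseline paired MSA on a second
#' published set (CCMpred and trRosettaX predictors).  Used to reproduce the
#' headline relative-improvement figures with [relative_improvement()].
#'
#' @return `data.frame` with columns `dataset`, `predictor`, `msa` and one
#'   precision column per contact count (`L5` ... `top5`).
#' @export
benchmark_precisions <- function() {
  path <- system.file("extdata", "benchmark_precisions.tsv", package = "pairmsa",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a contact matrix from text
#'
#' Dense: whitespace-delimited numeric rows.  Sparse: three columns
#' `i j value` with 0-based indices, densified into a `nrow x ncol` matrix
#' (unlisted cells are 0).
#'
#' @param path Input file.
#' @param format `"dense"` or `"sparse"`.
#' @param dims Length-2 integer vector `c(L_A, L_B)`, required for `sparse`.
#' @return Numeric matrix.
#' @export
read_contact_matrix <- function(path, format = c("dense", "sparse"),
                                dims = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = FALSE)
  if (format == "dense") {
    m <- as.matrix(tab)
    dimnames(m) <- NULL
    return(m)
  }
  if (ncol(tab) != 3L) stop("sparse contact files need columns: i j value")
  if (is.null(dims) || length(dims) != 2L) stop("sparse input needs dims = c(L_A, L_B)")
  m <- matrix(0, dims[1], dims[2])
  i <- tab[[1]] + 1L; j <- tab[[2]] + 1L
  if (any(i < 1L | i > dims[1] | j < 1L | j > dims[2])) stop("sparse index out of range")
  m[cbind(i, j)] <- tab[[3]]
  m
}
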