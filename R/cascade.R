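# Stage selection: build the genomic-distance alignment first, escalate to
# the phylogeny and then the interaction-network pairs only while the
# alignment's effective-sequence count stays below the requirement, then
# remove redundant rows.

#' Merge stage outputs into one paired MSA, removing duplicates
#'
#' Rows are deduplicated both on the concatenated two-chain sequence and on
#' the accession pair, keeping the earliest stage's copy; within one stage
#' the original order is preserved.  The query pair always comes first and
#' is never dropped.  Idempotent.
#'
#' @param stage_outputs List of paired-row `data.frame`s in stage order
#'   (e.g. genomic, phylogeny, string).
#' @param query_pair One-row `data.frame` (or list) with `accession_A`,
#'   `accession_B`, `seq_A`, `seq_B` for the query sequences.
#' @return A [cpx_msa()] object; `attr(x, "duplicates_removed")` counts the
#'   rows dropped.
#' @export
merge_and_dedupe <- function(stage_outputs, query_pair) {
  qp <- as.data.frame(query_pair, stringsAsFactors = FALSE)
  qp$stage <- "query"
  qp$delta_gene <- NA_real_; qp$taxid <- NA_real_; qp$rank <- NA_real_
  qp$combined_score <- NA_real_
  cols <- c("accession_A", "accession_B", "seq_A", "seq_B", "stage",
            "delta_gene", "taxid", "rank", "combined_score")
  stage_outputs <- Filter(function(d) !is.null(d) && nrow(d) > 0, stage_outputs)
  all_rows <- do.call(rbind, c(list(qp[, cols]),
                               lapply(stage_outputs, function(d) d[, cols])))
  L_A <- nchar(qp$seq_A); L_B <- nchar(qp$seq_B)
  if (any(nchar(all_rows$seq_A) != L_A) || any(nchar(all_rows$seq_B) != L_B))
    stop("stage outputs have rows inconsistent with the query chain lengths")
  dup <- duplicated(paste0(all_rows$seq_A, all_rows$seq_B)) |
         duplicated(paste(all_rows$accession_A, all_rows$accession_B, sep = "\r"))
  out <- cpx_msa(all_rows[!dup, , drop = FALSE], L_A = L_A, L_B = L_B)
  attr(out, "duplicates_removed") <- sum(dup)
  out
}

#' Build a paired complex MSA by cascading the three pairing strategies
#'
#' Step 1 pairs by genomic distance and computes the effective-sequence
#' count of the resulting alignment (query pair included); if it reaches
#' `necs_threshold` the cascade stops there.  Otherwise the phylogeny pairs
#' are merged in and the count recomputed; if still short, the
#' interaction-network pairs are added and the three-stage merge is returned
#' regardless.  Every step is recorded in the report.
#'
#' @param msaA,msaB [monomer_msa()] objects (annotated automatically when a
#'   bundle is given).
#' @param bundle An [annotation_bundle()].
#' @param necs_threshold Required alignment depth (default 128 with
#'   `inv_sqrt_L` scaling).
#' @param mode `"necs"` judges depth by the effective-sequence count,
#'   `"nrows"` by the raw row count.
#' @param min_d,max_d Gene-distance bounds for the genomic stage.
#' @param min_score Minimum combined score for the interaction stage.
#' @param threshold,scaling,identity_mode Passed to [compute_necs()].
#' @param match_method Matching method for [pair_genomic()]/[pair_string()].
#' @param quiet Suppress annotation messages.
#' @return List with elements `cpx` (the selected [cpx_msa()]) and `report`
#'   (class `cascade_report`): `chosen_stages`, `necs_per_step`
#'   (data.frame of stages/rows/depth per step), `rows_per_stage`,
#'   `duplicates_removed`, `depth` flag (`"query-only"` when all stages are
#'   empty).
#' @export
select_cpxmsa <- function(msaA, msaB, bundle, necs_threshold = 128,
                          mode = c("necs", "nrows"),
                          min_d = 1L, max_d = 20L, min_score = 0L,
                          threshold = 0.8, scaling = "inv_sqrt_L",
                          identity_mode = "both_ungapped",
                          match_method = "exact", quiet = TRUE) {
  mode <- match.arg(mode)
  if (!isTRUE(msaA$annotated)) msaA <- annotate(msaA, bundle, quiet = quiet)
  if (!isTRUE(msaB$annotated)) msaB <- annotate(msaB, bundle, quiet = quiet)
  query_pair <- data.frame(accession_A = msaA$query$accession,
                           accession_B = msaB$query$accession,
                           seq_A = msaA$query$matched, seq_B = msaB$query$matched,
                           stringsAsFactors = FALSE)
  s1 <- pair_genomic(msaA, msaB, min_d = min_d, max_d = max_d, method = match_method)
  s2 <- NULL; s3 <- NULL
  depth_of <- function(cpx) {
    if (mode == "nrows") nrow(cpx$rows)
    else compute_necs(cpx, threshold = threshold, scaling = scaling,
                      identity_mode = identity_mode)$necs
  }
  steps <- data.frame(stages = character(), n_rows = integer(),
                      depth = numeric(), stringsAsFactors = FALSE)
  dups <- 0L
  build <- function(outs, label) {
    cpx <- merge_and_dedupe(outs, query_pair)
    dups <<- dups + attr(cpx, "duplicates_removed")
    steps <<- rbind(steps, data.frame(stages = label, n_rows = nrow(cpx$rows),
                                      depth = depth_of(cpx), stringsAsFactors = FALSE))
    cpx
  }
  cpx <- build(list(s1), "1")
  chosen <- "1"
  if (steps$depth[nrow(steps)] < necs_threshold) {
    s2 <- pair_phylogeny(msaA, msaB)
    cpx <- build(list(s1, s2), "1+2")
    chosen <- "1+2"
    if (steps$depth[nrow(steps)] < necs_threshold) {
      s3 <- pair_string(msaA, msaB, bundle, min_score = min_score, method = match_method)
      cpx <- build(list(s1, s2, s3), "1+2+3")
      chosen <- "1+2+3"
    }
  }
  rows_per_stage <- c(genomic = nrow(s1),
                      phylogeny = if (is.null(s2)) NA_integer_ else nrow(s2),
                      string = if (is.null(s3)) NA_integer_ else nrow(s3))
  report <- structure(
    list(chosen_stages = as.integer(strsplit(chosen, "+", fixed = TRUE)[[1]]),
         necs_per_step = steps, rows_per_stage = rows_per_stage,
         duplicates_removed = dups, mode = mode,
         necs_threshold = necs_threshold, scaling = scaling,
         similarity_threshold = threshold,
         depth = if (nrow(cpx$rows) == 1L) "query-only" else chosen),
    class = "cascade_report")
  list(cpx = cpx, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("Cascade report (mode = %s, required depth = %g, scaling = %s)\n",
              x$mode, x$necs_threshold, x$scaling))
  for (i in seq_len(nrow(x$necs_per_step)))
    cat(sprintf("  stages %-5s : %4d rows, depth %.4f\n",
                x$necs_per_step$stages[i], x$necs_per_step$n_rows[i],
                x$necs_per_step$depth[i]))
  cat(sprintf("  chosen: stages {%s}; %d duplicate row(s) removed\n",
              paste(x$chosen_stages, collapse = ","), x$duplicates_removed))
  if (identical(x$depth, "query-only"))
    cat("  note: all stages empty, alignment holds the query pair only\n")
  invisible(x)
}

#' Remove redundant rows from a paired MSA
#'
#' With the default `max_id = 1` only rows whose concatenated sequence is
#' byte-identical to an earlier kept row are dropped.  With `max_id < 1`,
#' a row is additionally dropped when the harmonic-mean two-chain identity
#' to any earlier kept row reaches `max_id`.  The query pair is never
#' dropped.  Idempotent.
#'
#' @param cpx A [cpx_msa()] object.
#' @param max_id Identity ceiling in `(0, 1]` (default 1: exact duplicates
#'   only).
#' @param identity_mode Identity mode for the per-chain identities.
#' @return A filtered [cpx_msa()];
#'   `attr(x, "redundant_removed")` counts dropped rows.
#' @export
remove_redundant <- function(cpx, max_id = 1.0,
                             identity_mode = c("both_ungapped", "full_length")) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(inherits(cpx, "cpx_msa"), max_id > 0, max_id <= 1)
  rows <- cpx$rows
  n <- nrow(rows)
  keep <- logical(n); keep[1] <- TRUE
  kept_cat <- paste0(rows$seq_A[1], rows$seq_B[1])
  if (max_id < 1) {
    sA <- .chain_identity_matrix(rows$seq_A, identity_mode)
    sB <- .chain_identity_matrix(rows$seq_B, identity_mode)
    s <- matrix(harmonic_pair_identity(as.vector(sA), as.vector(sB)), n, n)
  }
  for (i in seq_len(n)[-1]) {
    cat_i <- paste0(rows$seq_A[i], rows$seq_B[i])
    drop <- cat_i %in% kept_cat
    if (!drop && max_id < 1)
      drop <- any(s[i, which(keep)] >= max_id)
    if (!drop) { keep[i] <- TRUE; kept_cat <- c(kept_cat, cat_i) }
  }
  out <- cpx_msa(rows[keep, , drop = FALSE], L_A = cpx$L_A, L_B = cpx$L_B)
  attr(out, "redundant_removed") <- sum(!keep)
  out
}
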