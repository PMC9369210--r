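# The three strategies that join rows of two annotated monomer MSAs into
# candidate paired rows: genomic distance, per-species phylogeny rank
# matching, and interaction-network links.  Each returns a one-to-one set of
# paired rows with stage-specific detail, fully deterministic in its inputs.

.require_annotated <- function(msa, what) {
  if (is.null(msa$annotated) || !isTRUE(msa$annotated))
    stop(sprintf("%s requires annotated MSAs; call annotate() first", what))
  invisible(TRUE)
}

.empty_pairs <- function() {
  data.frame(accession_A = character(), accession_B = character(),
             seq_A = character(), seq_B = character(), stage = character(),
             delta_gene = numeric(), taxid = numeric(), rank = numeric(),
             combined_score = numeric(), stringsAsFactors = FALSE)
}

# One-to-one matching over a sorted candidate table.  Candidates must already
# be ordered by the stage's total tie-breaking rule; `weight` is Delta-gene
# (minimised) or combined score (maximised).  The default resolves each
# connected conflict component exactly (maximum pairs, then best total
# weight, then first-in-order); components larger than `max_exact` candidate
# edges fall back to order-greedy selection.
.match_one_to_one <- function(cand, objective = c("min_weight", "max_weight"),
                              method = c("exact", "greedy"), max_exact = 16L) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  n <- nrow(cand)
  if (n == 0L) return(integer())
  if (method == "greedy") return(.match_greedy(cand))
  comp <- .conflict_components(cand$accession_A, cand$accession_B)
  sel <- integer()
  for (cc in split(seq_len(n), comp)) {
    sel <- c(sel, if (length(cc) > max_exact) .match_greedy(cand[cc, , drop = FALSE], cc)
                  else .match_exact(cand[cc, , drop = FALSE], cc, objective))
  }
  sort(sel)
}

.match_greedy <- function(cand, idx = seq_len(nrow(cand))) {
  usedA <- character(); usedB <- character(); keep <- integer()
  for (k in seq_len(nrow(cand))) {
    if (cand$accession_A[k] %in% usedA || cand$accession_B[k] %in% usedB) next
    usedA <- c(usedA, cand$accession_A[k]); usedB <- c(usedB, cand$accession_B[k])
    keep <- c(keep, idx[k])
  }
  keep
}

# Exhaustive search on one conflict component (<= max_exact edges):
# enumerate subsets that form a matching; compare by the stage objective.
.match_exact <- function(cand, idx, objective) {
  n <- nrow(cand)
  best <- NULL
  better <- function(card, total, pick) {
    if (is.null(best)) return(TRUE)
    if (objective == "min_weight") {
      if (card != best$card) return(card > best$card)
      if (total != best$total) return(total < best$total)
    } else {
      if (total != best$total) return(total > best$total)
      if (card != best$card) return(card > best$card)
    }
    # identical score: prefer the selection that takes earlier-sorted edges
    a <- c(pick, Inf); b <- c(best$pick, Inf)
    m <- min(length(a), length(b))
    for (i in seq_len(m)) if (a[i] != b[i]) return(a[i] < b[i])
    FALSE
  }
  rec <- function(k, usedA, usedB, pick, total) {
    if (k > n) {
      card <- length(pick)
      if (better(card, total, pick)) best <<- list(card = card, total = total, pick = pick)
      return(invisible(NULL))
    }
    a <- cand$accession_A[k]; b <- cand$accession_B[k]
    if (!(a %in% usedA) && !(b %in% usedB))
      rec(k + 1L, c(usedA, a), c(usedB, b), c(pick, k), total + cand$weight[k])
    rec(k + 1L, usedA, usedB, pick, total)
  }
  rec(1L, character(), character(), integer(), 0)
  idx[best$pick]
}

# Connected components of the conflict graph whose nodes are accessions and
# whose edges are candidate pairs.
.conflict_components <- function(accA, accB) {
  nodes <- unique(c(paste0("A\r", accA), paste0("B\r", accB)))
  parent <- seq_along(nodes); names(parent) <- nodes
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(accA)) {
    ra <- find(match(paste0("A\r", accA[k]), nodes))
    rb <- find(match(paste0("B\r", accB[k]), nodes))
    if (ra != rb) parent[rb] <- ra
  }
  vapply(paste0("A\r", accA), function(nm) find(match(nm, nodes)), integer(1),
         USE.NAMES = FALSE)
}

#' Pair MSA rows by genomic distance
#'
#' Candidate pairs are hits on the same genome whose gene-order indices
#' differ by `min_d` to `max_d` (small differences suggest operon
#' co-membership and hence physical interaction).  A one-to-one matching is
#' returned; within each conflict the assignment minimises the total gene
#' distance (maximum number of pairs first), with ties broken by higher mean
#' identity to the query and then lexicographic accessions.  Rows lacking a
#' gene location are skipped.
#'
#' @param msaA,msaB Annotated [monomer_msa()] objects (see [annotate()]).
#' @param min_d,max_d Inclusive bounds on the gene-rank difference
#'   (defaults 1 and 20).
#' @param method `"exact"` (default; order-greedy fallback for conflict
#'   components over 16 candidate pairs) or `"greedy"` for pure
#'   first-come selection in the sorted candidate order.
#' @return `data.frame` of paired rows with `stage = "genomic"` and
#'   `delta_gene` detail.
#' @export
pair_genomic <- function(msaA, msaB, min_d = 1L, max_d = 20L,
                         method = c("exact", "greedy")) {
  method <- match.arg(method)
  .require_annotated(msaA, "pair_genomic"); .require_annotated(msaB, "pair_genomic")
  a <- msaA$hits[!is.na(msaA$hits$genome_id) & !is.na(msaA$hits$gene_index), , drop = FALSE]
  b <- msaB$hits[!is.na(msaB$hits$genome_id) & !is.na(msaB$hits$gene_index), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(.empty_pairs())
  cand <- merge(a, b, by = "genome_id", suffixes = c("_A", "_B"))
  if (!nrow(cand)) return(.empty_pairs())
  cand$delta <- abs(cand$gene_index_A - cand$gene_index_B)
  cand <- cand[cand$delta >= min_d & cand$delta <= max_d, , drop = FALSE]
  if (!nrow(cand)) return(.empty_pairs())
  cand$mean_id <- (cand$identity_A + cand$identity_B) / 2
  cand <- cand[order(cand$delta, -cand$mean_id, cand$accession_A, cand$accession_B), , drop = FALSE]
  cand$weight <- cand$delta
  keep <- .match_one_to_one(cand, "min_weight", method)
  sel <- cand[keep, , drop = FALSE]
  data.frame(accession_A = sel$accession_A, accession_B = sel$accession_B,
             seq_A = sel$matched_A, seq_B = sel$matched_B, stage = "genomic",
             delta_gene = sel$delta, taxid = NA_real_, rank = NA_real_,
             combined_score = NA_real_, stringsAsFactors = FALSE, row.names = NULL)
}

#' Pair MSA rows by per-species similarity rank
#'
#' Within each species (taxid) present in both MSAs, chain-A hits are sorted
#' by identity to the query from high to low (ties by ascending e-value when
#' available, then accession), chain-B hits likewise, and rank *i* of A is
#' joined to rank *i* of B for *i* up to the smaller per-species count.
#' Rows lacking a taxid are skipped.
#'
#' @param msaA,msaB Annotated [monomer_msa()] objects.
#' @return `data.frame` of paired rows with `stage = "phylogeny"` and
#'   `taxid`/`rank` detail, ordered by taxid then rank.
#' @export
pair_phylogeny <- function(msaA, msaB) {
  .require_annotated(msaA, "pair_phylogeny"); .require_annotated(msaB, "pair_phylogeny")
  a <- msaA$hits[!is.na(msaA$hits$taxid), , drop = FALSE]
  b <- msaB$hits[!is.na(msaB$hits$taxid), , drop = FALSE]
  shared <- sort(intersect(unique(a$taxid), unique(b$taxid)))
  if (!length(shared)) return(.empty_pairs())
  rank_order <- function(h) {
    ev <- ifelse(is.na(h$evalue), Inf, h$evalue)
    h[order(-h$identity, ev, h$accession), , drop = FALSE]
  }
  out <- lapply(shared, function(tx) {
    ha <- rank_order(a[a$taxid == tx, , drop = FALSE])
    hb <- rank_order(b[b$taxid == tx, , drop = FALSE])
    m <- min(nrow(ha), nrow(hb))
    if (!m) return(NULL)
    data.frame(accession_A = ha$accession[seq_len(m)],
               accession_B = hb$accession[seq_len(m)],
               seq_A = ha$matched[seq_len(m)], seq_B = hb$matched[seq_len(m)],
               stage = "phylogeny", delta_gene = NA_real_,
               taxid = as.numeric(tx), rank = seq_len(m),
               combined_score = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .empty_pairs() else { rownames(out) <- NULL; out }
}

#' Pair MSA rows by interaction-network links
#'
#' Candidate pairs are hits whose network ids share an interaction link with
#' combined score at least `min_score`.  The one-to-one assignment maximises
#' the total combined score, with ties broken by higher mean identity to the
#' query and then lexicographic accessions.  Rows lacking a network id are
#' skipped.
#'
#' @param msaA,msaB Annotated [monomer_msa()] objects.
#' @param links Links table from [load_interaction_links()] or an
#'   [annotation_bundle()].
#' @param min_score Minimum combined score (0-1000; default 0).
#' @param method `"exact"` or `"greedy"`, as in [pair_genomic()].
#' @return `data.frame` of paired rows with `stage = "string"` and
#'   `combined_score` detail.
#' @export
pair_string <- function(msaA, msaB, links, min_score = 0L,
                        method = c("exact", "greedy")) {
  method <- match.arg(method)
  .require_annotated(msaA, "pair_string"); .require_annotated(msaB, "pair_string")
  if (inherits(links, "annotation_bundle")) links <- links$links
  a <- msaA$hits[!is.na(msaA$hits$netid), , drop = FALSE]
  b <- msaB$hits[!is.na(msaB$hits$netid), , drop = FALSE]
  if (!nrow(a) || !nrow(b) || !nrow(links)) return(.empty_pairs())
  cand <- merge(a, b, by = NULL, suffixes = c("_A", "_B"))  # cartesian
  cand$score <- link_score(links, cand$netid_A, cand$netid_B)
  cand <- cand[!is.na(cand$score) & cand$score >= min_score, , drop = FALSE]
  if (!nrow(cand)) return(.empty_pairs())
  cand$mean_id <- (cand$identity_A + cand$identity_B) / 2
  cand <- cand[order(-cand$score, -cand$mean_id, cand$accession_A, cand$accession_B), , drop = FALSE]
  cand$weight <- cand$score
  keep <- .match_one_to_one(cand, "max_weight", method)
  sel <- cand[keep, , drop = FALSE]
  data.frame(accession_A = sel$accession_A, accession_B = sel$accession_B,
             seq_A = sel$matched_A, seq_B = sel$matched_B, stage = "string",
             delta_gene = NA_real_, taxid = NA_real_, rank = NA_real_,
             combined_score = sel$score, stringsAsFactors = FALSE, row.names = NULL)
}
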