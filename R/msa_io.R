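# Reading, normalising and writing monomer and paired alignments, plus the
# pairwise identity primitive every downstream weighting step relies on.

#' Construct a monomer MSA object
#'
#' A monomer MSA holds the query sequence of one chain plus its aligned
#' homologs, all reduced to match columns: every row has exactly the query's
#' length and contains only uppercase residues, `X`, or the gap `-`.
#'
#' @param query_accession Accession of the query sequence.
#' @param query_seq Ungapped query sequence (match columns only).
#' @param hits `data.frame` with columns `accession` and `matched`
#'   (aligned strings of query length); optional column `evalue`.
#' @param chain Chain label, `"A"` or `"B"`.
#' @param identity_mode Mode passed to [pairwise_identity()] when computing
#'   each hit's identity to the query.
#' @return An object of class `monomer_msa` with elements `chain`, `query`
#'   (list with `accession`, `matched`), `hits` (data.frame with columns
#'   `accession`, `matched`, `identity`, `evalue`) and `L` (match-column
#'   count).
#' @export
monomer_msa <- function(query_accession, query_seq, hits = NULL,
                        chain = "A", identity_mode = "both_ungapped") {
  chain <- match.arg(chain, c("A", "B"))
  if (!is.character(query_seq) || length(query_seq) != 1L || !nzchar(query_seq))
    stop("query sequence must be a non-empty string")
  if (grepl("-", query_seq, fixed = TRUE))
    stop("query sequence must be ungapped (match columns only)")
  .check_aligned_chars(query_seq, query_accession)
  L <- nchar(query_seq)
  if (is.null(hits)) {
    hits <- data.frame(accession = character(), matched = character(),
                       evalue = numeric(), stringsAsFactors = FALSE)
  }
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (!all(c("accession", "matched") %in% names(hits)))
    stop("hits must have columns 'accession' and 'matched'")
  if (is.null(hits$evalue)) hits$evalue <- rep(NA_real_, nrow(hits))
  bad <- which(nchar(hits$matched) != L)
  if (length(bad))
    stop(sprintf("row '%s': aligned length %d differs from query length %d",
                 hits$accession[bad[1]], nchar(hits$matched[bad[1]]), L))
  for (i in seq_len(nrow(hits))) .check_aligned_chars(hits$matched[i], hits$accession[i])
  hits$identity <- vapply(hits$matched, pairwise_identity, numeric(1),
                          y = query_seq, mode = identity_mode, USE.NAMES = FALSE)
  hits <- hits[, c("accession", "matched", "identity", "evalue")]
  rownames(hits) <- NULL
  structure(
    list(chain = chain,
         query = list(accession = query_accession, matched = query_seq),
         hits = hits, L = L),
    class = "monomer_msa"
  )
}

.check_aligned_chars <- function(s, accession) {
  if (grepl("[^A-Z-]", s))
    stop(sprintf("row '%s': aligned string may contain only uppercase residues, 'X', or '-'",
                 accession))
  invisible(TRUE)
}

#' @export
print.monomer_msa <- function(x, ...) {
  cat(sprintf("Monomer MSA (chain %s): query '%s', %d match columns, %d hit row(s)\n",
              x$chain, x$query$accession, x$L, nrow(x$hits)))
  if (nrow(x$hits)) {
    shown <- utils::head(x$hits, 5L)
    cat(sprintf("  %-18s identity\n", "accession"))
    for (i in seq_len(nrow(shown)))
      cat(sprintf("  %-18s %.3f\n", shown$accession[i], shown$identity[i]))
    if (nrow(x$hits) > 5L) cat(sprintf("  ... and %d more\n", nrow(x$hits) - 5L))
  }
  invisible(x)
}

#' Read a monomer MSA from an A3M / aligned FASTA file
#'
#' The first record is taken as the query.  Following the A3M convention,
#' lowercase characters (insertions relative to the query's match states)
#' and `.` placeholders are removed, so every row collapses to the query's
#' match columns.  Per-hit identity to the query is recomputed after
#' normalisation.
#'
#' @param path Path to an A3M or aligned FASTA file, query first.
#' @param chain Chain label for the resulting MSA.
#' @param identity_mode Identity mode for the per-hit identity to the query.
#' @return A [monomer_msa()] object.
#' @export
read_a3m <- function(path, chain = "A", identity_mode = "both_ungapped") {
  recs <- .read_fasta_records(path)
  seqs <- vapply(as.character(recs), normalize_a3m_row, character(1), USE.NAMES = FALSE)
  accs <- vapply(strsplit(names(recs), "[ \t]"), `[`, character(1), 1L)
  L <- nchar(seqs[1])
  bad <- which(nchar(seqs) != L)
  if (length(bad))
    stop(sprintf("in '%s': row '%s' has normalized length %d, expected query length %d",
                 path, accs[bad[1]], nchar(seqs[bad[1]]), L))
  hits <- data.frame(accession = accs[-1], matched = seqs[-1], stringsAsFactors = FALSE)
  monomer_msa(accs[1], seqs[1], hits, chain = chain, identity_mode = identity_mode)
}

# FASTA reader tolerant of the leading '#' annotation lines some A3M
# dialects carry (they are skipped before handing off to Biostrings).
.read_fasta_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  n_hash <- 0L
  while (n_hash < length(lines) && grepl("^#", lines[n_hash + 1L])) n_hash <- n_hash + 1L
  body <- lines[seq_along(lines) > n_hash]
  if (!length(body) || !any(nzchar(body))) stop(sprintf("empty alignment file: %s", path))
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(body, tmp)
  recs <- tryCatch(Biostrings::readBStringSet(tmp),
                   error = function(e) stop(sprintf("cannot parse '%s' as FASTA: %s",
                                                    path, conditionMessage(e))))
  if (length(recs) == 0L) stop(sprintf("empty alignment file: %s", path))
  recs
}

#' Normalise one A3M row to match columns
#'
#' Removes lowercase insertion characters and `.` placeholders and upper-cases
#' nothing: remaining characters must already be uppercase residues or `-`.
#' Idempotent on normalised rows.
#'
#' @param s An A3M sequence string.
#' @return The match-column string.
#' @export
normalize_a3m_row <- function(s) gsub("[a-z.]", "", s)

#' Pairwise sequence identity between two aligned strings
#'
#' @param x,y Aligned strings of equal length.
#' @param mode `"both_ungapped"` counts identical residues over columns where
#'   both rows carry a residue (0 when no such column exists);
#'   `"full_length"` divides by the full alignment length.  `X` never matches
#'   anything, and a column gapped in both rows contributes to neither count.
#' @return Identity as a fraction in `[0, 1]`; symmetric in `x` and `y`.
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDF")                    # 0.75
#' pairwise_identity("AC-E", "ACDE")                    # 1.0  (3/3)
#' pairwise_identity("AC-E", "ACDE", "full_length")     # 0.75 (3/4)
pairwise_identity <- function(x, y, mode = c("both_ungapped", "full_length")) {
  mode <- match.arg(mode)
  if (nchar(x) != nchar(y))
    stop(sprintf("aligned lengths differ: %d vs %d", nchar(x), nchar(y)))
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  ident <- sum(cx == cy & cx != "-" & cx != "X")
  if (mode == "full_length") return(ident / length(cx))
  denom <- sum(cx != "-" & cy != "-")
  if (denom == 0L) return(0)
  ident / denom
}

# Character matrix (rows x columns) for a vector of equal-length aligned
# strings; used by the identity-matrix computations.
.char_matrix <- function(seqs) {
  if (!length(seqs)) return(matrix(character(), 0L, 0L))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# All-vs-all identity matrix for one chain of a paired alignment.
.chain_identity_matrix <- function(seqs, mode = "both_ungapped") {
  n <- length(seqs)
  m <- .char_matrix(seqs)
  out <- diag(1, n)
  if (n < 2L) return(out)
  L <- ncol(m)
  resid <- m != "-"
  matchable <- resid & m != "X"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ident <- sum(m[i, ] == m[j, ] & matchable[i, ])
      s <- if (mode == "full_length") ident / L else {
        denom <- sum(resid[i, ] & resid[j, ])
        if (denom == 0L) 0 else ident / denom
      }
      out[i, j] <- out[j, i] <- s
    }
  }
  # self-identity of a gap-only row is 0 under both_ungapped; keep diag consistent
  for (i in seq_len(n)) {
    out[i, i] <- if (mode == "full_length") sum(matchable[i, ]) / L
                 else if (any(resid[i, ])) sum(matchable[i, ]) / sum(resid[i, ])
                 else 0
  }
  out
}

#' Construct a paired (complex) MSA object
#'
#' @param rows `data.frame` with columns `accession_A`, `accession_B`,
#'   `seq_A`, `seq_B`, `stage` and the stage-detail columns `delta_gene`,
#'   `taxid`, `rank`, `combined_score` (missing detail columns are added as
#'   `NA`).  The first row must be the query pair, `stage = "query"`.
#' @param L_A,L_B Chain lengths; defaults taken from the query pair.
#' @return An object of class `cpx_msa` with elements `rows`, `L_A`, `L_B`,
#'   `L` (`= L_A + L_B`).
#' @export
cpx_msa <- function(rows, L_A = NULL, L_B = NULL) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("accession_A", "accession_B", "seq_A", "seq_B", "stage")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  if (nrow(rows) == 0L) stop("a paired MSA needs at least the query pair")
  for (col in c("delta_gene", "taxid", "rank", "combined_score"))
    if (is.null(rows[[col]])) rows[[col]] <- NA_real_
  rows <- rows[, c(need, "delta_gene", "taxid", "rank", "combined_score")]
  if (rows$stage[1] != "query") stop("the first row must be the query pair (stage 'query')")
  if (is.null(L_A)) L_A <- nchar(rows$seq_A[1])
  if (is.null(L_B)) L_B <- nchar(rows$seq_B[1])
  if (any(nchar(rows$seq_A) != L_A) || any(nchar(rows$seq_B) != L_B))
    stop("all rows must have chain lengths (L_A, L_B) = (", L_A, ", ", L_B, ")")
  key <- paste(rows$accession_A, rows$accession_B, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (accession_A, accession_B) pair: ",
         sub("\r", " / ", key[duplicated(key)][1], fixed = TRUE))
  rownames(rows) <- NULL
  structure(list(rows = rows, L_A = L_A, L_B = L_B, L = L_A + L_B),
            class = "cpx_msa")
}

#' @export
print.cpx_msa <- function(x, ...) {
  cat(sprintf("Paired complex MSA: %d row(s) (incl. query pair), L_A = %d, L_B = %d, L = %d\n",
              nrow(x$rows), x$L_A, x$L_B, x$L))
  tab <- table(x$rows$stage)
  cat("  rows by stage:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cpx_msa <- function(object, ...) {
  nec <- compute_necs(object)
  cat(sprintf("Paired complex MSA with %d rows (L = %d)\n", nrow(object$rows), object$L))
  tab <- table(object$rows$stage)
  cat("  rows by stage:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  effective sequences (Necs, threshold %.2f, %s): %.4f\n",
              nec$threshold, nec$scaling, nec$necs))
  invisible(nec)
}

# Concatenated two-chain sequence per row.
concat_rows <- function(cpx) paste0(cpx$rows$seq_A, cpx$rows$seq_B)

#' Write a paired MSA to disk
#'
#' `a3m` writes FASTA records with headers `>accA|accB|stage`, the query pair
#' first, preceded by a `#cpx L_A=<int> L_B=<int>` comment line so the file
#' round-trips through [read_complex_alignment()] without extra arguments.
#' `aln` writes one concatenated sequence per line, no headers.
#'
#' @param cpx A [cpx_msa()] object.
#' @param path Output file path.
#' @param format `"a3m"` or `"aln"`.
#' @return `path`, invisibly.
#' @export
write_complex_alignment <- function(cpx, path, format = c("a3m", "aln")) {
  format <- match.arg(format)
  stopifnot(inherits(cpx, "cpx_msa"))
  cat_seqs <- concat_rows(cpx)
  if (any(nchar(cat_seqs) != cpx$L))
    stop("internal consistency error: concatenated row lengths differ from L")
  if (format == "aln") {
    writeLines(cat_seqs, path)
  } else {
    hdr <- sprintf(">%s|%s|%s", cpx$rows$accession_A, cpx$rows$accession_B, cpx$rows$stage)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#cpx L_A=%d L_B=%d", cpx$L_A, cpx$L_B), con)
    writeLines(as.vector(rbind(hdr, cat_seqs)), con)
  }
  invisible(path)
}

#' Read a paired MSA written by [write_complex_alignment()]
#'
#' @param path Path to an `a3m` (headers `accA|accB|stage`) or `aln` file.
#' @param L_A Chain-A length, used to split the concatenated rows.  Optional
#'   for `a3m` files carrying the `#cpx` header line; required for `aln`.
#' @param format `"a3m"` or `"aln"`.
#' @return A [cpx_msa()] object.
#' @export
read_complex_alignment <- function(path, L_A = NULL, format = c("a3m", "aln")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "aln") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop(sprintf("empty alignment file: %s", path))
    if (is.null(L_A)) stop("L_A must be given to split concatenated aln rows")
    acc_a <- c("queryA", sprintf("rowA%03d", seq_along(lines)[-1] - 1L))
    acc_b <- c("queryB", sprintf("rowB%03d", seq_along(lines)[-1] - 1L))
    stage <- c("query", rep("unknown", length(lines) - 1L))
    seqs <- lines
  } else {
    first <- readLines(path, n = 1L)
    if (length(first) && grepl("^#cpx ", first)) {
      la <- as.integer(sub(".*L_A=(\\d+).*", "\\1", first))
      if (is.null(L_A)) L_A <- la
    }
    recs <- .read_fasta_records(path)
    parts <- strsplit(names(recs), "|", fixed = TRUE)
    if (any(lengths(parts) < 3L))
      stop("a3m headers must have the form accA|accB|stage")
    acc_a <- vapply(parts, `[`, character(1), 1L)
    acc_b <- vapply(parts, `[`, character(1), 2L)
    stage <- vapply(parts, `[`, character(1), 3L)
    seqs <- vapply(as.character(recs), normalize_a3m_row, character(1), USE.NAMES = FALSE)
    if (is.null(L_A)) stop("L_A missing: no #cpx header line and no L_A argument")
  }
  if (any(nchar(seqs) < L_A)) stop("row shorter than declared L_A")
  cpx_msa(data.frame(accession_A = acc_a, accession_B = acc_b,
                     seq_A = substr(seqs, 1L, L_A),
                     seq_B = substr(seqs, L_A + 1L, nchar(seqs)),
                     stage = stage, stringsAsFactors = FALSE),
          L_A = L_A)
}
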