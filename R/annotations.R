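# Loading and indexing the three metadata sources that drive pairing:
# gene locations (genome + gene-order index), taxonomy, and interaction
# network identifiers/links.  Tables are pre-extracted TSV at desk scale;
# lookups on absent accessions yield NA ("unannotated"), never an error.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Load gene locations (accession, genome, gene-order index, strand)
#'
#' The gene index is an ordinal gene rank along its genome (0-based), not a
#' base-pair coordinate; genomic pairing works on differences of these ranks.
#'
#' @param path TSV file with header columns `accession`, `genome_id`,
#'   `gene_index`, `strand`.
#' @return `data.frame` indexed by accession (one row per accession; on
#'   duplicates the last row wins, with a warning).
#' @export
load_gene_locations <- function(path) {
  tab <- .read_tsv(path)
  need <- c("accession", "genome_id", "gene_index", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("gene table '%s' lacks column(s): %s", path, paste(miss, collapse = ", ")))
  idx <- suppressWarnings(as.integer(tab$gene_index))
  num <- suppressWarnings(as.numeric(tab$gene_index))
  bad <- which(is.na(idx) | idx < 0 | is.na(num) | idx != num)
  if (length(bad))
    stop(sprintf("gene table '%s' line %d: gene_index '%s' is not a non-negative integer",
                 path, bad[1] + 1L, tab$gene_index[bad[1]]))
  tab$gene_index <- idx
  tab$strand <- ifelse(tab$strand %in% c("+", "-"), tab$strand, "unknown")
  if (anyDuplicated(tab$accession)) {
    warning(sprintf("gene table '%s': duplicate accession(s), keeping the last occurrence", path))
    tab <- tab[!duplicated(tab$accession, fromLast = TRUE), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, need]
}

#' Load taxonomy assignments (accession, taxid, optional species name)
#'
#' @param path TSV file with header columns `accession`, `taxid`
#'   (`species_name` optional).
#' @return `data.frame` with one row per accession (last duplicate wins,
#'   with a warning).
#' @export
load_taxonomy <- function(path) {
  tab <- .read_tsv(path)
  miss <- setdiff(c("accession", "taxid"), names(tab))
  if (length(miss))
    stop(sprintf("taxonomy table '%s' lacks column(s): %s", path, paste(miss, collapse = ", ")))
  taxid <- suppressWarnings(as.integer(tab$taxid))
  bad <- which(is.na(taxid) | taxid <= 0L)
  if (length(bad))
    stop(sprintf("taxonomy table '%s' line %d: taxid '%s' is not a positive integer",
                 path, bad[1] + 1L, tab$taxid[bad[1]]))
  tab$taxid <- taxid
  if (is.null(tab$species_name)) tab$species_name <- rep(NA_character_, nrow(tab))
  if (anyDuplicated(tab$accession)) {
    warning(sprintf("taxonomy table '%s': duplicate accession(s), keeping the last occurrence", path))
    tab <- tab[!duplicated(tab$accession, fromLast = TRUE), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("accession", "taxid", "species_name")]
}

#' Load accession-to-network-id mappings
#'
#' @param path TSV file with header columns `accession`, `string_id`.
#' @return `data.frame` with one row per accession (last duplicate wins).
#' @export
load_netids <- function(path) {
  tab <- .read_tsv(path)
  miss <- setdiff(c("accession", "string_id"), names(tab))
  if (length(miss))
    stop(sprintf("network-id table '%s' lacks column(s): %s", path, paste(miss, collapse = ", ")))
  if (anyDuplicated(tab$accession)) {
    warning(sprintf("network-id table '%s': duplicate accession(s), keeping the last occurrence", path))
    tab <- tab[!duplicated(tab$accession, fromLast = TRUE), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("accession", "string_id")]
}

#' Load undirected interaction links
#'
#' Accepts the interaction network's space-separated dialect
#' (`protein1 protein2 combined_score`, header line tolerated).  Links are
#' stored canonically with lexicographically ordered endpoints; symmetric
#' duplicates collapse keeping the maximum score, and self-links are dropped
#' with a warning.
#'
#' @param path Whitespace-delimited links file.
#' @param min_score Drop links with `combined_score` below this value
#'   (0-1000 scale; default 0 keeps all).
#' @return `data.frame` with columns `protein1`, `protein2`,
#'   `combined_score` (`protein1 < protein2`).
#' @export
load_interaction_links <- function(path, min_score = 0L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("protein1", lines[1], fixed = TRUE)) lines <- lines[-1]
  if (!length(lines))
    return(data.frame(protein1 = character(), protein2 = character(),
                      combined_score = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("links file '%s' line %d: expected 'protein1 protein2 combined_score'",
                 path, bad[1]))
  p1 <- vapply(parts, `[`, character(1), 1L)
  p2 <- vapply(parts, `[`, character(1), 2L)
  sc <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  bad <- which(is.na(sc) | sc < 0L | sc > 1000L)
  if (length(bad))
    stop(sprintf("links file '%s' line %d: combined_score must be an integer in [0, 1000]",
                 path, bad[1]))
  self <- p1 == p2
  if (any(self)) {
    warning(sprintf("links file '%s': dropping %d self-link(s)", path, sum(self)))
    p1 <- p1[!self]; p2 <- p2[!self]; sc <- sc[!self]
  }
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  df <- data.frame(protein1 = lo, protein2 = hi, combined_score = sc,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein1, df$protein2, -df$combined_score), , drop = FALSE]
  df <- df[!duplicated(paste(df$protein1, df$protein2)), , drop = FALSE]
  df <- df[df$combined_score >= min_score, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Bundle the three annotation sources
#'
#' @param gene_table Output of [load_gene_locations()] (or `NULL`).
#' @param taxon_table Output of [load_taxonomy()] (or `NULL`).
#' @param netid_table Output of [load_netids()] (or `NULL`).
#' @param links Output of [load_interaction_links()] (or `NULL`).
#' @return An object of class `annotation_bundle`.  Missing components behave
#'   as empty tables: lookups return "unannotated", never fail.
#' @export
annotation_bundle <- function(gene_table = NULL, taxon_table = NULL,
                              netid_table = NULL, links = NULL) {
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (is.null(gene_table))
    gene_table <- empty(accession = character(), genome_id = character(),
                        gene_index = integer(), strand = character())
  if (is.null(taxon_table))
    taxon_table <- empty(accession = character(), taxid = integer(),
                         species_name = character())
  if (is.null(netid_table))
    netid_table <- empty(accession = character(), string_id = character())
  if (is.null(links))
    links <- empty(protein1 = character(), protein2 = character(),
                   combined_score = integer())
  structure(list(gene_table = gene_table, taxon_table = taxon_table,
                 netid_table = netid_table, links = links),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("Annotation bundle: %d gene location(s), %d taxon assignment(s), %d network id(s), %d link(s)\n",
              nrow(x$gene_table), nrow(x$taxon_table), nrow(x$netid_table), nrow(x$links)))
  invisible(x)
}

#' Query an undirected interaction link
#'
#' @param bundle An [annotation_bundle()] (or a links `data.frame`).
#' @param p,q Network ids.
#' @return The link's combined score, or `NA` if no link exists.  Symmetric:
#'   `link_score(b, p, q) == link_score(b, q, p)`.
#' @export
link_score <- function(bundle, p, q) {
  links <- if (inherits(bundle, "annotation_bundle")) bundle$links else bundle
  lo <- pmin(p, q); hi <- pmax(p, q)
  hit <- match(paste(lo, hi), paste(links$protein1, links$protein2))
  ifelse(is.na(hit), NA_integer_, links$combined_score[hit])
}

#' Tag every MSA row with its annotations
#'
#' Adds columns `genome_id`, `gene_index`, `strand`, `taxid`, `netid` to the
#' hit table; absent annotations become `NA` ("unannotated") and counts per
#' source are reported as a message.  Missing annotation is data, not an
#' error.
#'
#' @param msa A [monomer_msa()] object.
#' @param bundle An [annotation_bundle()].
#' @param quiet Suppress the per-source unannotated counts.
#' @return The annotated `monomer_msa`.
#' @export
annotate <- function(msa, bundle, quiet = FALSE) {
  stopifnot(inherits(msa, "monomer_msa"), inherits(bundle, "annotation_bundle"))
  h <- msa$hits
  gi <- match(h$accession, bundle$gene_table$accession)
  h$genome_id <- bundle$gene_table$genome_id[gi]
  h$gene_index <- bundle$gene_table$gene_index[gi]
  h$strand <- bundle$gene_table$strand[gi]
  ti <- match(h$accession, bundle$taxon_table$accession)
  h$taxid <- bundle$taxon_table$taxid[ti]
  ni <- match(h$accession, bundle$netid_table$accession)
  h$netid <- bundle$netid_table$string_id[ni]
  msa$hits <- h
  msa$annotated <- TRUE
  if (!quiet && nrow(h))
    message(sprintf("chain %s: %d/%d rows lack gene location, %d/%d lack taxid, %d/%d lack network id",
                    msa$chain, sum(is.na(gi)), nrow(h), sum(is.na(ti)), nrow(h),
                    sum(is.na(ni)), nrow(h)))
  msa
}
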