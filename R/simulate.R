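# Synthetic two-chain homolog families with planted ground-truth pairings.
# Each interacting pair shares a genome with a gene-rank difference inside
# the genomic window, shares a species, and carries an interaction link, so
# every pairing strategy can recover it.  Orphan rows act as decoys: they
# sit on real genomes but far outside the gene-distance window, carry a
# species seen on one side only, and have no interaction link.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

#' Mutate a protein sequence position-wise
#'
#' Each position is independently substituted, with probability `rate`, by a
#' uniformly chosen different amino acid.  Length is always preserved and no
#' indels are introduced.
#'
#' @param seq Residue string (standard 20-letter alphabet).
#' @param rate Per-position substitution probability in `[0, 1]`.
#' @return Mutated residue string.
#' @export
mutate_sequence <- function(seq, rate) {
  if (rate < 0 || rate > 1) stop("substitution rate must lie in [0, 1]")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic two-chain family with planted pairings
#'
#' Two ancestor (query) sequences are mutated once per (species, genome,
#' paralog block) to produce homolog rows for both chains.  Interacting
#' partners are placed on one genome within the gene-distance window
#' (rank difference drawn from 1-20); paralog blocks on the same genome are
#' separated by more than the window so each planted pair is the unique
#' in-window candidate.  Taxonomy and network ids are consistent with the
#' planted pairs, and every pair carries an interaction link.  A fraction of
#' extra rows per chain are orphans/decoys as described above.  Per-row
#' identity to the query is recomputed from the generated sequences.
#'
#' @param n_species Number of species (default 10).
#' @param genomes_per_species Genomes per species (default 1).
#' @param paralogs_per_genome Planted pairs per genome (default 1).
#' @param substitution_rate Per-position substitution probability
#'   (default 0.2).
#' @param orphan_fraction Orphans added per chain as a fraction of the
#'   planted rows (default 0).
#' @param L_A,L_B Chain lengths (defaults 60 and 50).
#' @param max_d Width of the gene-distance window the pairs are planted in
#'   (default 20).
#' @param seed Integer RNG seed; the family is reproducible from it.
#' @return Object of class `synthetic_family`: list with `msaA`, `msaB`
#'   ([monomer_msa()]), `bundle` ([annotation_bundle()]), `true_pairs`
#'   (`data.frame` of planted accession pairs) and `params`.
#' @export
generate_family <- function(n_species = 10L, genomes_per_species = 1L,
                            paralogs_per_genome = 1L, substitution_rate = 0.2,
                            orphan_fraction = 0, L_A = 60L, L_B = 50L,
                            max_d = 20L, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("substitution_rate must lie in [0, 1]")
  if (orphan_fraction < 0 || orphan_fraction > 1)
    stop("orphan_fraction must lie in [0, 1]")
  if (n_species < 0 || genomes_per_species < 0 || paralogs_per_genome < 0)
    stop("counts must be non-negative")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  queryA <- .random_protein(L_A)
  queryB <- .random_protein(L_B)
  hitsA <- hitsB <- gene <- taxon <- netid <- links <- tp <- list()
  k <- 0L
  for (s in seq_len(n_species)) {
    taxid <- 1000L + s
    for (g in seq_len(genomes_per_species)) {
      genome <- sprintf("genome_s%02d_g%02d", s, g)
      for (p in seq_len(paralogs_per_genome)) {
        k <- k + 1L
        accA <- sprintf("homA_s%02dg%02dp%02d", s, g, p)
        accB <- sprintf("homB_s%02dg%02dp%02d", s, g, p)
        seqA <- mutate_sequence(queryA, substitution_rate)
        seqB <- mutate_sequence(queryB, substitution_rate)
        # paralog blocks 3 windows apart so only the planted partner is in range
        base <- (p - 1L) * 3L * max_d
        dg <- sample.int(max_d, 1L)
        hitsA[[k]] <- data.frame(accession = accA, matched = seqA, stringsAsFactors = FALSE)
        hitsB[[k]] <- data.frame(accession = accB, matched = seqB, stringsAsFactors = FALSE)
        gene[[length(gene) + 1L]] <- data.frame(
          accession = c(accA, accB), genome_id = genome,
          gene_index = c(base, base + dg), strand = sample(c("+", "-"), 2L, replace = TRUE),
          stringsAsFactors = FALSE)
        taxon[[length(taxon) + 1L]] <- data.frame(
          accession = c(accA, accB), taxid = taxid,
          species_name = sprintf("Species %02d", s), stringsAsFactors = FALSE)
        netid[[length(netid) + 1L]] <- data.frame(
          accession = c(accA, accB), string_id = c(paste0("net.", accA), paste0("net.", accB)),
          stringsAsFactors = FALSE)
        links[[length(links) + 1L]] <- data.frame(
          protein1 = paste0("net.", accA), protein2 = paste0("net.", accB),
          combined_score = sample(600:999, 1L), stringsAsFactors = FALSE)
        tp[[k]] <- data.frame(accession_A = accA, accession_B = accB,
                              taxid = taxid, genome_id = genome, delta_gene = dg,
                              stringsAsFactors = FALSE)
      }
    }
  }
  n_orphans <- as.integer(round(orphan_fraction * k))
  genomes <- unique(do.call(rbind, gene)$genome_id)
  for (o in seq_len(n_orphans)) {
    for (chain in c("A", "B")) {
      acc <- sprintf("orph%s_%03d", chain, o)
      qry <- if (chain == "A") queryA else queryB
      row <- data.frame(accession = acc, matched = mutate_sequence(qry, substitution_rate),
                        stringsAsFactors = FALSE)
      if (chain == "A") hitsA[[length(hitsA) + 1L]] <- row
      else hitsB[[length(hitsB) + 1L]] <- row
      if (length(genomes))  # on a real genome, but far outside every window
        gene[[length(gene) + 1L]] <- data.frame(
          accession = acc, genome_id = sample(genomes, 1L),
          gene_index = 100000L + o * 5L * max_d + (chain == "B") * 2L * max_d,
          strand = "+", stringsAsFactors = FALSE)
      taxon[[length(taxon) + 1L]] <- data.frame(
        accession = acc, taxid = 90000L + 2L * o + (chain == "B"),
        species_name = NA_character_, stringsAsFactors = FALSE)
      netid[[length(netid) + 1L]] <- data.frame(
        accession = acc, string_id = paste0("net.", acc), stringsAsFactors = FALSE)
    }
  }
  msaA <- monomer_msa("queryA", queryA, do.call(rbind, hitsA), chain = "A")
  msaB <- monomer_msa("queryB", queryB, do.call(rbind, hitsB), chain = "B")
  bundle <- annotation_bundle(
    gene_table = if (length(gene)) do.call(rbind, gene) else NULL,
    taxon_table = if (length(taxon)) do.call(rbind, taxon) else NULL,
    netid_table = if (length(netid)) do.call(rbind, netid) else NULL,
    links = if (length(links)) do.call(rbind, links) else NULL)
  structure(list(msaA = msaA, msaB = msaB, bundle = bundle,
                 true_pairs = if (k) do.call(rbind, tp) else
                   data.frame(accession_A = character(), accession_B = character()),
                 params = list(n_species = n_species,
                               genomes_per_species = genomes_per_species,
                               paralogs_per_genome = paralogs_per_genome,
                               substitution_rate = substitution_rate,
                               orphan_fraction = orphan_fraction,
                               L_A = L_A, L_B = L_B, max_d = max_d, seed = seed)),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("Synthetic two-chain family: %d planted pair(s), %d + %d hit rows, seed %d\n",
              nrow(x$true_pairs), nrow(x$msaA$hits), nrow(x$msaB$hits), x$params$seed))
  invisible(x)
}

#' Write a synthetic family to an output directory
#'
#' Writes `chainA.a3m`, `chainB.a3m`, the three annotation tables
#' (`genes.tsv`, `taxonomy.tsv`, `netids.tsv`), the links file
#' (`links.txt`), `true_pairs.tsv` and the generation parameters
#' (`params.json`).
#'
#' @param fam A `synthetic_family` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_family <- function(fam, dir) {
  stopifnot(inherits(fam, "synthetic_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_msa_a3m <- function(msa, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(paste0(">", msa$query$accession), msa$query$matched), con)
    for (i in seq_len(nrow(msa$hits)))
      writeLines(c(paste0(">", msa$hits$accession[i]), msa$hits$matched[i]), con)
  }
  write_msa_a3m(fam$msaA, file.path(dir, "chainA.a3m"))
  write_msa_a3m(fam$msaB, file.path(dir, "chainB.a3m"))
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(fam$bundle$gene_table, "genes.tsv")
  wt(fam$bundle$taxon_table, "taxonomy.tsv")
  wt(fam$bundle$netid_table, "netids.tsv")
  writeLines(c("protein1 protein2 combined_score",
               sprintf("%s %s %d", fam$bundle$links$protein1,
                       fam$bundle$links$protein2, fam$bundle$links$combined_score)),
             file.path(dir, "links.txt"))
  wt(fam$true_pairs, "true_pairs.tsv")
  jsonlite::write_json(fam$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
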