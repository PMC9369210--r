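# Independent brute-force oracles and small random-instance generators.
# These deliberately re-derive every quantity from first principles
# (per-column loops, full enumeration) so they share no code path with the
# package implementation they check.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(L, gap_prob = 0) {
  chars <- sample(AAS, L, replace = TRUE)
  if (gap_prob > 0) chars[runif(L) < gap_prob] <- "-"
  paste(chars, collapse = "")
}

# Mutated copies of an ancestor, so similarity clusters exist.
mutant_of <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in which(runif(length(chars)) < rate))
    if (chars[i] != "-") chars[i] <- sample(setdiff(AAS, chars[i]), 1)
  paste(chars, collapse = "")
}

# ---- identity / effective-sequence oracles --------------------------------

oracle_identity <- function(x, y, mode = "both_ungapped") {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  n_id <- 0L; n_both <- 0L
  for (k in seq_along(cx)) {
    if (cx[k] != "-" && cy[k] != "-") {
      n_both <- n_both + 1L
      if (cx[k] == cy[k] && cx[k] != "X") n_id <- n_id + 1L
    }
  }
  if (mode == "full_length") return(n_id / length(cx))
  if (n_both == 0L) 0 else n_id / n_both
}

# Plain double loop over rows; every S_ij recomputed from the strings.
oracle_necs <- function(seqA, seqB, threshold = 0.8, scaling = "inv_sqrt_L",
                        mode = "both_ungapped") {
  n <- length(seqA)
  L <- nchar(seqA[1]) + nchar(seqB[1])
  total <- 0
  for (i in seq_len(n)) {
    nbr <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      sA <- oracle_identity(seqA[i], seqA[j], mode)
      sB <- oracle_identity(seqB[i], seqB[j], mode)
      s <- if (sA == 0 || sB == 0) 0 else 2 / (1 / sA + 1 / sB)
      if (s >= threshold) nbr <- nbr + 1L
    }
    total <- total + 1 / (1 + nbr)
  }
  if (scaling == "inv_sqrt_L") total / sqrt(L) else total / L
}

# Random paired MSA with clustered rows (mutants of a few ancestor pairs).
rand_cpx <- function(n_rows, L_A, L_B, n_clusters = max(1, n_rows %/% 4),
                     rate = 0.08, gap_prob = 0.05) {
  ancA <- replicate(n_clusters, rand_seq(L_A))
  ancB <- replicate(n_clusters, rand_seq(L_B))
  cl <- sample.int(n_clusters, n_rows, replace = TRUE)
  rows <- data.frame(
    accession_A = sprintf("a%03d", seq_len(n_rows)),
    accession_B = sprintf("b%03d", seq_len(n_rows)),
    seq_A = vapply(cl, function(c) mutant_of(ancA[c], rate), character(1)),
    seq_B = vapply(cl, function(c) mutant_of(ancB[c], rate), character(1)),
    stage = c("query", rep("genomic", n_rows - 1)),
    stringsAsFactors = FALSE)
  if (gap_prob > 0 && n_rows > 1) {
    for (i in 2:n_rows) {
      ca <- strsplit(rows$seq_A[i], "")[[1]]
      ca[runif(L_A) < gap_prob] <- "-"
      rows$seq_A[i] <- paste(ca, collapse = "")
    }
  }
  cpx_msa(rows)
}

# ---- matching oracles -----------------------------------------------------

# All one-to-one matchings of a candidate edge list, by full enumeration.
enumerate_matchings <- function(accA, accB) {
  n <- length(accA)
  out <- list()
  rec <- function(k, pick) {
    if (k > n) { out[[length(out) + 1]] <<- pick; return(invisible(NULL)) }
    a_used <- accA[pick]; b_used <- accB[pick]
    if (!(accA[k] %in% a_used) && !(accB[k] %in% b_used)) rec(k + 1, c(pick, k))
    rec(k + 1, pick)
  }
  rec(1L, integer())
  out
}

# Maximum-cardinality matching with minimum total weight (gene distances).
oracle_min_weight_matching <- function(accA, accB, weight) {
  ms <- enumerate_matchings(accA, accB)
  card <- vapply(ms, length, integer(1))
  ms <- ms[card == max(card)]
  tot <- vapply(ms, function(p) sum(weight[p]), numeric(1))
  ms[abs(tot - min(tot)) < 1e-9]
}

# Matchings maximising the total weight (interaction scores).
oracle_max_weight_matching <- function(accA, accB, weight) {
  ms <- enumerate_matchings(accA, accB)
  tot <- vapply(ms, function(p) sum(weight[p]), numeric(1))
  ms <- ms[abs(tot - max(tot)) < 1e-9]
  card <- vapply(ms, length, integer(1))
  ms[card == max(card)]
}

# Per-species rank matching done the slow, obvious way.
oracle_rank_pairs <- function(hitsA, hitsB) {
  taxids <- sort(intersect(hitsA$taxid, hitsB$taxid))
  res <- list()
  for (tx in taxids) {
    ha <- hitsA[hitsA$taxid %in% tx, ]
    hb <- hitsB[hitsB$taxid %in% tx, ]
    ha <- ha[order(-ha$identity, ifelse(is.na(ha$evalue), Inf, ha$evalue), ha$accession), ]
    hb <- hb[order(-hb$identity, ifelse(is.na(hb$evalue), Inf, hb$evalue), hb$accession), ]
    for (i in seq_len(min(nrow(ha), nrow(hb))))
      res[[length(res) + 1]] <- c(ha$accession[i], hb$accession[i])
  }
  res
}

# ---- misc fixtures --------------------------------------------------------

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Tiny annotated two-chain toy: explicit hit tables and annotation tables.
toy_msas <- function(hitsA, hitsB, gene = NULL, taxon = NULL, netid = NULL,
                     links = NULL, L_A = 8, L_B = 6) {
  qa <- paste(rep("A", L_A), collapse = ""); qb <- paste(rep("C", L_B), collapse = "")
  msaA <- monomer_msa("qryA", qa, hitsA, chain = "A")
  msaB <- monomer_msa("qryB", qb, hitsB, chain = "B")
  bundle <- annotation_bundle(gene, taxon, netid, links)
  list(msaA = annotate(msaA, bundle, quiet = TRUE),
       msaB = annotate(msaB, bundle, quiet = TRUE), bundle = bundle)
}

# Annotated toy pair of MSAs whose hits sit at the given gene indices.
genomic_toy <- function(idxA, idxB, genomeA = "g1", genomeB = "g1") {
  nA <- length(idxA); nB <- length(idxB)
  hitsA <- data.frame(accession = sprintf("a%02d", seq_len(nA)),
                      matched = seqs_of(nA, 8), stringsAsFactors = FALSE)
  hitsB <- data.frame(accession = sprintf("b%02d", seq_len(nB)),
                      matched = seqs_of(nB, 6, "C"), stringsAsFactors = FALSE)
  gene <- data.frame(
    accession = c(hitsA$accession, hitsB$accession),
    genome_id = c(rep_len(genomeA, nA), rep_len(genomeB, nB)),
    gene_index = c(idxA, idxB),
    strand = "+", stringsAsFactors = FALSE)
  toy_msas(hitsA, hitsB, gene = gene)
}

seqs_of <- function(n, L, base = "A") {
  vapply(seq_len(n), function(i) {
    ch <- rep(base, L); ch[1 + (i %% L)] <- "W"; paste(ch, collapse = "")
  }, character(1))
}
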