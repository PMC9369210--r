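test_that("genomic pairing enforces the gene-distance window", {
  toy <- genomic_toy(5, 7)
  out <- pair_genomic(toy$msaA, toy$msaB)
  expect_identical(nrow(out), 1L)
  expect_identical(out$delta_gene, 2)
  expect_identical(out$stage, "genomic")

  expect_identical(nrow(pair_genomic(genomic_toy(5, 5)$msaA,
                                     genomic_toy(5, 5)$msaB)), 0L)   # delta 0
  toy21 <- genomic_toy(5, 26)
  expect_identical(nrow(pair_genomic(toy21$msaA, toy21$msaB)), 0L)   # delta 21
  toy20 <- genomic_toy(5, 25)
  expect_identical(pair_genomic(toy20$msaA, toy20$msaB)$delta_gene, 20)
  # different genomes never pair
  toyg <- genomic_toy(5, 6, genomeA = "g1", genomeB = "g2")
  expect_identical(nrow(pair_genomic(toyg$msaA, toyg$msaB)), 0L)
})

test_that("conflicting genomic candidates resolve to the smallest gene distance", {
  toy <- genomic_toy(c(5, 9), 6)   # a01 at 5 and a02 at 9 compete for b01 at 6
  out <- pair_genomic(toy$msaA, toy$msaB)
  expect_identical(nrow(out), 1L)
  expect_identical(out$accession_A, "a01")
  expect_identical(out$delta_gene, 1)
})

test_that("genomic matching is one-to-one, within bounds, and order-invariant", {
  set.seed(42)
  for (rep in 1:30) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    toy <- genomic_toy(sample(0:30, nA), sample(0:30, nB))
    out <- pair_genomic(toy$msaA, toy$msaB)
    expect_false(anyDuplicated(out$accession_A) > 0)
    expect_false(anyDuplicated(out$accession_B) > 0)
    if (nrow(out)) expect_true(all(out$delta_gene >= 1 & out$delta_gene <= 20))
    # permuting input hit rows changes nothing
    toy2 <- toy
    toy2$msaA$hits <- toy2$msaA$hits[rev(seq_len(nrow(toy2$msaA$hits))), ]
    toy2$msaB$hits <- toy2$msaB$hits[sample(nrow(toy2$msaB$hits)), ]
    expect_identical(pair_genomic(toy2$msaA, toy2$msaB), out)
  }
})

test_that("genomic matching attains the exhaustive minimum-distance optimum", {
  set.seed(7)
  for (rep in 1:60) {
    toy <- genomic_toy(sample(0:25, sample(2:4, 1)), sample(0:25, sample(2:4, 1)))
    out <- pair_genomic(toy$msaA, toy$msaB)
    # rebuild the candidate edge list independently
    ga <- toy$msaA$hits; gb <- toy$msaB$hits
    cand <- expand.grid(i = seq_len(nrow(ga)), j = seq_len(nrow(gb)))
    d <- abs(ga$gene_index[cand$i] - gb$gene_index[cand$j])
    keep <- d >= 1 & d <= 20
    cand <- cand[keep, ]; d <- d[keep]
    if (!nrow(cand)) { expect_identical(nrow(out), 0L); next }
    best <- oracle_min_weight_matching(ga$accession[cand$i], gb$accession[cand$j], d)
    expect_true(length(best) >= 1)
    expect_identical(nrow(out), length(best[[1]]))
    expect_equal(sum(out$delta_gene),
                 sum(d[best[[1]]]))
    # the returned pair set is one of the optimal matchings
    got <- sort(paste(out$accession_A, out$accession_B))
    opts <- lapply(best, function(p) sort(paste(ga$accession[cand$i[p]],
                                                gb$accession[cand$j[p]])))
    expect_true(any(vapply(opts, identical, logical(1), y = got)))
  }
})

test_that("phylogeny pairing joins per-species similarity ranks", {
  # identities are controlled through the number of mismatches to the query
  mk <- function(acc, nmut, L, base) {
    ch <- rep(base, L); if (nmut) ch[seq_len(nmut)] <- "W"
    data.frame(accession = acc, matched = paste(ch, collapse = ""),
               stringsAsFactors = FALSE)
  }
  hitsA <- rbind(mk("a_hi", 1, 8, "A"), mk("a_lo", 3, 8, "A"))       # 0.875, 0.625
  hitsB <- rbind(mk("b_hi", 0, 6, "C"), mk("b_mid", 1, 6, "C"),
                 mk("b_lo", 2, 6, "C"))
  taxon <- data.frame(accession = c(hitsA$accession, hitsB$accession),
                      taxid = 7L, species_name = NA, stringsAsFactors = FALSE)
  toy <- toy_msas(hitsA, hitsB, taxon = taxon)
  out <- pair_phylogeny(toy$msaA, toy$msaB)
  expect_identical(nrow(out), 2L)                       # min(m, n) pairs
  expect_identical(out$accession_A, c("a_hi", "a_lo"))
  expect_identical(out$accession_B, c("b_hi", "b_mid")) # third B hit unpaired
  expect_equal(out$rank, c(1, 2))

  # taxid on one side only contributes nothing
  taxon1 <- taxon; taxon1$taxid[taxon1$accession %in% hitsB$accession] <- 8L
  toy1 <- toy_msas(hitsA, hitsB, taxon = taxon1)
  expect_identical(nrow(pair_phylogeny(toy1$msaA, toy1$msaB)), 0L)
})

test_that("phylogeny pairing equals the per-species brute-force oracle", {
  set.seed(99)
  for (rep in 1:40) {
    nA <- sample(1:8, 1); nB <- sample(1:8, 1)
    hitsA <- data.frame(accession = sprintf("a%02d", seq_len(nA)),
                        matched = replicate(nA, mutant_of(strrep("A", 10), 0.4)),
                        stringsAsFactors = FALSE)
    hitsB <- data.frame(accession = sprintf("b%02d", seq_len(nB)),
                        matched = replicate(nB, mutant_of(strrep("C", 10), 0.4)),
                        stringsAsFactors = FALSE)
    taxon <- data.frame(accession = c(hitsA$accession, hitsB$accession),
                        taxid = sample(1:3, nA + nB, replace = TRUE),
                        species_name = NA, stringsAsFactors = FALSE)
    toy <- toy_msas(hitsA, hitsB, taxon = taxon, L_A = 10, L_B = 10)
    out <- pair_phylogeny(toy$msaA, toy$msaB)
    oracle <- oracle_rank_pairs(toy$msaA$hits, toy$msaB$hits)
    expect_identical(nrow(out), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_setequal(paste(out$accession_A, out$accession_B),
                      paste(om[, 1], om[, 2]))
    }
  }
})

test_that("interaction pairing follows links and prefers higher scores", {
  hitsA <- data.frame(accession = "a01", matched = seqs_of(1, 8),
                      stringsAsFactors = FALSE)
  hitsB <- data.frame(accession = c("b01", "b02"), matched = seqs_of(2, 6, "C"),
                      stringsAsFactors = FALSE)
  netid <- data.frame(accession = c("a01", "b01", "b02"),
                      string_id = c("nA", "nB1", "nB2"), stringsAsFactors = FALSE)
  links <- data.frame(protein1 = c("nA", "nA"), protein2 = c("nB1", "nB2"),
                      combined_score = c(400L, 900L), stringsAsFactors = FALSE)
  toy <- toy_msas(hitsA, hitsB, netid = netid, links = links)
  out <- pair_string(toy$msaA, toy$msaB, toy$bundle)
  expect_identical(nrow(out), 1L)
  expect_identical(out$accession_B, "b02")       # 900 beats 400
  expect_equal(out$combined_score, 900)

  # score threshold filters candidates
  out700 <- pair_string(toy$msaA, toy$msaB, toy$bundle, min_score = 950)
  expect_identical(nrow(out700), 0L)
  # no links at all -> empty
  toy0 <- toy_msas(hitsA, hitsB, netid = netid)
  expect_identical(nrow(pair_string(toy0$msaA, toy0$msaB, toy0$bundle)), 0L)
})

test_that("interaction matching attains the exhaustive max-score optimum", {
  set.seed(5)
  for (rep in 1:40) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    hitsA <- data.frame(accession = sprintf("a%02d", seq_len(nA)),
                        matched = seqs_of(nA, 8), stringsAsFactors = FALSE)
    hitsB <- data.frame(accession = sprintf("b%02d", seq_len(nB)),
                        matched = seqs_of(nB, 6, "C"), stringsAsFactors = FALSE)
    netid <- data.frame(accession = c(hitsA$accession, hitsB$accession),
                        string_id = paste0("n.", c(hitsA$accession, hitsB$accession)),
                        stringsAsFactors = FALSE)
    cand <- expand.grid(a = hitsA$accession, b = hitsB$accession,
                        stringsAsFactors = FALSE)
    cand <- cand[runif(nrow(cand)) < 0.5, ]
    if (!nrow(cand)) next
    links <- data.frame(protein1 = paste0("n.", cand$a),
                        protein2 = paste0("n.", cand$b),
                        combined_score = sample(100:999, nrow(cand)),
                        stringsAsFactors = FALSE)
    toy <- toy_msas(hitsA, hitsB, netid = netid, links = links)
    out <- pair_string(toy$msaA, toy$msaB, toy$bundle)
    best <- oracle_max_weight_matching(cand$a, cand$b, links$combined_score)
    expect_equal(sum(out$combined_score), sum(links$combined_score[best[[1]]]))
    expect_identical(nrow(out), length(best[[1]]))
  }
})
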