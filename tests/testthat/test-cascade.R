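qp <- function(L_A = 8, L_B = 6)
  data.frame(accession_A = "qryA", accession_B = "qryB",
             seq_A = strrep("A", L_A), seq_B = strrep("C", L_B),
             stage = "query", delta_gene = NA_real_, taxid = NA_real_,
             rank = NA_real_, combined_score = NA_real_,
             stringsAsFactors = FALSE)

prow <- function(a, b, sA, sB, stage)
  data.frame(accession_A = a, accession_B = b, seq_A = sA, seq_B = sB,
             stage = stage, delta_gene = NA_real_, taxid = NA_real_,
             rank = NA_real_, combined_score = NA_real_, stringsAsFactors = FALSE)

test_that("merging keeps the earliest stage's copy and is idempotent", {
  r1 <- prow("a1", "b1", "AAAAAAAW", "CCCCCW", "genomic")
  r2 <- prow("a1", "b1", "AAAAAAAW", "CCCCCW", "phylogeny")  # same pair + seq
  r3 <- prow("a2", "b2", "AAAAAAWW", "CCCCWW", "phylogeny")
  merged <- merge_and_dedupe(list(r1, rbind(r2, r3)), qp())
  expect_identical(nrow(merged$rows), 3L)
  expect_identical(merged$rows$stage, c("query", "genomic", "phylogeny"))
  expect_identical(attr(merged, "duplicates_removed"), 1L)

  again <- merge_and_dedupe(list(merged$rows[-1, ]), qp())
  expect_identical(again$rows, merged$rows)

  # disjoint outputs of sizes 3 and 4 give 8 rows with the query
  s1 <- do.call(rbind, lapply(1:3, function(i)
    prow(paste0("ga", i), paste0("gb", i), seqs_of(i, 8)[i], seqs_of(i, 6, "C")[i], "genomic")))
  s2 <- do.call(rbind, lapply(4:7, function(i)
    prow(paste0("pa", i), paste0("pb", i), seqs_of(i, 8)[i], seqs_of(i, 6, "D")[i], "phylogeny")))
  expect_identical(nrow(merge_and_dedupe(list(s1, s2), qp())$rows), 8L)
  expect_error(merge_and_dedupe(list(prow("x", "y", "AAA", "CC", "genomic")), qp()),
               "inconsistent")
})

test_that("the cascade stops as soon as the depth requirement is met", {
  fam <- generate_family(n_species = 8, seed = 4)
  # stage 1 alone is deep enough for a low requirement
  res1 <- select_cpxmsa(fam$msaA, fam$msaB, fam$bundle, necs_threshold = 0.3)
  expect_identical(res1$report$chosen_stages, 1L)
  expect_identical(nrow(res1$report$necs_per_step), 1L)
  expect_identical(unique(res1$cpx$rows$stage[-1]), "genomic")

  # no gene annotations: stage 1 is empty, stage 2 satisfies the requirement
  bundle2 <- annotation_bundle(NULL, fam$bundle$taxon_table,
                               fam$bundle$netid_table, fam$bundle$links)
  res2 <- select_cpxmsa(fam$msaA, fam$msaB, bundle2, necs_threshold = 0.3)
  expect_identical(res2$report$chosen_stages, c(1L, 2L))
  expect_identical(unique(res2$cpx$rows$stage[-1]), "phylogeny")

  # an unreachable requirement falls through to the full three-stage merge
  res3 <- select_cpxmsa(fam$msaA, fam$msaB, fam$bundle, necs_threshold = 128)
  expect_identical(res3$report$chosen_stages, c(1L, 2L, 3L))
  expect_identical(nrow(res3$report$necs_per_step), 3L)

  # the recorded depth never shrinks while rows accumulate
  steps <- res3$report$necs_per_step
  expect_true(all(diff(steps$n_rows) >= 0))

  # all stages empty: the query pair alone survives
  res0 <- select_cpxmsa(fam$msaA, fam$msaB, annotation_bundle(), necs_threshold = 1)
  expect_identical(nrow(res0$cpx$rows), 1L)
  expect_identical(res0$report$depth, "query-only")
})

test_that("raising the depth requirement never selects fewer stages", {
  fam <- generate_family(n_species = 6, seed = 9)
  depths <- vapply(c(0.1, 0.5, 1.0, 5, 128),
                   function(thr) length(select_cpxmsa(fam$msaA, fam$msaB, fam$bundle,
                                                      necs_threshold = thr)$report$chosen_stages),
                   numeric(1))
  expect_true(all(diff(depths) >= 0))
})

test_that("the selected alignment is at least as deep as stage 1 alone", {
  for (seed in 1:5) {
    fam <- generate_family(n_species = 6, orphan_fraction = 0.2, seed = seed)
    res <- select_cpxmsa(fam$msaA, fam$msaB, fam$bundle, necs_threshold = 128)
    steps <- res$report$necs_per_step
    expect_gte(steps$depth[nrow(steps)], steps$depth[1] - 1e-12)
  }
})

test_that("redundancy removal drops duplicates and near-identical rows", {
  # byte-identical duplicate
  rows <- rbind(qp(), prow("a1", "b1", "AAAAAAAW", "CCCCCW", "genomic"),
                prow("a2", "b2", "AAAAAAAW", "CCCCCW", "string"))
  rows$stage[1] <- "query"
  cpx <- cpx_msa(rows)
  red <- remove_redundant(cpx)
  expect_identical(nrow(red$rows), 2L)
  expect_identical(attr(red, "redundant_removed"), 1L)
  expect_identical(remove_redundant(red)$rows, red$rows)   # fixed point

  # near-identical pair at S = 0.995 is removed once max_id drops below it
  L <- 200
  s1 <- strrep("A", L); s2 <- paste0("W", strrep("A", L - 1))   # identity 0.995
  rows2 <- rbind(qp(L, L),
                 prow("a1", "b1", s1, s1, "genomic"),
                 prow("a2", "b2", s2, s2, "genomic"))
  rows2$seq_A[1] <- rand_seq(L); rows2$seq_B[1] <- rand_seq(L)
  cpx2 <- cpx_msa(rows2)
  expect_identical(nrow(remove_redundant(cpx2)$rows), 3L)        # distinct bytes
  red99 <- remove_redundant(cpx2, max_id = 0.99)
  expect_identical(nrow(red99$rows), 2L)
  expect_identical(red99$rows$accession_A, c("qryA", "a1"))
  # the query pair survives even when identical to a hit row
  rows3 <- rbind(qp(), prow("a1", "b1", strrep("A", 8), strrep("C", 6), "genomic"))
  expect_identical(remove_redundant(cpx_msa(rows3))$rows$accession_A, "qryA")
})
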