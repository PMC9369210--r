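Package: pairmsa
Title: Paired Multiple Sequence Alignments for Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds paired ("complex") multiple sequence alignments for
    two-chain protein complexes by joining the rows of two monomer
    alignments with three complementary strategies: genomic distance
    (gene-neighbourhood / operon co-membership), per-species phylogeny
    rank matching, and interaction-network links. A cascade escalates
    through the strategies until the alignment reaches a target number
    of effective sequences, computed with a harmonic-mean two-chain
    identity weighting. Includes A3M/aln input and output, redundancy
    removal, top-k inter-chain contact precision evaluation, and a
    synthetic family generator with planted ground-truth pairings for
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
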