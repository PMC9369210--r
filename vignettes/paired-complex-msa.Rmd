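---
title: "Building paired complex MSAs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building paired complex MSAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairmsa)
```

## The problem

Inter-protein contact prediction from sequence coevolution requires a paired
alignment: each row concatenates one homolog of chain A with the homolog of
chain B that it putatively forms the same complex with. The pairing is the
modelling step — concatenating the wrong partners destroys the inter-chain
covariation signal. pairmsa implements three pairing strategies and a
depth-driven cascade over them.

### Stage 1 — genomic distance

Interacting prokaryotic proteins are frequently encoded in the same operon,
i.e. adjacently on the genome. Hits of both chains are mapped to
(genome, gene-order rank); a candidate pair is two hits on the *same* genome
whose rank difference Δgene satisfies `min_d ≤ Δgene ≤ max_d` (defaults 1
and 20, in units of genes, not base pairs). Δgene = 0 would mean the same
gene and is excluded by the lower bound.

A hit can satisfy the window for several partners, so a one-to-one matching
must be chosen. The obvious greedy rule — take candidates in order of
ascending Δgene — is *not* optimal even on tiny instances: with A-hits at
ranks {9, 10} and B-hits at {11, 30}, greedy takes (10, 11) with Δgene = 1
and strands both remaining hits (|9−30| = 21 is out of window), whereas the
two-pair matching {(9, 11), (10, 30)} exists. We therefore resolve each
conflict component *exactly*: maximise the number of pairs, then minimise
total Δgene, then prefer the candidate earliest in the deterministic sort
order (ascending Δgene, descending mean identity to the query, lexicographic
accessions). Components are found on the graph whose vertices are hits and
whose edges are candidates; exhaustive branch-and-bound is used up to 16
edges per component (worst case 2^16 subsets, instantaneous), beyond which
the sorted-order greedy rule takes over — in real data conflict components
are operon-sized and far below that bound. `method = "greedy"` selects the
pure greedy behaviour throughout if wanted.

### Stage 2 — phylogeny rank matching

Within each species present in both MSAs, hits are sorted by identity to
their query from high to low and rank *i* of chain A is joined to rank *i*
of chain B for *i* ≤ min(m, n). The assumption is that orthologs — rather
than diverged paralogs — occupy the same similarity rank in both families.
Similarity here is query identity; e-value (ascending, when present) and
then accession break ties, so the ranking is total and the output is a
function of the input regardless of row order.

### Stage 3 — interaction-network links

Hits are mapped to interaction-network protein ids; a candidate pair is two
hits whose ids share a link with combined score ≥ `min_score` (0–1000
scale; default 0 because no published cutoff accompanies the method — raise
it to, say, 700 for high-confidence links). The matching maximises total
combined score with the same exactness/tie machinery as stage 1.

## The effective-sequence statistic

Alignment depth is measured on the paired alignment as

$$N_{ecs} = \frac{1}{\sqrt{L}} \sum_{i=1}^{N} \frac{1}{1 + \sum_{j \ne i}
\delta(S_{i,j} \ge 0.8)}, \qquad
S_{i,j} = \frac{2}{1/S^A_{i,j} + 1/S^B_{i,j}},$$

with $L$ the summed chain length, $S^A_{i,j}$, $S^B_{i,j}$ the per-chain
pairwise identities of rows $i$ and $j$, and the harmonic mean ensuring two
rows only count as mutually redundant when *both* chains are similar. Each
row's weight is one over one plus its neighbour count; duplicated rows share
their weight, so exact copies collapse to one effective sequence.

Numerical and boundary choices, each surfaced as an argument:

* **Scaling.** `1/sqrt(L)` by default — the convention of the monomer
  effective-sequence (Nf) measures this statistic generalises — with `1/L`
  available (`scaling = "inv_L"`). Any depth requirement must be quoted
  together with the scaling used.
* **The boundary `S = 0.8`** counts as a neighbour (the indicator is
  `S ≥ threshold`).
* **The query pair is a row** and counts toward `N`
  (`include_query = FALSE` excludes it).
* **Identity denominator.** `both_ungapped` (identical residues over
  columns where both rows carry residues) by default; `full_length`
  (divide by the alignment length) by option. `X` never matches anything,
  and a column gapped in both rows counts in neither numerator nor
  denominator. A row with no overlapping residues has identity 0; a pair
  with either chain identity 0 has `S = 0` (the continuous limit of the
  harmonic mean).

## The cascade

Stage 1's alignment (query pair always included, emitted by the cascade
itself rather than any stage) is scored first; if its depth reaches
`necs_threshold` it is used as-is. Otherwise stage 2's pairs are merged in
and the depth recomputed; if still short, stage 3's pairs are added and the
three-stage merge is returned regardless — there is no further fallback.
Merging deduplicates on the concatenated sequence *and* on the accession
pair, keeping the earliest stage's copy, so provenance always names the
first strategy that found a row. `mode = "nrows"` judges depth by raw row
count instead, for users who read "number of sequences" literally.

`necs_threshold` defaults to 128 (with `1/sqrt(L)` scaling): the published
depth requirements in the monomer-alignment lineage this cascade extends
use that order of magnitude, and no value is published for the paired case;
it is a tunable requirement, not a constant, and every report records it.
Redundancy removal then drops exact duplicate rows; `max_id < 1`
additionally removes rows whose harmonic-mean two-chain identity to an
already-kept row reaches `max_id`. The query pair is never removed.

Degenerate inputs are data, not errors: hits missing a stage's annotation
are skipped (counted in the log), stages may be empty, and when all three
are, the result is a query-only alignment flagged as such in the report.

## The synthetic generator

`generate_family()` plants ground truth so every stage is testable offline:
two random query sequences (defaults `L_A = 60`, `L_B = 50`, realistic
small-domain lengths) are mutated once per planted pair at
`substitution_rate` (default 0.2; each position independently replaced by a
different residue). Each planted pair sits on its own genome at a gene-rank
offset drawn uniformly from 1–20; paralog blocks on one genome are spaced
three windows apart so the planted partner is the unique in-window
candidate; every pair shares a species and carries an interaction link
scored 600–999. Orphan rows (a fraction `orphan_fraction` per chain) are
the decoys: placed on real genomes but far outside every window, given a
species seen on one side only and an unlinked network id, they must appear
in no stage's output. Defaults are 10 species, one genome per species, one
pair per genome — small enough that every brute-force oracle in the test
suite runs in seconds, large enough that each stage has real work to do.

What the generator deliberately does **not** emulate: insertions and
deletions (rows are match-state-only so identity arithmetic is exact; gap
handling is exercised by dedicated alignment-level tests instead),
tree-structured evolution (mutations are i.i.d., so there is no
phylogenetic correlation between species), horizontal transfer, chimeric
genomes, and many-to-many interaction ambiguity beyond what
`paralogs_per_genome > 1` introduces. Passing the planted-recovery tests
therefore demonstrates the *bookkeeping and matching logic* is right, not
that the biological heuristics succeed on real proteomes — on real data the
three stages genuinely disagree, which is exactly why the cascade and the
depth statistic exist. Note also that with several planted pairs per
species, per-species rank matching is only guaranteed to recover the truth
when the similarity ranking happens to align across chains; the recovery
guarantee is stated for one pair per species.

## Evaluation utilities

`topk_precision()` ranks the `L_A × L_B` inter-chain score cells by
descending score (ties by ascending position, so tied inputs still give a
deterministic answer) and reports the fraction of true contacts among the
top `k`; `resolve_k()` turns the customary `L/k` counts into integers
(floor, never below 1). Contact truth maps are *inputs* — no distance
cutoff or atom convention is imposed here. `relative_improvement()` is the
percentage arithmetic `100·(a−b)/b`, rounded to one decimal as customarily
reported; the shipped `benchmark_precisions()` table provides published
per-strategy precisions to apply it to.

## Problem sizes used by the test suite

The suite's oracle checks use 200 random paired alignments of up to 50 rows
and summed length up to 200 for the effective-sequence brute force
(tolerance 1e-12), full matching enumeration on instances of at most 6
candidate edges (and random 2–5 × 2–5 hit layouts), and planted families of
10 species — sizes at which exhaustive enumeration is exact and the whole
suite completes in well under a minute per file.

## Known limitations

* Exact matching falls back to sorted-order greedy above 16 candidate edges
  per conflict component; pathological mega-components would be resolved
  greedily (and deterministically), not optimally.
* Identity computations are O(N²·L) in pure R; alignments of tens of
  thousands of rows will feel it. The statistic's double loop is the
  defining computation, so this is a constant-factor, not asymptotic,
  concern.
* A3M support covers the common dialect (lowercase insertions, `.`
  padding, optional leading `#` lines); Stockholm is out of scope.
* The cascade trusts its annotation tables; it does not verify that a gene
  index really is an ordinal rank or that network ids come from the same
  database release as the links file.
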