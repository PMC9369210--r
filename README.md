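# pairmsa

Coevolution analysis of a protein **complex** needs a *paired* multiple
sequence alignment (MSA): each row concatenates a homolog of chain A with
the homolog of chain B it plausibly interacts with, so that inter-chain
covariation becomes visible to contact predictors and direct-coupling
analysis. Building that pairing is the hard part — a homology search returns
two independent monomer MSAs, and nothing in them says which A-row belongs
with which B-row.

pairmsa is for structural bioinformaticians who already have two monomer
alignments (A3M / aligned FASTA, e.g. from HHblits) plus ordinary annotation
tables, and need a deep, non-redundant paired alignment. It joins the two
MSAs with three complementary strategies, applied as a cascade:

1. **Genomic distance** — hits on the same genome whose gene-order ranks
   differ by Δgene with 1 ≤ Δgene ≤ 20 (operon neighbourhoods; conflicts are
   resolved by a one-to-one matching minimising total Δgene).
2. **Phylogeny rank matching** — within each species, the i-th most
   query-similar A-hit is joined to the i-th most query-similar B-hit,
   for i ≤ min(m, n).
3. **Interaction-network links** — hits whose network ids share a link with
   sufficient combined score (0–1000), matched to maximise total score.

The cascade stops as soon as the alignment is deep enough, measured by the
effective number of sequences of the paired alignment

```
Necs = (1/√L) · Σ_i  1 / (1 + Σ_{j≠i} δ(S_ij ≥ 0.8)),
S_ij = 2 / (1/S_ij^A + 1/S_ij^B),
```

where L is the summed chain length and S_ij^A, S_ij^B are the per-chain
pairwise identities — the harmonic mean makes two rows "redundant" only when
*both* chains are ≥ 80 % identical. Stage 1 is tried first; phylogeny pairs
are merged in only if Necs falls short, then network pairs, after which
exact-duplicate (optionally near-identical) rows are removed.

Also included: top-k / top-L/k inter-chain contact precision, the
relative-improvement arithmetic used to compare alignment strategies on
published benchmarks, and a synthetic family generator that plants
ground-truth pairings so the entire pipeline is testable offline.

## Worked example

```r
library(pairmsa)

# a synthetic family: 10 planted pairs plus 30% orphan decoy rows
fam <- generate_family(seed = 42, n_species = 10, orphan_fraction = 0.3)
fam
#> Synthetic two-chain family: 10 planted pair(s), 13 + 13 hit rows, seed 42

res <- select_cpxmsa(fam$msaA, fam$msaB, fam$bundle, necs_threshold = 128)
res$report
#> Cascade report (mode = necs, required depth = 128, scaling = inv_sqrt_L)
#>   stages 1     :   11 rows, depth 0.7818
#>   stages 1+2   :   11 rows, depth 0.7818
#>   stages 1+2+3 :   11 rows, depth 0.7818
#>   chosen: stages {1,2,3}; 30 duplicate row(s) removed
res$cpx
#> Paired complex MSA: 11 row(s) (incl. query pair), L_A = 60, L_B = 50, L = 110
#>   rows by stage: genomic=10, query=1
compute_necs(res$cpx)
#> Effective sequences: Necs = 0.7818  (N = 11, L = 110, threshold = 0.80, scaling = inv_sqrt_L)
```

Reading the output: all 10 planted pairs are found by the genomic stage
(they keep the earliest stage's provenance when later stages re-find them —
hence 30 duplicates removed), the 6 orphan rows pair with nothing, and the
alignment's depth is Necs ≈ 0.78 — every row counts almost fully because at
a 20 % substitution rate most row pairs sit below the 80 % similarity
threshold. A desk-sized family can never reach the default production
requirement of 128, so the cascade runs through all three stages, as the
report shows step by step.

The same pipeline is scriptable from a shell via `inst/scripts/pairmsa`
(subcommands `simulate`, `pair`, `necs`, `eval`); every `pair` run writes
`complex.a3m`, `complex.aln`, a JSON cascade report and the effective
configuration.

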