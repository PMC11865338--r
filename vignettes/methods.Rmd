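---
title: "Methods: multi-rank weighted disturbance similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-rank weighted disturbance similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model the package implements,
the choices made where the method leaves details open, what the
synthetic generator does and does not emulate, and the package's known
limitations.

## The evidence model

The unit of input is one documented disturbance: source, entity (a
dietary fiber or disease), microbe, the taxonomic rank it was reported
at, and a direction (increase/decrease of relative abundance against a
healthy or habitual-diet baseline). Three assumptions are built in:

* **Evidence rows are exchangeable counts.** Two reports of the same
  change weigh twice as much as one; no study-size or quality
  weighting is attempted. Exact duplicate rows are collapsed once; a
  source reporting both a genus and, separately, its phylum is counted
  at the phylum twice (once directly, once by propagation). We keep
  both because the row — not the source — is the evidence unit;
  deduplicating by source would silently discount papers that made
  genuinely separate observations.
* **Propagation is upward only.** A genus report implies a
  disturbance of its family through phylum, never of its species.
  Microbes lacking a lineage entry at some rank simply contribute
  nothing there; microbes absent from the taxonomy altogether stay at
  their reported rank (logged). This mirrors how amplicon and
  metagenomic assays resolve taxa at heterogeneous depths.
* **Direction conflicts cancel.** The per-(entity, taxon, rank)
  direction is the sign of `c_inc − c_dec` and the count its absolute
  value. The strength model defines a direction α and a count C but
  not their behavior under mixed reports; net signed counting uses all
  rows, reduces to the plain definition when reports are unanimous,
  and makes a perfect tie exactly zero — the conservative reading. A
  tied record still counts toward the taxon's document frequency n.

## Strength, similarity, aggregation

Per rank, strength is `D = α · C · ln(N/n)` with N the entities at the
rank and n the entities associated with the taxon. Consequences worth
knowing: a taxon associated with *every* entity has strength 0 for
all of them (ln 1 = 0), so fully saturated ranks — common at phylum
level, where only a handful of phyla exist — often contribute nothing.
This is intended: ubiquitous taxa carry no discriminative information.

Per-rank similarity is the cosine of the two strength vectors. Its
significance is assessed by treating the cosine like a correlation
coefficient: `t = SIM·sqrt(df/(1−SIM²))` with `df = m_shared − 2`,
where `m_shared` counts taxa in the union support of the pair. The
deviation `σ = SIM/t = sqrt((1−SIM²)/df)` is finite and positive for
all |SIM| < 1 including SIM = 0, which keeps the weight `W = 1/σ`
defined everywhere. Choices made here:

* **W = 1/σ, not 1/σ².** The aggregation weight is literally the
  inverse deviation. An inverse-variance convention would change the
  relative rank weights; we follow the printed form of the method.
* **Clamp at |SIM| ≤ 1 − 10⁻¹².** Identical (or exactly opposed)
  vectors would otherwise get infinite t and weight; the clamp caps a
  single rank's weight at about 10⁶·sqrt(df) instead of letting one
  degenerate rank dominate the aggregate with ∞.
* **Non-contributing ranks.** A rank with an all-zero vector on
  either side, or with fewer than 3 support taxa (df < 1), is dropped
  from both the numerator and denominator of the weighted mean. A pair
  with no contributing rank has undefined similarity and never enters
  a network — reported as NA, not as 0.
* **Degrees of freedom for the aggregate p-value.** The method calls
  for a two-tailed Student-t p on `t = SIM/σ̄` without stating df; we
  use the sum of the contributing ranks' support sizes minus 2, and
  expose it in the output (`df` column) so users can judge the
  reference distribution themselves. Because propagated ranks reuse
  the same underlying evidence, these df overstate the effective
  sample size; p-values should be read as a ranking device feeding the
  FDR step rather than literal error rates.
* **FDR family.** One Benjamini–Hochberg family per run (per network
  mode), over all defined non-self pairs. Pooling all three modes into
  one family would couple unrelated analyses run at different times.
* **Cross-set alignment.** Comparing a fiber database against a
  disease database, each side is quantified with its own N and n (IDF
  within its own database — the two databases differ vastly in size,
  and a shared IDF would let the larger one set the weights), then
  vectors are aligned on the union of the two taxon universes with
  zero fill. Union keeps taxa documented on only one side as genuine
  disagreement; an `align = "intersection"` switch exists for
  sensitivity analysis.

## Networks and loop coherency

The loop census runs on the *unfiltered* network of all defined pairs:
coherency is a property of the global sign pattern, and an FDR-filtered
network is far too sparse to host a meaningful triangle census. A
triangle is coherent iff the product of its three edge signs is
positive — the structural-balance rule, which reproduces the two
canonical cases (all-positive coherent, all-negative incoherent) and
fixes the mixed-sign cases by the same algebra. Counts come from trace
identities on the signed adjacency matrix (`tr(|S|³)/6` triples,
`tr(S³)/6` their sign excess); the test suite checks them against a
brute-force triple scan on graphs up to 12 nodes.

The permutation null shuffles, independently per iteration and per
rank, each entity's strength vector across the taxon axis — the most
literal randomization of "which taxa carry this entity's
disturbances" that preserves each entity's strength multiset (and so
its vector norm). A `null = "global"` variant shuffles all cells of a
rank matrix instead, destroying row marginals too. Iterations with no
incoherent loop have an undefined ratio; they are excluded from the
null median and counted in `n_undefined` rather than mapped to an
arbitrary large value.

## Body-site scores

Scores are computed per body site because the same disease disturbs
different sites to very different degrees. Within a site, strengths
are re-quantified site-locally: N is the number of diseases documented
at the site and n the diseases at the site associated with the taxon.
Sites with a single disease are dropped (N = 1 makes ln(N/n) ≡ 0 and a
score of 0 for everything — uninformative, and the site cannot anchor
a comparison). Strengths are squashed to (−1, 1) by
`2/(1+e^(−D)) − 1`, identically `tanh(D/2)`, and the score is the
Euclidean norm across all six ranks' cells. Propagation deliberately
lets one documented disturbance contribute at every rank its lineage
reaches — the score measures the breadth and strength of the
disturbance footprint, not a deduplicated taxon count. Direction is
lost in the norm; the signed per-cell table (`site_dhat_table`)
retains it.

## Clustering and matrix comparison

Distance is `1 − SIM` (range [0, 2]), complete linkage, k-cut. The
method names only the linkage; we prefer `1 − SIM` over
`sqrt(2(1−SIM))` because it is affine in the similarity and keeps
merge heights interpretable as dissimilarity; the choice does not
affect complete-linkage merge order (it is a monotone transform).
`k` defaults to 6 in the fiber workflow, matching the six functional
subgroups the reference analysis reports; disease-scale runs typically
consume the dendrogram directly. Cluster labels C1..Ck order by size
with name ties broken alphabetically, so labelings are reproducible.
Matrix comparison (e.g., microbiota-based vs etiology-based disease
similarity) is the Pearson correlation over upper-triangle pairs
defined in both matrices, with optional per-category subsetting.

## The synthetic generator

The generator emulates the statistical skeleton of a curated evidence
database: entities in latent blocks, each block holding a ±1 direction
profile over genera; per-entity evidence rows sampled at genus rank
with a within-block agreement probability, a between-block profile
agreement, a per-row conflict (sign-flip) rate, and 1–3 rows per
(entity, genus) pair; a random but internally consistent six-rank
taxonomy above the genera. Profiles are planted at genus rank
specifically so every downstream analysis exercises the same
upward-propagation path as real data.

Defaults are set to a fiber-database-scale study: 32 entities, 6
blocks, 40 genera, 15 active genera per entity, within-block agreement
0.9, between-block 0.5, conflict rate 0.1. The agreement and conflict
levels are not printed anywhere in the reference analysis; they were
chosen once as "blocky but noisy" — strong enough that block structure
is real, noisy enough that nothing is deterministic — and are not
tuned thereafter. Sparsity (15/40) matters structurally: in a dense
table every taxon is associated with every entity and the IDF term
annihilates all strengths; real curated databases are sparse in
exactly this sense.

What the generator does **not** emulate: the heavy-tailed taxon
frequency spectrum of real databases (a few taxa dominate curated
evidence), heterogeneous ranks of reporting (all synthetic evidence is
genus-level), correlated missingness by body site, and
curation-induced name noise. Passing the recovery tests therefore
shows the pipeline is algebraically and statistically sound on planted
structure, not that real databases contain such structure.

## Problem sizes and runtime choices

The test suite runs small: oracle-equivalence on 200 random instances
of ≤ 6 entities × ≤ 10 taxa × 3 ranks against an independently coded
scalar re-derivation (tolerance 10⁻¹⁰); loop censuses cross-checked by
brute force up to 12 nodes; block-separation checks across 100 seeds
at 6 entities; the permutation null exercised at 200 iterations on 20
entities (production default is 10,000 iterations, a pure scale-up of
the same code path). The acceptance script runs the full pipeline at
32 entities.

## Known limitations

* P-values inherit the df overstatement discussed above and the
  non-independence of propagated ranks; the FDR step controls ordering
  within a run, not a literal false-discovery proportion.
* Name matching is exact after case/whitespace normalization; synonym
  resolution and fuzzy matching belong upstream in curation.
* The loop census assumes an undirected signed simple graph; zero
  similarities are treated as missing edges, not as a third state.
* Cross-site score aggregation is deliberately absent: scores at
  different sites are computed under different site-local IDFs and are
  not commensurable.
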