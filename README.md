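# bhwa

Signed similarity networks between dietary fibers and diseases, built
from multi-rank microbiota disturbance evidence.

## The problem

Intervention and case–control studies report directional changes in
microbial relative abundance — "inulin increases *Bifidobacterium*",
"Crohn's disease decreases *Faecalibacterium prausnitzii*" — at
whatever taxonomic rank the assay resolved, from species up to phylum.
Two entities (two fibers, two diseases, or a fiber and a disease) that
disturb the microbiota in the same way are plausibly linked: similar
fibers are functional substitutes, similar diseases share microbial
risk factors, and a fiber whose disturbance profile opposes a
disease's is a candidate dietary intervention. Comparing entities at a
single rank wastes most of the evidence; this package implements the
Bio-taxonomic Hierarchy Weighted Aggregation (BHWA) scheme, which uses
all six ranks at once.

## The model

Evidence is first propagated upward through a user-supplied taxonomy:
a genus-level record also counts at family, order, class and phylum
(never downward). At each rank *S*, the disturbance strength of taxon
*m* for entity *i* is

> D<sub>m,i</sub><sup>S</sup> = α<sub>m,i</sub><sup>S</sup> · C<sub>m,i</sub><sup>S</sup> · ln(N<sup>S</sup>/n<sub>m</sub><sup>S</sup>)

where α ∈ {−1, 0, +1} is the net direction of change, C the net
evidence count (increase and decrease reports cancel), N the number of
entities at the rank and n<sub>m</sub> the number of entities
associated with taxon m — an IDF factor that silences taxa associated
with everything. Entities are compared per rank by the cosine
SIM<sup>S</sup> of their strength vectors; each rank receives weight
W<sup>S</sup> = 1/σ<sup>S</sup> with σ<sup>S</sup> = SIM<sup>S</sup>/t<sup>S</sup> =
√((1 − SIM²)/df), df = (taxa in the pair's support) − 2. The ranks are
combined as

> SIM<sub>i,j</sub> = Σ<sub>S</sub> W<sup>S</sup> SIM<sup>S</sup> / Σ<sub>S</sub> W<sup>S</sup>,  σ̄ = √(1/Σ<sub>S</sub> W<sup>S</sup>)

with a two-tailed Student-t p-value on t = SIM/σ̄ and
Benjamini–Hochberg FDR control across all pairs of a run.

On top of the similarities the package builds signed networks
(edges with FDR < 0.05, or unfiltered), counts three-node loops and
classifies them by the structural-balance rule (coherent iff the
product of the three edge signs is positive) against a within-entity
permutation null; computes body-site-specific disturbance scores
DS<sub>i</sub> = √(Σ<sub>ranks</sub> Σ<sub>m</sub> D̂²) with
D̂ = 2/(1+e<sup>−D</sup>) − 1 = tanh(D/2); and clusters entities by
complete linkage on 1 − SIM.

## Worked example

A synthetic fiber database (32 fibers in 6 planted blocks, genus-level
evidence over a random six-rank taxonomy) exercises the whole
pipeline:

```r
library(bhwa)
syn  <- generate_synthetic_data(synth_config(seed = 42))
ev   <- filter_min_disturbance(syn$evidence, threshold = 3)
cts  <- propagate_up(ev, syn$taxonomy)
cts
#> multi-rank evidence: 32 entities
#>   species     0 taxa,     0 (entity, taxon) records
#>   genus      40 taxa,   480 (entity, taxon) records
#>   family     12 taxa,   274 (entity, taxon) records
#>   order       7 taxa,   185 (entity, taxon) records
#>   class       3 taxa,    86 (entity, taxon) records
#>   phylum      2 taxa,    55 (entity, taxon) records

sims <- pairwise_similarity(cts)
head(as.data.frame(sims)[, c("entity_i", "entity_j", "sim_genus",
                             "sim_weighted", "p", "fdr")], 3)
#>   entity_i entity_j  sim_genus sim_weighted          p       fdr
#> 1  Fiber01  Fiber02  0.1179035    0.5359530 0.07136973 0.9997901
#> 2  Fiber01  Fiber03  0.1111776    0.4597922 0.11802602 0.9997901
#> 3  Fiber02  Fiber03 -0.2692081    0.3719864 0.17445654 0.9997901

full <- build_network(sims)            # unfiltered, for the loop census
loop_census(full)
#> three-node loops: 4960 of 4960 possible; 2840 coherent / 2120 incoherent (ratio 1.340)

randomization_test(cts, iterations = 200, seed = 7)
#> coherency randomization: observed ratio 1.340, null median 1.182
#> (200 iterations, 0 undefined), fold 1.13, empirical p 0.0000

ca <- cluster_entities(similarity_matrix(sims), k = 6)
table(ca$labels)
#> C1 C2 C3 C4 C5 C6
#>  9  8  5  5  3  2
```

The weighted similarity for Fiber01/Fiber02 (0.54) is larger than its
genus-level cosine (0.12) because higher ranks, where the two fibers'
propagated profiles agree more strongly, contribute with their own
inverse-deviation weights. The observed coherent-to-incoherent loop
ratio (1.34) exceeds the permutation-null median (1.18): even at this
noise level, planted block structure leaves the network more balanced
than chance. The six recovered clusters correspond to the generator's
planted blocks.

`exec/bhwa` exposes the same pipeline as subcommands
(`simulate`, `similarity`, `network`, `loops`, `ds`, `cluster`,
`compare`), each writing TSV/JSON results plus a `provenance.json`
with the full configuration and seed.

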