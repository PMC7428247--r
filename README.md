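# beemir

Comparative analysis of brain-expressed microRNAs across bee species.

Bees span the full range of social organization, from solitary foragers to
complex eusocial colonies, and lineage-specific gene regulation is a leading
candidate for what changes when sociality evolves. `beemir` re-implements a
comparative miRNA analysis for this setting as a tested, reusable R
pipeline:

* **Discovery filters** — small-RNA read QC (length ≥ 18, standard bases),
  exact-match genome mapping, mature/star arm support counting (≥ 5 reads
  each), an rRNA/tRNA contaminant screen, and a randfold-style secondary
  structure permutation test (dinucleotide-preserving shuffles of a
  weighted Nussinov fold; retain candidates with p < 0.05).
* **Homology classification** — expressed miRNAs are grouped by exact seed
  identity (mature positions 2–8) into three tiers: *seed match* (seed
  shared with another species or a known insect miRNA), *pre-miR homolog*
  (no seed twin, but a local-alignment hit of the precursor in another
  genome at ≥ 50% identity and Karlin–Altschul E ≤ 1e−5), and *unique*.
  Lineage-specific = expressed in one species with no seed match.
* **Localization** — strand-aware interval intersection of precursor loci
  with gene models and repeats (intergenic / exon / intron / transposable
  element / uncharacterized repeat), with both-strand double counting and
  the intragenic-vs-lineage-specific chi-squared test.
* **Target prediction** — 500 bp downstream flanks as 3′-UTR proxies,
  strict seed sites, one duplex pairing scored under an alignment score
  (≥ 140) and a duplex energy (≤ −20) with a permutation p < 0.01; gene
  pairs deduplicated.
* **Gene age** — orthogroup taxonomic breadth over the clade ladder
  Vertebrata → … → Apoidea, "Unique" for genes without orthologues.
* **Enrichment** — hypergeometric over/under-representation with the
  representation factor RF = x/E, E = nD/N, BH correction, reciprocal-
  best-hit orthologue mapping, and Welch t-tests of lineage-specific vs
  homologous miRNA expression on log2(RPM+1).
* **Phylogenetic statistics** — miRNA copy-number vs sociality via
  Felsenstein's independent contrasts and Spearman correlation (exact
  permutation p for ≤ 9 contrasts), BH-corrected across accessions.
* **Synthetic worlds** — `generate_world()` builds multi-species genomes
  with planted shared seed families, lineage-specific miRNAs at 0.25×
  expression, context-stratified precursor placement, and target sites
  enriched downstream of young genes at a planted representation factor,
  together with a truth manifest, so every stage is scored against known
  ground truth.

## Worked example

```r
library(beemir)

world <- generate_world(world_config(rng_seed = 1))
res   <- run_pipeline(world)

res$summary
#>   species_id total seed_match premir unique lineage_specific
#> 1       sp01    72         49     11     12               23
#> 2       sp02    61         39     10     12               22
#> 3       sp03    76         50     12     14               26
#> 4       sp04    71         45     13     13               26
#> 5       sp05    66         44     12     10               22
#> 6       sp06    65         43     10     12               22

rec <- evaluate_recovery(res, world)
round(rec$rf_estimated, 2)
#> sp01 sp02 sp03 sp04 sp05 sp06
#> 1.56 2.21 1.84 1.86 1.97 1.78
round(rec$rf_realized, 2)
#> sp01 sp02 sp03 sp04 sp05 sp06
#> 1.56 2.12 1.93 1.87 1.95 1.46
c(sensitivity = rec$sensitivity, specificity = rec$specificity)
#> sensitivity specificity
#>           1           1
```

Reading the output: each species expresses 61–76 miRNAs after the
discovery filters; most fall into cross-species seed groups (`seed_match`),
while `premir` and `unique` miRNAs expressed in only that species are the
lineage-specific set. The planted enrichment of lineage-specific targets
among young genes (representation factor ≈ 1.5–2.1 as realized per
species) is recovered closely by the prediction + enrichment stages, and
every planted lineage-specific miRNA that survives
the read-support filters is classified correctly (sensitivity and
specificity 1.0 on this world).

A thin command-line wrapper is included for the two shell-level entry
points:

```sh
Rscript inst/cli/beemir.R simulate --out world_dir --seed 7
Rscript inst/cli/beemir.R pipeline --seed 7 --out results.json
```

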