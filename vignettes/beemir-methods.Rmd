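---
title: "Methods: comparative brain miRNA analysis across bee species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative brain miRNA analysis across bee species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemir)
```

## The scientific problem

Eusociality evolved repeatedly in bees, and lineage-specific changes in gene
regulation are a candidate substrate for that evolution. MicroRNAs (miRNAs)
— ~21–22 nt non-coding RNAs that repress mRNAs through 3′-UTR binding — are
a plausible source of regulatory novelty: new miRNAs arise easily from
hairpin-forming loci, are often expressed at low levels, and either
integrate into gene networks or are purged. `beemir` implements a
comparative analysis of brain-expressed miRNAs across bee species that vary
in social organization, asking:

1. Which expressed miRNAs are shared across species (by seed identity),
   which have only a genomic precursor homologue elsewhere, and which are
   unique to one lineage?
2. Where do precursor loci sit in each genome (intergenic, intronic,
   exonic, repeat-derived), and do lineage-specific miRNAs localize
   differently?
3. Do the predicted targets of lineage-specific miRNAs preferentially fall
   on evolutionarily young ("Unique") genes, quantified by a representation
   factor and hypergeometric tests?
4. Is miRNA copy number across genomes associated with sociality once
   phylogeny is removed via independent contrasts?

The package is exercised end-to-end on synthetic multi-species data with
planted ground truth, so every stage has a measurable recovery target.

## Discovery filters

Candidate hairpin loci (inputs, as in small-RNA discovery pipelines whose
precursor-excision step is out of scope here) are gated by the classic
novel-miRNA criteria:

* **Read QC** — reads shorter than 18 nt or containing non-standard bases
  are dropped; counts are preserved.
* **Exact mapping** — reads are matched exactly (both strands) against the
  genome; the mapper indexes 11-mer read prefixes and verifies full-length
  matches in a single genome pass, which is an acceleration of exact
  matching, not a change of definition. A mismatch budget is deliberately
  not applied: synthetic reads are error-free, and exactness keeps support
  counts deterministic.
* **Arm support** — read stacks inside a hairpin locus define the mature
  arm (highest-count stack) and star arm (highest non-overlapping stack);
  a candidate needs ≥ 5 reads on *each* arm, counted with a ±2 nt slop at
  arm ends (read-stacking tolerance, configurable).
* **Contaminant screen** — local alignment against rRNA/tRNA sequences;
  a hit is ≥ 80% identity over ≥ 20 columns (configurable; this
  approximates the usual rRNA/tRNA exclusion whose exact configuration is
  rarely reported).
* **Secondary structure** — a randfold-style permutation test (below) with
  p < 0.05, strictly.

### Folding engine and the structure test

Thermodynamically parameterized folding is not required for the structure
test: the decision only needs a consistent stability ordering between a
sequence and its shuffles. We therefore use a weighted Nussinov dynamic
program — maximize total pair weight with GC = 3, AU = 2, GU = 1, nested
structures only, minimum hairpin loop of 3 unpaired bases — and report the
negated weight as an energy score in arbitrary units. Traceback is
deterministic (leftmost pairing partner preferred), so results are
reproducible bit-for-bit.

The permutation test compares the native energy against
dinucleotide-preserving shuffles (Altschul–Erickson Eulerian-path method,
which conserves the exact dinucleotide count vector). The p-value uses the
add-one formula `p = (1 + #(E_shuffle below E_native)) / (n + 1)`, so p is
never zero and the test is valid at finite n. Because the energies are
integers, exact ties between the native energy and shuffle energies are
frequent (~20% of draws for a 120-nt sequence); counting every tie against
the native sequence makes the p-value noticeably conservative, so by
default the native sequence's rank within its tie block is drawn uniformly
at random — the standard randomized permutation p, exactly uniform under
the null — with the all-ties-count variant available as
`tie_break = "conservative"`. The same mechanism is used by the
target-site permutation test. The function default is 999 shuffles; the
pipeline uses 99 (resolution 0.01 against the 0.05 threshold), which keeps
20-replicate world studies tractable without changing any decision in
practice.

## Homology classification

The seed — mature positions 2–8, a 7-mer, the miRBase/miRDeep2 convention
(2–7 is available via `seed_end`) — determines homology grouping: two
miRNAs are homologous iff their seeds are identical strings (the strictest
reading of "matching seed sequences"; no 1-nt tolerance). Tiers are
assigned with priority **seed match > precursor homolog > unique**:

* *seed match* — the seed group spans ≥ 2 species or matches a known
  insect mature miRNA;
* *precursor homolog* — no seed twin, but the precursor has a significant
  local-alignment hit in another genome;
* *unique* — neither.

A miRNA is **lineage-specific** iff it is expressed in exactly one species
and is not a seed match. Genomic similarity of the precursor elsewhere does
not disqualify it: sequence presence is not evidence of transcription.

The genomic homology search emulates a blastn run (`-perc_identity 50
-evalue 1e-5`) with an affine-gap Smith–Waterman (+2/−3, gap open 5,
extend 2) seeded by exact 11-mer words, and converts scores to E-values
with Karlin–Altschul statistics: λ is the exact root of
Σ pᵢpⱼe^{λsᵢⱼ} = 1 (bisection to 1e−12), and K is fitted once per scoring
system from simulated maximal ungapped segment scores via the extreme-value
relation P(M < s) = exp(−K·m·n·e^{−λs}), using a fixed internal RNG stream
so the constant is deterministic. Applying ungapped statistics to gapped
scores is the same documented approximation BLAST itself makes with fitted
constants. The search space `n` counts both strands of the subject genome.

## Localization

Precursor loci are intersected with gene models (genes, exons, derived
introns) and repeat annotations under a single coordinate convention —
0-based half-open everywhere, GFF3 converted at the boundary — using a
sorted sweep that is exhaustively checked against brute force. Conventions
follow the usual genome-arithmetic defaults: ≥ 1 bp overlap counts; a locus
contributes one count to every distinct (category, strand-relation) it
touches, so a precursor overlapping genes on both strands is deliberately
double-counted; "intragenic" for the 2×2 test means any gene overlap on
either strand; exon and intron overlaps of the same gene both count
(categories are feature-wise, not exclusive). The lineage-specific vs
intragenic 2×2 test uses Yates-corrected chi-squared (matching R's 2×2
default, toggleable), with a Fisher fallback when an expected cell drops
below 1.

## Target prediction

Each gene's 3′-UTR proxy is the 500 bp immediately downstream of its model
(reverse-complemented for minus-strand genes so it reads 5′→3′ of the
mRNA), clipped at chromosome edges but *not* at neighbouring genes —
flanking tools do not clip either, and the proxy mimics an average
insect 3′ UTR (~440 nt in flies).

A candidate site requires a strict seed: the exact Watson–Crick reverse
complement of the full 7-mer seed, no G:U wobble. One optimal pairing is
then computed by a banded DP extending 3′ of the seed (pairs, symmetric
mismatches, single-nucleotide bulges; band 3) and scored under two linear
models:

* **alignment score** — +5 per WC pair, +1 per G:U, −3 per mismatch, −9
  per bulge opening, with seed-region pairs weighted ×3;
* **duplex energy** — −3 per GC, −2 per AU, −1 per GU, +3 per interior
  loop/bulge opening.

Both are computed from the same pairing, and a site is retained only when
`score >= 140` **and** `energy <= −20` **and** permutation `p < 0.01` —
the intersection structure (two thresholded scores plus a p-value) of
running two independent predictors and keeping the consensus. The seed
weighting is a deliberate design choice: under a flat +5-per-pair model no
mature sequence of ≤ 26 nt can reach a score of 140, so the published
cutoff would be unsatisfiable; weighting the seed ×3 (the same idea as
miRanda's scaling of seed matches) makes 140 the boundary "seed plus
substantial 3′-supplementary pairing" — a seed-only site scores 105 and is
rejected, a perfect 22-nt duplex scores 180 and passes. All constants are
configurable in `target_config()`.

The p-value needs care. The natural-sounding null — best energy over a
shuffled UTR — is 0-inflated (a random 500-mer contains a given seed
complement only ~3% of the time) and produces anti-conservative p-values
because the observed site is conditioned on existing while the null is
not. We therefore condition the null the same way the observation is
conditioned: the seed complement is implanted into flanks drawn without
replacement from the UTR's own letter pool and the duplex is evaluated at
the implanted site. This statistic is exchangeable with a chance site in a
composition-matched UTR, so null p-values are uniform (verified by KS test
in the acceptance suite) and weak sites get p ≈ 1 as they should. Gene
pairs are deduplicated: a gene counts once per miRNA regardless of site
count.

## Gene age and enrichment

Gene ages come from orthogroup taxonomic breadth over the ladder
Vertebrata, Metazoa, Arthropoda, Insecta, Holometabola, Hymenoptera,
Aculeata, Apoidea: walking oldest-first, a gene takes the first label
having an orthogroup member that belongs to that clade but not the next.
Vertebrata sits outside the nested chain (any vertebrate member ⇒
Vertebrata). Genes without orthogroups are "Unique". Orthogroups containing
only focal-clade species take the youngest ladder label (Apoidea), not
Unique — an orthogroup exists, so the gene is not novel; a flag exposes the
alternative. The species→clade mapping is an explicit input table; no
taxonomy services are consulted.

Enrichment uses the representation factor RF = x/E with E = nD/N (x the
overlap of an n-gene list with a D-gene list in an N-gene universe) and
hypergeometric tail p-values computed in log space; both tails are
reported and share the point mass at x, so `p_over + p_under >= 1`.
Benjamini–Hochberg correction is applied within each named battery.
Cross-species list mapping uses reciprocal best hits under the same
alignment machinery with a flat identity scoring for proteins — synthetic
protein sets have uniform residue composition, where a substitution matrix
adds nothing; the matrix is configurable.

Expression of lineage-specific vs homologous miRNAs is compared by Welch's
t-test on log2(RPM + 1) (raw scale available); the transform is our choice —
small-RNA counts are heavy-tailed — and the default is two-sided since the
direction was not prespecified in the test itself.

## Phylogenetic statistics

Copy-number/sociality association uses Felsenstein's independent contrasts
(via `ape::pic`) of both variables on the same rooted binary tree —
sociality is treated as a numeric ordinal 0–3, which inherits the usual
caveat about contrasting ordinal scales — followed by Spearman rank
correlation on the contrast pairs and BH correction across accessions.
For ≤ 9 contrasts the two-sided p is exact by full enumeration of rank
permutations; above that the t-approximation of `cor.test` is used.
Accessions with zero copy-number variance are skipped with a reason (half
of real accessions are constant across genomes and carry no information).
Zero-length branches are replaced by 1e−8 with a warning; polytomies are
an error unless explicitly resolved by zero-length splits.

## The synthetic world

`generate_world()` builds, per species: a uniform-composition genome
(500 kb default) carrying 400 gene models (two exons, one intron, with a
reserved 500 bp downstream flank), 30 repeat intervals, and a miRNA
complement of shared families plus lineage-specific miRNAs; a phylogeny
with ordinal sociality scores; a copy-number matrix; orthogroups inducing
a configurable age distribution; caste-style and selection-style gene
lists with no planted relation; and small-RNA read sets. Everything is a
deterministic function of the configuration, including its seed.

Key planted structure, with defaults chosen to represent realistic
comparative study conditions:

* 60 shared seed families, each carried by a species with probability
  0.85 (at least two species), sharing an identical 7-mer seed but
  differing elsewhere; 70% of family seeds match a "known insect miRNA"
  reference set.
* 30 lineage-specific miRNAs per species (≈ 25–40% of a species'
  complement, a realistic lineage-specific share for
  bee brain complements),
  with globally unique seeds; half are "unique" (no genomic homologue
  anywhere), half get one diverged (~84% identity) unexpressed precursor
  copy planted in another genome.
* Expression: mature counts are negative binomial (dispersion 0.3 —
  overdispersion is the norm for small-RNA counts and stresses the t-test
  stage) with lineage-specific means at 0.25× the shared mean of 200;
  star counts are a binomial thinning (p = 0.2) of mature counts, so the
  ≥ 5-read star filter has realistic failures.
* Placement: intergenic/intron/exon/repeat at 0.45/0.35/0.05/0.15
  (real precursor localization is dominated by intergenic and intronic
  loci; per-category frequencies are approximations exposed in the
  config), with hosted loci sense-biased 0.8 toward their host strand.
* Targets: each species' lineage-specific miRNAs get perfect-complement
  22-nt sites implanted in downstream flanks of a gene set selected so
  that young ("Unique") genes are hit at a representation factor of 1.8
  (a moderate, realistic effect size for young-gene
  targeting); at RF = 1 the selection is a uniform subset — exact
  independence — which is the null used for calibration. The realized RF
  of every draw is recorded in the truth manifest and recovery is judged
  against that realization, not the nominal target.
* Contaminant decoys: two hairpins per species embed a 30-nt rRNA/tRNA
  fragment and receive reads, so the contaminant screen is exercised on
  loci that would otherwise be scored.

What the generator does **not** emulate: realistic genome composition
(isochores, repeat families, paralogues), sequencing error, adapter
artifacts, expression variation across biological replicates, arm
switching, or clustered miRNA transcription. Passing recovery tests
therefore demonstrates that the pipeline's logic is correct and its
statistics calibrated under the stated generative model — not that it
would match a particular empirical dataset.

## Numerical choices and problem sizes

Add-one permutation p-values throughout (never zero); strict inequalities
at the printed thresholds (randfold p < 0.05, target p < 0.01, score ≥
140, energy ≤ −20, ≥ 5 reads per arm); ties in the Nussinov traceback
broken leftmost; E-values use total searched length on both strands;
degenerate inputs (homopolymer precursors, empty contaminant sets, genes
at chromosome edges, constant copy-number rows) return defined results or
warnings rather than errors where the analysis can proceed.

The shipped test and acceptance studies use: 20 default worlds (6 species,
~80 expressed miRNAs each) for recovery; 1 000 null replicates for battery
type-I error; 300 replicates each for the two p-value uniformity checks
(KS); 150 twelve-leaf Brownian worlds for false-discovery control of the
copy-number scan; and 400 replicates for each power mirror (4× expression
deficit detected at p < 0.001 in ≥ 95%; 2× intragenic excess at p < 0.05
in ≥ 90%). These sizes were chosen to give stable Monte-Carlo estimates of
each rate while keeping a complete run comfortably reproducible on one
CPU.

## Known limitations

* The folding engine ranks stability; its energies are not thermodynamic
  and should not be compared across sequence lengths.
* The duplex score/energy constants are a self-contained emulation of the
  two-predictor consensus, not a reimplementation of either predictor;
  absolute score values are only meaningful relative to the configured
  thresholds.
* Exact-match read mapping is appropriate for error-free reads; real data
  would need a mismatch budget (exposed in the config as a future knob).
* Seed-and-extend homology search can in principle miss homologues diverged
  below ~1 exact 11-mer (word size is configurable).
* The gene-age ladder is fixed to the eight-clade hierarchy above plus
  "Unique"; other ladders require only a different mapping table but have
  not been exercised.
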