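Package: beemir
Title: Comparative Analysis of Brain microRNAs Across Bee Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative brain microRNA
    analysis for bees: quality filtering and support counting of small-RNA
    reads, a dinucleotide-shuffle secondary-structure permutation test for
    novel hairpin candidates, cross-species seed-match homology
    classification with a local-alignment genomic homology search under
    Karlin-Altschul E-value statistics, strand-aware genomic localization of
    precursor loci, consensus microRNA target prediction over 500 bp
    downstream flanks, orthogroup-breadth gene-age assignment, hypergeometric
    enrichment with representation factors, and phylogenetically independent
    contrasts for copy-number versus sociality.  A synthetic multi-species
    world generator with planted ground truth supports end-to-end recovery
    and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
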