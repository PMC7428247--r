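# Cross-species homology classification: seed-match grouping, local-alignment
# genomic homology search with Karlin-Altschul E-values, and the three-tier
# call (seed_match > premir_homolog > unique).

#' Extract the seed of a mature miRNA
#'
#' The seed is positions 2 to `seed_end` (1-based) of the mature sequence,
#' the primary determinant of target recognition; the default 2-8 gives the
#' conventional 7-mer. Returned uppercased in the RNA alphabet.
#'
#' @param mature mature miRNA sequence (length >= `seed_end`)
#' @param seed_end last 1-based seed position (7 or 8)
#' @return seed string
#' @export
extract_seed <- function(mature, seed_end = 8L) {
  if (any(nchar(mature) < seed_end))
    stop("mature sequence shorter than the seed span (", seed_end, " nt)")
  as_rna(substr(mature, 2L, seed_end))
}

#' Group miRNAs into seed-identity classes
#'
#' Two miRNAs fall in one group iff their seeds are identical strings.
#' Groups spanning at least two species, or containing any known mature
#' miRNA, are seed-match (homologous) groups.
#'
#' @param catalog data.frame with columns `mirna_id`, `species_id`,
#'   `mature_seq`
#' @param known_mirs named character vector of known mature miRNA sequences
#'   (names are identifiers); may be empty
#' @param seed_end seed span passed to [extract_seed()]
#' @return `catalog` with added columns `seed`, `group_id`, `n_species`
#'   (species expressing the group) and `known_match`
#' @export
seed_match_classes <- function(catalog, known_mirs = character(),
                               seed_end = 8L) {
  catalog$seed <- extract_seed(catalog$mature_seq, seed_end)
  known_seeds <- if (length(known_mirs))
    unique(extract_seed(as.character(known_mirs), seed_end)) else character()
  grp <- match(catalog$seed, sort(unique(catalog$seed)))
  catalog$group_id <- paste0("seed_", grp)
  nsp <- tapply(catalog$species_id, catalog$group_id,
                function(s) length(unique(s)))
  catalog$n_species <- as.integer(nsp[catalog$group_id])
  catalog$known_match <- catalog$seed %in% known_seeds
  catalog
}

#' Solve ungapped Karlin-Altschul parameters for a scoring system
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, found by bisection on (0, 10].
#' `K` is estimated once per scoring system by simulation: maximal ungapped
#' segment scores of random sequence pairs are fitted to the extreme-value
#' relation `P(M < s) = exp(-K m n exp(-lambda s))` (a documented
#' approximation; BLAST similarly applies fitted constants to gapped scores).
#'
#' @param scoring named vector with `match` and `mismatch` (plus optional
#'   `gap_open`, `gap_extend`, carried through for the aligner)
#' @param base_freqs letter frequencies (uniform 4-letter by default)
#' @param k_sims number of simulated pairs for the K fit
#' @return list with `lambda`, `k`, `scoring`
#' @export
solve_karlin_altschul <- function(scoring = c(match = 2, mismatch = -3,
                                              gap_open = 5, gap_extend = 2),
                                  base_freqs = rep(0.25, 4), k_sims = 200L) {
  p2 <- sum(base_freqs^2)
  m <- scoring[["match"]]
  x <- scoring[["mismatch"]]
  if (m <= 0 || x >= 0 || p2 * m + (1 - p2) * x >= 0)
    stop("invalid scoring system: need match > 0, mismatch < 0 and ",
         "negative expected score")
  f <- function(lam) p2 * exp(lam * m) + (1 - p2) * exp(lam * x) - 1
  lambda <- uniroot(f, c(1e-9, 10), tol = 1e-12)$root

  # K by simulation under the solved lambda (deterministic internal stream)
  letters4 <- if (length(base_freqs) <= 4)
    c("A", "C", "G", "T")[seq_along(base_freqs)]
  else LETTERS[seq_along(base_freqs)]
  L <- 128L
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(20201L)
  mx <- vapply(seq_len(k_sims), function(i) {
    a <- paste(sample(letters4, L, TRUE, prob = base_freqs), collapse = "")
    b <- paste(sample(letters4, L, TRUE, prob = base_freqs), collapse = "")
    .max_segment_cpp(a, b, m, x)
  }, numeric(1))
  s_star <- stats::median(mx)
  frac <- mean(mx < s_star)
  if (frac <= 0 || frac >= 1) frac <- min(max(frac, 1 / k_sims), 1 - 1 / k_sims)
  k <- -log(frac) * exp(lambda * s_star) / (as.numeric(L) * L)
  list(lambda = lambda, k = k, scoring = scoring)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' @param score alignment score
#' @param m,n query length and total searched subject length
#' @param params result of [solve_karlin_altschul()]
#' @return expected number of chance hits at or above `score`
#' @export
ka_evalue <- function(score, m, n, params) {
  params$k * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

#' Local alignment of two sequences (affine-gap Smith-Waterman)
#'
#' @param a,b sequences (T-normalized internally)
#' @param scoring named vector (match, mismatch, gap_open, gap_extend);
#'   gap penalties are positive costs, a gap of length L costs
#'   `gap_open + L * gap_extend`
#' @return list with score, identity_pct, aligned_cols, matches and 1-based
#'   alignment coordinates in both sequences
#' @export
smith_waterman <- function(a, b, scoring = c(match = 2, mismatch = -3,
                                             gap_open = 5, gap_extend = 2)) {
  .sw_align_cpp(as_dna(a), as_dna(b), scoring[["match"]],
                scoring[["mismatch"]], scoring[["gap_open"]],
                scoring[["gap_extend"]])
}

#' Search genomes for homologues of a precursor sequence
#'
#' Word-seeded local alignment of the precursor against both strands of each
#' genome; a hit is reported iff its identity is at least `min_identity`
#' percent and its E-value `K m n exp(-lambda S)` is at most `max_evalue`,
#' with `n` the total length searched (both strands of all chromosomes of
#' the subject species).
#'
#' @param pre_mir_seq precursor sequence
#' @param genomes named list (by species) of named character vectors of
#'   chromosome sequences
#' @param params Karlin-Altschul parameters from [solve_karlin_altschul()]
#' @param min_identity identity threshold (percent)
#' @param max_evalue E-value threshold
#' @param word_size seed word length for the scan
#' @return data.frame of hits (subject_species, chrom, strand, g_start,
#'   g_end, score, identity_pct, aligned_cols, e_value)
#' @export
premir_homology_search <- function(pre_mir_seq, genomes, params,
                                   min_identity = 50, max_evalue = 1e-5,
                                   word_size = 11L) {
  q <- as_dna(pre_mir_seq)
  sc <- params$scoring
  out <- list()
  for (sp in names(genomes)) {
    g <- genomes[[sp]]
    n_tot <- 2 * sum(nchar(g))
    for (chrom in names(g)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") q else revcomp(q)
        hits <- .seeded_scan_cpp(pat, g[[chrom]], as.integer(word_size),
                                 sc[["match"]], sc[["mismatch"]],
                                 sc[["gap_open"]], sc[["gap_extend"]])
        if (!nrow(hits)) next
        hits$e_value <- ka_evalue(hits$score, nchar(q), n_tot, params)
        keep <- hits$identity_pct >= min_identity & hits$e_value <= max_evalue
        if (!any(keep)) next
        hits <- hits[keep, , drop = FALSE]
        hits$subject_species <- sp
        hits$chrom <- chrom
        hits$strand <- str
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out))
    return(data.frame(score = numeric(), identity_pct = numeric(),
                      aligned_cols = integer(), g_start = integer(),
                      g_end = integer(), e_value = numeric(),
                      subject_species = character(), chrom = character(),
                      strand = character(), stringsAsFactors = FALSE))
  `rownames<-`(do.call(rbind, out), NULL)
}

#' Classify expressed miRNAs into homology tiers
#'
#' Tier priority is seed_match > premir_homolog > unique: a miRNA whose seed
#' group spans two or more species, or matches a known mature miRNA, is a
#' seed match; otherwise its precursor is searched against the other
#' species' genomes, giving premir_homolog on a hit and unique on none. A
#' miRNA is lineage-specific iff it is expressed in exactly one species and
#' is not a seed match (genomic similarity alone is not evidence of
#' expression elsewhere).
#'
#' @param catalog data.frame with `mirna_id`, `species_id`, `mature_seq`,
#'   `premir_seq` (and optionally `expression`)
#' @param known_mirs named character vector of known mature sequences
#' @param genomes named list of genomes (see [premir_homology_search()]);
#'   the focal species' own genome is excluded per query
#' @param params Karlin-Altschul parameters; solved from `scoring` if NULL
#' @param seed_end seed span
#' @param min_identity,max_evalue,word_size homology-search thresholds
#' @return data.frame of per-miRNA calls (mirna_id, species_id, tier,
#'   group_id, n_species, lineage_specific, premir_hit_species), with a
#'   per-species tier summary in attribute `summary`
#' @export
classify_all <- function(catalog, known_mirs = character(), genomes = list(),
                         params = NULL, seed_end = 8L, min_identity = 50,
                         max_evalue = 1e-5, word_size = 11L) {
  cl <- seed_match_classes(catalog, known_mirs, seed_end)
  if (is.null(params)) params <- solve_karlin_altschul()
  tier <- character(nrow(cl))
  hit_species <- character(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    if (cl$n_species[i] >= 2L || cl$known_match[i]) {
      tier[i] <- "seed_match"
      next
    }
    others <- genomes[setdiff(names(genomes), cl$species_id[i])]
    hits <- if (length(others))
      premir_homology_search(cl$premir_seq[i], others, params, min_identity,
                             max_evalue, word_size)
    else data.frame(subject_species = character())
    if (nrow(hits)) {
      tier[i] <- "premir_homolog"
      hit_species[i] <- paste(sort(unique(hits$subject_species)),
                              collapse = ",")
    } else {
      tier[i] <- "unique"
    }
  }
  cl$tier <- tier
  cl$premir_hit_species <- hit_species
  cl$lineage_specific <- cl$n_species == 1L & cl$tier != "seed_match"

  tab <- do.call(rbind, lapply(split(cl, cl$species_id), function(d) {
    data.frame(species_id = d$species_id[1], total = nrow(d),
               seed_match = sum(d$tier == "seed_match"),
               premir = sum(d$tier == "premir_homolog"),
               unique = sum(d$tier == "unique"),
               lineage_specific = sum(d$lineage_specific),
               stringsAsFactors = FALSE)
  }))
  attr(cl, "summary") <- `rownames<-`(tab, NULL)
  cl
}

#' Count seed groups shared by every species combination
#'
#' For every non-empty species subset, counts the seed groups expressed in
#' exactly that subset (the upset-plot cells); counts sum to the number of
#' distinct expressed seed groups.
#'
#' @param calls classification table from [classify_all()]
#' @return data.frame with `species_set` (comma-joined, sorted) and `count`
#' @export
upset_sets <- function(calls) {
  sets <- tapply(calls$species_id, calls$group_id,
                 function(s) paste(sort(unique(s)), collapse = ","))
  tab <- table(unlist(sets))
  data.frame(species_set = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
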