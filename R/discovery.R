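# Read QC, exact-match mapping, arm support counting and the contaminant
# screen that gate novel miRNA candidates.

#' Quality-filter a set of small-RNA reads
#'
#' Retains reads of length >= `min_len` whose alphabet is restricted to
#' standard bases (A, C, G and U/T); counts are preserved.
#'
#' @param reads data.frame with columns `sequence` and `count`
#' @param min_len minimum read length
#' @return filtered data.frame
#' @export
qc_reads <- function(reads, min_len = 18L) {
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  keep <- nchar(reads$sequence) >= min_len & is_standard_seq(reads$sequence)
  out <- reads[keep, , drop = FALSE]
  if (!nrow(out)) message("qc_reads: no reads retained")
  `rownames<-`(out, NULL)
}

#' Map reads to a genome by exact matching
#'
#' Each read (T-normalized) is matched exactly against both strands of every
#' chromosome in a single indexed genome pass. A minus-strand hit at 0-based
#' `start` means the reverse complement of the read equals the genome
#' substring starting there.
#'
#' @param reads data.frame with `sequence` and `count`
#' @param genome named character vector of chromosome sequences
#' @return data.frame of hits (sequence, count, chrom, start, end, strand);
#'   the fraction of reads (count-weighted) with at least one hit is
#'   attached as attribute `mapping_fraction`, and unmapped sequences as
#'   attribute `unmapped`
#' @export
map_reads_exact <- function(reads, genome) {
  seqs <- as_dna(reads$sequence)
  hit_rows <- list()
  for (ci in seq_along(genome)) {
    h <- .map_exact_cpp(seqs, genome[[ci]])
    if (!nrow(h)) next
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      sequence = reads$sequence[h$read], count = reads$count[h$read],
      chrom = names(genome)[ci], start = h$start,
      end = h$start + nchar(seqs[h$read]),
      strand = ifelse(h$forward, "+", "-"), stringsAsFactors = FALSE)
  }
  out <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(sequence = character(), count = integer(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  mapped <- reads$sequence %in% out$sequence
  attr(out, "mapping_fraction") <-
    if (sum(reads$count)) sum(reads$count[mapped]) / sum(reads$count) else NA_real_
  attr(out, "unmapped") <- reads$sequence[!mapped]
  `rownames<-`(out, NULL)
}

# Locate mature and star arms of a hairpin from stacked read hits: the
# highest-count read stack inside the locus is the mature arm, the highest
# non-overlapping stack the star arm. Returns NULL when no arm can be called.
locate_arms <- function(premir, hits) {
  h <- hits[hits$chrom == premir$chrom & hits$strand == premir$strand &
              hits$start >= premir$start - 2L & hits$end <= premir$end + 2L, ,
            drop = FALSE]
  if (!nrow(h)) return(NULL)
  stacks <- aggregate(count ~ start + end, data = h, FUN = sum)
  stacks <- stacks[order(-stacks$count, stacks$start), , drop = FALSE]
  mature <- stacks[1, ]
  star <- NULL
  for (k in seq_len(nrow(stacks))[-1]) {
    if (stacks$start[k] >= mature$end || stacks$end[k] <= mature$start) {
      star <- stacks[k, ]
      break
    }
  }
  list(mature = c(start = mature$start, end = mature$end),
       star = if (!is.null(star)) c(start = star$start, end = star$end))
}

#' Count read support on the mature and star arms of a hairpin
#'
#' A read supports an arm when its mapped locus lies within the arm interval
#' extended by `slop` nucleotides at each end (read-stacking tolerance).
#'
#' @param hits mapped-read data.frame (see [map_reads_exact()])
#' @param premir one-row data.frame with chrom, start, end, strand
#' @param mature_iv,star_iv numeric `c(start, end)` 0-based half-open arm
#'   intervals; `star_iv` may be NULL (count 0)
#' @param slop tolerance at arm ends
#' @return list with `mature_count` and `star_count`
#' @export
count_support <- function(hits, premir, mature_iv, star_iv, slop = 2L) {
  if (!is.null(star_iv) &&
      mature_iv["start"] < star_iv["end"] && star_iv["start"] < mature_iv["end"])
    stop("malformed hairpin: mature and star arms overlap")
  h <- hits[hits$chrom == premir$chrom & hits$strand == premir$strand, ,
            drop = FALSE]
  in_arm <- function(iv) {
    if (is.null(iv)) return(0L)
    sum(h$count[h$start >= iv["start"] - slop & h$end <= iv["end"] + slop])
  }
  list(mature_count = in_arm(mature_iv), star_count = in_arm(star_iv))
}

#' Screen a precursor against contaminant (rRNA/tRNA) sequences
#'
#' Local alignment of the precursor against every contaminant; a hit is an
#' alignment with identity >= `min_identity` percent over >=
#' `min_cols` columns.
#'
#' @param pre_mir_seq precursor sequence
#' @param contaminants character vector of contaminant sequences (may be
#'   empty)
#' @param min_identity,min_cols hit thresholds
#' @param scoring alignment scoring (match, mismatch, gap_open, gap_extend)
#' @return logical: TRUE when the precursor resembles a contaminant
#' @export
contaminant_screen <- function(pre_mir_seq, contaminants,
                               min_identity = 80, min_cols = 20,
                               scoring = c(match = 2, mismatch = -3,
                                           gap_open = 5, gap_extend = 2)) {
  if (!length(contaminants)) return(FALSE)
  q <- as_dna(pre_mir_seq)
  for (ct in as_dna(contaminants)) {
    for (s in c(ct, revcomp(ct))) {
      al <- .sw_align_cpp(q, s, scoring[["match"]], scoring[["mismatch"]],
                          scoring[["gap_open"]], scoring[["gap_extend"]])
      if (al$aligned_cols >= min_cols && al$identity_pct >= min_identity)
        return(TRUE)
    }
  }
  FALSE
}

#' Apply the novel-miRNA retention filters
#'
#' A candidate is retained iff it has no contaminant similarity, at least
#' `min_reads` reads on each of the mature and star arms, and a structure
#' permutation p-value strictly below `alpha`. The first failing criterion is
#' recorded as the reject reason.
#'
#' @param candidates data.frame with columns `contaminant_hit`,
#'   `mature_count`, `star_count`, `randfold_p`
#' @param min_reads minimum reads per arm
#' @param alpha structure-test threshold (strict `<`)
#' @return `candidates` with added `retained` and `reject_reason` columns
#' @export
apply_novel_filters <- function(candidates, min_reads = 5L, alpha = 0.05) {
  reason <- rep("", nrow(candidates))
  reason[is.na(candidates$randfold_p) | candidates$randfold_p >= alpha] <-
    "randfold_p"
  reason[candidates$star_count < min_reads] <- "star_support"
  reason[candidates$mature_count < min_reads] <- "mature_support"
  reason[candidates$contaminant_hit] <- "contaminant"
  candidates$retained <- reason == ""
  candidates$reject_reason <- reason
  candidates
}
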