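# Strand-aware assignment of precursor loci to genomic context categories,
# with double counting when a locus overlaps features on both strands.

#' Intersect precursor loci with genomic features
#'
#' Sorted-sweep interval intersection (0-based half-open, >= 1 bp shared);
#' equivalent to all-pairs comparison but near-linear after sorting.
#'
#' @param premirs data.frame with id, chrom, start, end, strand
#' @param features feature data.frame (see [genomic_features()])
#' @return data.frame with one row per overlapping (premir, feature) pair:
#'   premir_id, feature kind, gene_id, same_strand, overlap_bp
#' @export
intersect_features <- function(premirs, features) {
  empty <- data.frame(premir_id = character(), kind = character(),
                      gene_id = character(), same_strand = logical(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (!nrow(premirs) || !nrow(features)) return(empty)
  out <- list()
  for (chrom in unique(premirs$chrom)) {
    p <- premirs[premirs$chrom == chrom, , drop = FALSE]
    f <- features[features$chrom == chrom, , drop = FALSE]
    if (!nrow(f)) next
    p <- p[order(p$start), , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    cmax_end <- cummax(f$end)
    for (i in seq_len(nrow(p))) {
      # candidate window: first feature whose running max end passes the
      # precursor start, through the last feature starting before its end
      first <- findInterval(p$start[i], cmax_end) + 1L
      last <- findInterval(p$end[i] - 1L, f$start) # last start <= p_end - 1
      if (first > last) next
      for (j in first:last) {
        ov <- min(p$end[i], f$end[j]) - max(p$start[i], f$start[j])
        if (ov > 0) {
          out[[length(out) + 1L]] <- data.frame(
            premir_id = p$id[i], kind = f$kind[j],
            gene_id = f$gene_id[j],
            same_strand = p$strand[i] == f$strand[j],
            overlap_bp = as.integer(ov), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  `rownames<-`(do.call(rbind, out), NULL)
}

#' Summarize genomic localization of precursor loci
#'
#' Each precursor contributes one count to every distinct
#' (category, strand-relation) combination it overlaps; a precursor
#' overlapping genes on both strands is counted in both the same- and
#' opposite-strand columns (double counting, reported in
#' `n_double_counted`). A precursor with no gene overlap on either strand is
#' intergenic; repeat categories are counted independently of genic status.
#' `sense_fraction_genic` is the fraction of genic (precursor, strand)
#' assignments that are same-strand.
#'
#' @param premirs precursor data.frame (id, chrom, start, end, strand)
#' @param features feature data.frame with gene models (gene/exon/intron)
#'   and repeats
#' @return list with `counts` (per category, same/opposite), `intergenic`,
#'   `n_double_counted`, `sense_fraction_genic` and the per-precursor label
#'   table `per_premir`
#' @export
summarize_localization <- function(premirs, features) {
  hits <- intersect_features(premirs, features)
  cats <- c("exon", "intron", "transposable_element", "uncharacterized_repeat")
  counts <- matrix(0L, nrow = length(cats), ncol = 2,
                   dimnames = list(cats, c("same", "opposite")))
  genic_kinds <- c("gene", "exon", "intron")
  per <- data.frame(premir_id = premirs$id, intragenic = FALSE,
                    genic_same = FALSE, genic_opposite = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(premirs))) {
    h <- hits[hits$premir_id == premirs$id[k], , drop = FALSE]
    if (nrow(h)) {
      combos <- unique(h[h$kind %in% cats, c("kind", "same_strand")])
      if (nrow(combos)) {
        for (r in seq_len(nrow(combos)))
          counts[combos$kind[r], ifelse(combos$same_strand[r], "same",
                                        "opposite")] <-
            counts[combos$kind[r], ifelse(combos$same_strand[r], "same",
                                          "opposite")] + 1L
      }
      g <- h[h$kind %in% genic_kinds, , drop = FALSE]
      per$intragenic[k] <- nrow(g) > 0
      per$genic_same[k] <- any(g$same_strand)
      per$genic_opposite[k] <- any(!g$same_strand)
    }
  }
  n_same <- sum(per$genic_same)
  n_opp <- sum(per$genic_opposite)
  list(counts = counts,
       intergenic = sum(!per$intragenic),
       n_double_counted = sum(per$genic_same & per$genic_opposite),
       sense_fraction_genic = if (n_same + n_opp > 0)
         n_same / (n_same + n_opp) else NA_real_,
       per_premir = per)
}

#' Test intra/intergenic proportions of lineage-specific vs homologous miRNAs
#'
#' 2x2 chi-squared test with Yates continuity correction (matching R's
#' default for 2x2 tables); when any expected cell is below 1 a Fisher exact
#' test is reported instead, with a warning.
#'
#' @param lineage_specific logical per miRNA
#' @param intragenic logical per miRNA (any gene overlap, either strand)
#' @param correct apply the continuity correction
#' @return list with `statistic`, `p_value`, `method` and the 2x2 `table`
#' @export
intra_inter_chi2 <- function(lineage_specific, intragenic, correct = TRUE) {
  tab <- table(factor(lineage_specific, levels = c(TRUE, FALSE)),
               factor(intragenic, levels = c(TRUE, FALSE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell below 1; reporting Fisher exact test")
    ft <- fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                method = "fisher", table = tab))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chisq", table = tab)
}
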