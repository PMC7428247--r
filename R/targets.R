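# Consensus miRNA target prediction over 500 bp downstream flanks: strict
# seed sites, one duplex pairing scored under two linear models, and a
# composition-matched permutation p-value. A site is retained only when it
# passes the score threshold AND the energy threshold AND p < alpha.

#' Default target-prediction configuration
#'
#' @param flank_len downstream flank length used as a 3'UTR proxy (nt)
#' @param min_score alignment-score retention threshold
#' @param max_energy duplex-energy retention threshold (energy units)
#' @param alpha permutation p-value threshold (strict `<`)
#' @param n_perm permutation count for the site p-value
#' @param band band width (maximum net bulge offset) of the duplex DP
#' @param seed_weight multiplier on seed-region pair scores
#' @param seed_end last 1-based seed position
#' @return named list of settings
#' @export
target_config <- function(flank_len = 500L, min_score = 140, max_energy = -20,
                          alpha = 0.01, n_perm = 199L, band = 3L,
                          seed_weight = 3, seed_end = 8L) {
  list(flank_len = flank_len, min_score = min_score, max_energy = max_energy,
       alpha = alpha, n_perm = n_perm, band = band, seed_weight = seed_weight,
       seed_end = seed_end)
}

#' Extract the downstream-flank 3'UTR proxy of a gene
#'
#' For "+" genes the proxy is `[end, end + flank_len)`; for "-" genes it is
#' `[start - flank_len, start)` reverse-complemented, so the returned
#' sequence always reads 5' to 3' of the mRNA. Clipped at chromosome edges;
#' flanks are not clipped at neighbouring genes.
#'
#' @param gene one-row feature data.frame (kind "gene")
#' @param genome named character vector of chromosome sequences
#' @param flank_len proxy length
#' @return list with gene_id, sequence, chrom, start, end, strand; NULL
#'   (with a warning) when the clipped proxy is empty
#' @export
extract_utr_proxy <- function(gene, genome, flank_len = 500L) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", gene$chrom)
  clen <- nchar(chrom_seq)
  if (gene$strand == "+") {
    s <- gene$end
    e <- min(gene$end + flank_len, clen)
  } else {
    s <- max(gene$start - flank_len, 0L)
    e <- gene$start
  }
  if (e <= s) {
    warning("gene at chromosome edge skipped: ", gene$gene_id)
    return(NULL)
  }
  seq <- substr(chrom_seq, s + 1L, e)
  if (gene$strand == "-") seq <- revcomp(seq)
  list(gene_id = gene$gene_id, sequence = seq, chrom = gene$chrom,
       start = s, end = e, strand = gene$strand)
}

#' Find strict seed sites of a miRNA in a UTR proxy
#'
#' Offsets (0-based) where the UTR contains the exact Watson-Crick reverse
#' complement of the full seed; no G:U wobble is allowed in the seed.
#'
#' @param mature mature miRNA sequence
#' @param utr_seq UTR proxy sequence (mRNA sense, 5'->3')
#' @param seed_end last 1-based seed position
#' @return integer vector of 0-based offsets (possibly empty)
#' @export
find_seed_sites <- function(mature, utr_seq, seed_end = 8L) {
  pat <- revcomp(as_dna(extract_seed(mature, seed_end)))
  m <- gregexpr(pat, as_dna(utr_seq), fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

#' Score the miRNA:target duplex anchored at a seed site
#'
#' One optimal pairing (seed block plus banded 3' extension allowing pairs,
#' symmetric mismatches and single-nucleotide bulges) is scored under two
#' linear models: alignment score (WC +5, G:U +1, mismatch -3, bulge opening
#' -9; seed pairs weighted by `seed_weight`) and duplex energy (GC -3,
#' AU -2, GU -1, +3 per interior loop/bulge opening).
#'
#' @param mature mature miRNA sequence
#' @param utr_seq UTR proxy sequence
#' @param offset 0-based seed-site offset from [find_seed_sites()]
#' @param band,seed_weight duplex DP settings
#' @return list with align_score, duplex_energy, n_pairs
#' @export
score_duplex <- function(mature, utr_seq, offset, band = 3L, seed_weight = 3) {
  .duplex_site_cpp(as_dna(mature), as_dna(utr_seq), as.integer(offset),
                   as.integer(band), seed_weight)
}

#' Permutation p-value for a duplex energy
#'
#' The null statistic is the duplex energy at a chance seed site: the seed
#' complement implanted into flanks drawn from the UTR's own letter
#' composition, giving the add-one p-value
#' `p = (1 + #(null energy below observed)) / (n_perm + 1)`. Duplex
#' energies are integer-valued, so exact ties with null draws occur; with
#' `tie_break = "randomized"` (default) the observed site's rank within its
#' tie block is drawn uniformly, making the p-value exactly uniform under
#' the null; `"conservative"` counts all ties against the site.
#'
#' @param mature mature miRNA sequence
#' @param utr_seq UTR proxy sequence (supplies the composition)
#' @param observed_energy duplex energy at the observed site
#' @param n_perm number of null draws
#' @param band,seed_weight duplex DP settings
#' @param tie_break `"randomized"` or `"conservative"` handling of ties
#' @return p-value in (0, 1]
#' @export
site_pvalue <- function(mature, utr_seq, observed_energy, n_perm = 199L,
                        band = 3L, seed_weight = 3,
                        tie_break = c("randomized", "conservative")) {
  tie_break <- match.arg(tie_break)
  null_e <- .duplex_null_cpp(as_dna(mature), as_dna(utr_seq),
                             as.integer(n_perm), as.integer(band),
                             seed_weight)
  below <- sum(null_e < observed_energy)
  tied <- sum(null_e == observed_energy)
  hits <- if (tie_break == "conservative") below + tied else
    below + (if (tied > 0) sample.int(tied + 1L, 1L) - 1L else 0L)
  (1 + hits) / (n_perm + 1)
}

#' Predict miRNA targets over a set of UTR proxies
#'
#' Runs [find_seed_sites()], [score_duplex()] and [site_pvalue()] for every
#' miRNA x gene combination and retains sites with
#' `align_score >= min_score`, `duplex_energy <= max_energy` and
#' `p < alpha`. Gene-level pairs are deduplicated (a gene counts once per
#' miRNA regardless of site count).
#'
#' @param mirnas data.frame with `mirna_id` and `mature_seq`
#' @param utrs list of UTR proxies from [extract_utr_proxy()]
#' @param config settings from [target_config()]
#' @return list with `sites` (all evaluated sites with a `retained` flag)
#'   and `pairs` (deduplicated retained miRNA-gene pairs: mirna_id, gene_id,
#'   n_sites, best_score, best_energy, min_p)
#' @export
predict_targets <- function(mirnas, utrs, config = target_config()) {
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    mat <- mirnas$mature_seq[i]
    for (u in utrs) {
      offs <- find_seed_sites(mat, u$sequence, config$seed_end)
      for (o in offs) {
        sc <- score_duplex(mat, u$sequence, o, config$band,
                           config$seed_weight)
        # the p-value is only needed when both hard thresholds pass
        pass_hard <- sc$align_score >= config$min_score &&
          sc$duplex_energy <= config$max_energy
        p <- if (pass_hard)
          site_pvalue(mat, u$sequence, sc$duplex_energy, config$n_perm,
                      config$band, config$seed_weight) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mirnas$mirna_id[i], gene_id = u$gene_id,
          utr_offset = o, align_score = sc$align_score,
          duplex_energy = sc$duplex_energy, p_value = p,
          retained = isTRUE(pass_hard && p < config$alpha),
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(rows)) `rownames<-`(do.call(rbind, rows), NULL) else
    data.frame(mirna_id = character(), gene_id = character(),
               utr_offset = integer(), align_score = numeric(),
               duplex_energy = numeric(), p_value = numeric(),
               retained = logical(), stringsAsFactors = FALSE)
  kept <- sites[sites$retained, , drop = FALSE]
  pairs <- if (nrow(kept)) {
    sp <- split(kept, paste(kept$mirna_id, kept$gene_id, sep = "\r"))
    `rownames<-`(do.call(rbind, lapply(sp, function(d) data.frame(
      mirna_id = d$mirna_id[1], gene_id = d$gene_id[1], n_sites = nrow(d),
      best_score = max(d$align_score), best_energy = min(d$duplex_energy),
      min_p = min(d$p_value), stringsAsFactors = FALSE))), NULL)
  } else {
    data.frame(mirna_id = character(), gene_id = character(),
               n_sites = integer(), best_score = numeric(),
               best_energy = numeric(), min_p = numeric(),
               stringsAsFactors = FALSE)
  }
  list(sites = sites, pairs = pairs)
}
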