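#' Fold an RNA sequence with a weighted Nussinov algorithm
#'
#' Maximizes total base-pair weight (GC = 3, AU = 2, GU = 1) over all nested
#' (pseudoknot-free) structures with a minimum hairpin loop of `min_loop`
#' unpaired nucleotides. The reported `energy` is the negated total weight,
#' in arbitrary energy units, so more stable structures are more negative.
#' Traceback is deterministic with leftmost-pair preference.
#'
#' @param seq RNA or DNA sequence (U and T are equivalent)
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#' @return list with `pairing` (two-column matrix of 1-based paired
#'   positions) and `energy` (<= 0)
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  s <- as_dna(seq)
  if (nchar(s) < 1) stop("empty sequence")
  res <- .nussinov_cpp(s, as.integer(min_loop), TRUE)
  list(pairing = res$pairs, energy = res$energy)
}

# energy only, skipping traceback (used by the permutation test)
fold_energy <- function(seq, min_loop = 3L) {
  .nussinov_cpp(as_dna(seq), as.integer(min_loop), FALSE)$energy
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the returned sequence has exactly
#' the same dinucleotide (and hence mononucleotide) counts as the input, with
#' first and last characters fixed.
#'
#' @param seq character sequence
#' @return shuffled sequence
#' @export
dinucleotide_shuffle <- function(seq) {
  .dinuc_shuffle_cpp(seq)
}

#' Secondary-structure permutation test for a hairpin precursor
#'
#' Tests whether a candidate precursor folds more stably than
#' dinucleotide-preserving shuffles of itself (the randfold idea), via the
#' add-one permutation p-value
#' `p = (1 + #(shuffled energy below native)) / (n_shuffles + 1)`, which is
#' never exactly zero. Because the fold energies are integer-valued, exact
#' ties between the native energy and shuffle energies are common; with
#' `tie_break = "randomized"` (default) the native sequence's rank within
#' its tie block is drawn uniformly, which makes the p-value exactly
#' uniform under the null. `tie_break = "conservative"` counts every tie
#' against the native sequence (`<=`), giving a conservative
#' (super-uniform) p-value.
#'
#' @param pre_mir_seq precursor sequence (>= 20 nt)
#' @param n_shuffles number of dinucleotide shuffles
#' @param min_loop minimum hairpin loop passed to the folding engine
#' @param tie_break `"randomized"` or `"conservative"` handling of energy
#'   ties
#' @return p-value in (0, 1]
#' @export
randfold_test <- function(pre_mir_seq, n_shuffles = 999L, min_loop = 3L,
                          tie_break = c("randomized", "conservative")) {
  tie_break <- match.arg(tie_break)
  s <- as_dna(pre_mir_seq)
  if (nchar(s) < 20) stop("precursor sequence must be at least 20 nt")
  if (length(unique(seq_chars(s))) == 1L) {
    warning("degenerate sequence (single repeated dinucleotide); p = 1")
    return(1)
  }
  native <- fold_energy(s, min_loop)
  below <- 0L
  tied <- 0L
  for (i in seq_len(n_shuffles)) {
    e <- fold_energy(dinucleotide_shuffle(s), min_loop)
    if (e < native) below <- below + 1L else if (e == native) tied <- tied + 1L
  }
  hits <- if (tie_break == "conservative") below + tied else
    below + (if (tied > 0) sample.int(tied + 1L, 1L) - 1L else 0L)
  (1 + hits) / (n_shuffles + 1)
}
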