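# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately use naive exhaustive strategies.

# all nested structures of seq enumerated explicitly; returns the maximum
# total pair weight (GC=3, AU=2, GU=1, min_loop unpaired bases per hairpin)
oracle_nussinov_energy <- function(seq, min_loop = 3) {
  s <- strsplit(beemir::as_dna(seq), "")[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    res <- best(i + 1, j) # i unpaired
    for (k in seq(i + min_loop + 1, j)) {
      if (w(s[i], s[k]) > 0) {
        inner <- if (k > i + 1) best(i + 1, k - 1) else 0
        outer <- if (k < j) best(k + 1, j) else 0
        res <- max(res, w(s[i], s[k]) + inner + outer)
      }
    }
    res
  }
  n <- length(s)
  if (n < 2) return(0)
  -best(1, n)
}

# plain three-state affine Smith-Waterman in R (quadratic DP, score only)
oracle_sw_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                            gap_extend = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H)
}

# hypergeometric tail probabilities by explicit enumeration of all
# n-subsets of a universe of size N containing D marked elements
oracle_hyper_tails <- function(N, D, n, x) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(D)
  overlaps <- apply(subsets, 2, function(s) length(intersect(s, marked)))
  list(p_over = mean(overlaps >= x), p_under = mean(overlaps <= x))
}

# all-pairs interval intersection (0-based half-open); every (premir,
# feature) combination is examined explicitly
oracle_intersect <- function(premirs, features) {
  g <- expand.grid(i = seq_len(nrow(premirs)), j = seq_len(nrow(features)))
  same_chrom <- premirs$chrom[g$i] == features$chrom[g$j]
  ov <- pmin(premirs$end[g$i], features$end[g$j]) -
    pmax(premirs$start[g$i], features$start[g$j])
  keep <- same_chrom & ov > 0
  data.frame(premir_id = premirs$id[g$i[keep]],
             kind = features$kind[g$j[keep]],
             gene_id = features$gene_id[g$j[keep]],
             same_strand = premirs$strand[g$i[keep]] ==
               features$strand[g$j[keep]],
             overlap_bp = as.integer(ov[keep]), stringsAsFactors = FALSE)
}

# exhaustive search over all banded alignment paths of the duplex 3'
# extension (same scoring constants as the implementation, pure recursion)
oracle_duplex_ext <- function(a, b, band = 3) {
  ptype <- function(m, u) {
    if ((m == "A" && u == "T") || (m == "T" && u == "A") ||
        (m == "G" && u == "C") || (m == "C" && u == "G")) return(1)
    if ((m == "G" && u == "T") || (m == "T" && u == "G")) return(2)
    0
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  rec <- function(ci, cj) { # ci of a and cj of b consumed so far
    best <- 0 # stopping is always allowed
    if (ci < la && cj < lb && abs(ci + 1 - (cj + 1)) <= band) {
      t <- ptype(av[ci + 1], bv[cj + 1])
      add <- if (t == 1) 5 else if (t == 2) 1 else -3
      best <- max(best, add + rec(ci + 1, cj + 1))
    }
    if (ci < la && abs(ci + 1 - cj) <= band)
      best <- max(best, -9 + rec(ci + 1, cj))
    if (cj < lb && abs(ci - (cj + 1)) <= band)
      best <- max(best, -9 + rec(ci, cj + 1))
    best
  }
  rec(0, 0)
}

# random genomic feature fixture on one chromosome
random_intervals <- function(n, chrom_len = 1000, kinds = "gene",
                             prefix = "f") {
  start <- sample.int(chrom_len - 20L, n, replace = TRUE) - 1L
  len <- sample(1:50, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start,
             end = pmin(start + len, chrom_len),
             strand = sample(c("+", "-"), n, replace = TRUE),
             kind = sample(kinds, n, replace = TRUE),
             gene_id = paste0(prefix, seq_len(n)),
             id = paste0(prefix, seq_len(n)), stringsAsFactors = FALSE)
}

dinuc_counts <- function(x) {
  ch <- strsplit(x, "")[[1]]
  sort(table(paste0(ch[-length(ch)], ch[-1])))
}
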