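# Copy-number vs sociality association through phylogenetically independent
# contrasts and Spearman rank correlation with BH correction.

#' Phylogenetically independent contrasts of a leaf trait
#'
#' Felsenstein's contrasts via [ape::pic()]: n-1 standardized, mutually
#' independent differences under a Brownian-motion model. The tree is
#' reordered deterministically first so that two traits contrasted on the
#' same tree are paired node-for-node (both contrasts flip sign together
#' under child swaps).
#'
#' @param tree rooted binary `phylo` tree with positive branch lengths
#' @param trait named numeric vector, names = tip labels
#' @return numeric vector of n-1 contrasts (named by internal node)
#' @export
pic_contrasts <- function(tree, trait) {
  if (!ape::is.binary(tree)) stop("tree must be binary")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("missing trait value for: ", paste(missing, collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  ape::pic(trait[tree$tip.label], tree)
}

#' Spearman correlation of two contrast vectors
#'
#' Rank correlation on average-ranked contrasts. For 9 or fewer pairs the
#' two-sided p-value is exact by full enumeration of rank permutations;
#' above that the t-approximation of `cor.test` is used.
#'
#' @param cx,cy numeric contrast vectors of equal length >= 3
#' @return list with rho, p_value, method
#' @export
contrast_spearman <- function(cx, cy) {
  n <- length(cx)
  if (length(cy) != n) stop("contrast vectors differ in length")
  if (n < 3) stop("need at least 3 contrasts")
  rx <- rank(cx)
  ry <- rank(cy)
  rho <- cor(rx, ry)
  if (n <= 9) {
    # exact two-sided permutation p over all n! rank orderings
    perms <- permutations_of(n)
    cross <- matrix(ry[perms], nrow(perms)) %*% rx # sum_i rx_i ry_perm(i)
    null_rho <- (cross / n - mean(rx) * mean(ry)) /
      sqrt(var(rx) * (n - 1) / n) / sqrt(var(ry) * (n - 1) / n)
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, method = "exact permutation")
  } else {
    ct <- suppressWarnings(cor.test(cx, cy, method = "spearman",
                                    exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value,
         method = "t approximation")
  }
}

# all permutations of 1..n as a matrix (n! rows); n <= 9
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k)) # insert k, shift the rest
  }))
}

#' Scan a copy-number matrix for associations with sociality
#'
#' One test per miRNA accession: both the accession's copy numbers and the
#' sociality scores are transformed to independent contrasts on the same
#' tree, correlated by Spearman's rank method, and BH-corrected across
#' accessions. Accessions with zero copy-number variance across species are
#' skipped (no information).
#'
#' @param copy_matrix integer matrix, rows = accessions, columns = species
#'   (must equal the tree's tip labels as a set)
#' @param tree rooted binary `phylo` tree
#' @param sociality named numeric vector of ordinal sociality scores
#'   (0 = solitary ... 3 = obligate complex eusocial)
#' @return data.frame (accession, rho, p_value, p_adj, skipped, reason)
#' @export
copy_number_scan <- function(copy_matrix, tree, sociality) {
  if (!setequal(colnames(copy_matrix), tree$tip.label))
    stop("matrix columns must match tree tip labels")
  soc_c <- pic_contrasts(tree, sociality)
  res <- data.frame(accession = rownames(copy_matrix),
                    rho = NA_real_, p_value = NA_real_, p_adj = NA_real_,
                    skipped = FALSE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(copy_matrix))) {
    cn <- copy_matrix[i, tree$tip.label]
    if (var(cn) == 0) {
      res$skipped[i] <- TRUE
      res$reason[i] <- "constant copy number"
      next
    }
    cs <- contrast_spearman(pic_contrasts(tree, cn), soc_c)
    res$rho[i] <- cs$rho
    res$p_value[i] <- cs$p_value
  }
  tested <- !res$skipped
  res$p_adj[tested] <- bh_adjust(res$p_value[tested])
  res
}

#' Summary statistics of a copy-number matrix
#'
#' Mean and standard deviation of copy number over all accession x species
#' entries, plus the fraction of accessions with identical copy number in
#' every genome.
#'
#' @param copy_matrix integer matrix (accessions x species)
#' @return list with `mean`, `sd` and `fraction_constant`
#' @export
copy_number_summary <- function(copy_matrix) {
  v <- as.numeric(copy_matrix)
  const <- apply(copy_matrix, 1, function(r) length(unique(r)) == 1L)
  list(mean = mean(v), sd = sd(v), fraction_constant = mean(const))
}
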