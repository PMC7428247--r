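#' @useDynLib beemir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate chisq.test cor cor.test fisher.test ks.test
#'   median p.adjust phyper pnorm pt quantile rbinom rnbinom rnorm rpois
#'   runif sd setNames t.test uniroot var
#' @importFrom utils combn head read.delim write.table
NULL

# Internal convention: genomic/DNA sequences are stored with T; mature miRNA
# sequences are presented with U at the interfaces. All comparisons happen on
# the T alphabet through these helpers.

#' Normalize a sequence to the DNA alphabet (U -> T, uppercase)
#' @param x character vector of sequences
#' @return uppercased T-alphabet sequences
#' @export
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Normalize a sequence to the RNA alphabet (T -> U, uppercase)
#' @param x character vector of sequences
#' @return uppercased U-alphabet sequences
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse-complement DNA sequences
#' @param x character vector of T-alphabet sequences
#' @return reverse complements
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTN", "TGCAN", as_dna(s))
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# random DNA string of length n (uniform base composition)
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# TRUE where sequences contain only standard bases (T alphabet)
is_standard_seq <- function(x) !grepl("[^ACGT]", as_dna(x))

# split a string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
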