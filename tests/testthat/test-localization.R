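test_that("interval intersection handles the canonical cases", {
  premirs <- data.frame(id = "p1", chrom = "chr1", start = 100L, end = 170L,
                        strand = "+", stringsAsFactors = FALSE)
  feats <- genomic_features(
    chrom = "chr1", start = c(150L, 0L, 160L), end = c(300L, 90L, 400L),
    strand = c("+", "-", "-"), kind = c("exon", "gene", "intron"),
    gene_id = c("g1", "g2", "g3"))
  hits <- intersect_features(premirs, feats)
  expect_equal(nrow(hits), 2) # the [0,90) gene does not overlap
  ex <- hits[hits$kind == "exon", ]
  expect_equal(ex$overlap_bp, 20L)
  expect_true(ex$same_strand)
  intr <- hits[hits$kind == "intron", ]
  expect_equal(intr$overlap_bp, 10L)
  expect_false(intr$same_strand) # a parenthetical (opposite-strand) count
})

test_that("sweep intersection equals brute force on random fixtures", {
  set.seed(19)
  for (rep in 1:30) {
    p <- random_intervals(sample(5:40, 1), prefix = "p")
    f <- random_intervals(sample(5:60, 1),
                          kinds = c("gene", "exon", "intron",
                                    "transposable_element"))
    got <- intersect_features(p, f)
    want <- oracle_intersect(p, f)
    key <- function(d) sort(paste(d$premir_id, d$kind, d$gene_id,
                                  d$same_strand, d$overlap_bp))
    expect_identical(key(got), key(want))
  }
})

test_that("category counts are invariant to input order", {
  set.seed(20)
  p <- random_intervals(20, prefix = "p")
  f <- random_intervals(40, kinds = c("gene", "exon", "intron"))
  f$gene_id[f$kind %in% c("exon", "intron")] <- "gX"
  a <- summarize_localization(p, f)
  b <- summarize_localization(p[sample(nrow(p)), ], f[sample(nrow(f)), ])
  expect_equal(a$counts, b$counts)
  expect_equal(a$intergenic, b$intergenic)
})

test_that("localization double-counts both-strand gene overlaps", {
  premirs <- data.frame(id = "p1", chrom = "chr1", start = 100L, end = 160L,
                        strand = "+", stringsAsFactors = FALSE)
  feats <- genomic_features(
    chrom = "chr1", start = c(50L, 120L), end = c(130L, 300L),
    strand = c("+", "-"), kind = "gene", gene_id = c("gA", "gB"))
  s <- summarize_localization(premirs, feats)
  expect_equal(s$n_double_counted, 1L)
  expect_equal(s$per_premir$genic_same, TRUE)
  expect_equal(s$per_premir$genic_opposite, TRUE)
  expect_equal(s$intergenic, 0L)
})

test_that("precursors overlapping nothing are intergenic", {
  premirs <- data.frame(id = c("p1", "p2"), chrom = "chr1",
                        start = c(10L, 500L), end = c(70L, 560L),
                        strand = "+", stringsAsFactors = FALSE)
  feats <- genomic_features(chrom = "chr1", start = 100L, end = 200L,
                            strand = "+", kind = "gene", gene_id = "g1")
  s <- summarize_localization(premirs, feats)
  expect_equal(s$intergenic, 2L)
  expect_true(is.na(s$sense_fraction_genic))
})

test_that("sense fraction of genic precursors is the same-strand share", {
  n <- 10
  premirs <- data.frame(id = paste0("p", 1:n), chrom = "chr1",
                        start = seq(0L, by = 1000L, length.out = n),
                        end = seq(60L, by = 1000L, length.out = n),
                        strand = "+", stringsAsFactors = FALSE)
  feats <- genomic_features(
    chrom = "chr1", start = premirs$start, end = premirs$end + 100L,
    strand = c(rep("+", 8), rep("-", 2)), kind = "gene",
    gene_id = paste0("g", 1:n))
  s <- summarize_localization(premirs, feats)
  expect_equal(s$sense_fraction_genic, 0.8)
})

test_that("intragenic chi-squared matches the hand-computed Yates value", {
  # 2x2 table [[30,10],[10,30]]: all expected cells are 20, so
  # chi2_Yates = 4 * (|30-20| - 0.5)^2 / 20 = 18.05
  ls <- rep(c(TRUE, FALSE), times = c(40, 40))
  intra <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  r <- intra_inter_chi2(ls, intra)
  expect_equal(r$statistic, 18.05, tolerance = 1e-12)
  expect_equal(r$method, "chisq")
})

test_that("independent 2x2 tables give chi-squared zero", {
  ls <- rep(c(TRUE, FALSE), each = 40)
  intra <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 20)
  r <- intra_inter_chi2(ls, intra, correct = FALSE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("tiny expected cells fall back to Fisher with a warning", {
  ls <- c(TRUE, rep(FALSE, 39))
  intra <- c(TRUE, rep(c(TRUE, FALSE), 19), FALSE)
  expect_warning(r <- intra_inter_chi2(ls, intra), "Fisher")
  expect_equal(r$method, "fisher")
  expect_true(r$p_value > 0 && r$p_value <= 1)
})
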