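test_that("read QC enforces minimum length and standard alphabet", {
  reads <- data.frame(
    sequence = c("ACGUACGUACGUACGUAC",     # exactly 18 nt: retained
                 "ACGUACGUACGUACGUA",      # 17 nt: removed
                 "ACGTNNNACGTACGTACGT",    # non-standard base: removed
                 "ACGUACGUACGUACGUACGUAC"),
    count = c(3L, 5L, 2L, 7L), stringsAsFactors = FALSE)
  out <- qc_reads(reads)
  expect_equal(out$sequence, reads$sequence[c(1, 4)])
  expect_equal(out$count, c(3L, 7L)) # counts preserved
})

test_that("exact mapping reports both strands and flags unmapped reads", {
  set.seed(21)
  g <- random_dna(800)
  fwd <- substr(g, 101, 122)
  rev <- revcomp(substr(g, 201, 222))
  reads <- data.frame(sequence = c(fwd, rev, strrep("A", 22)),
                      count = c(2L, 3L, 1L), stringsAsFactors = FALSE)
  hits <- map_reads_exact(reads, c(chr1 = g))
  h1 <- hits[hits$sequence == fwd, ]
  expect_true(any(h1$start == 100 & h1$strand == "+"))
  h2 <- hits[hits$sequence == rev, ]
  expect_true(any(h2$start == 200 & h2$strand == "-"))
  expect_true(strrep("A", 22) %in% attr(hits, "unmapped"))
  expect_equal(attr(hits, "mapping_fraction"), 5 / 6)
  # reported loci really contain the read (or its reverse complement)
  for (r in seq_len(nrow(hits))) {
    seg <- substr(g, hits$start[r] + 1, hits$end[r])
    expected <- if (hits$strand[r] == "+") as_dna(hits$sequence[r]) else
      revcomp(hits$sequence[r])
    expect_equal(seg, expected)
  }
})

test_that("arm support counting honors the five-read filter boundary", {
  premir <- data.frame(chrom = "chr1", start = 100L, end = 164L,
                       strand = "+", stringsAsFactors = FALSE)
  mk_hits <- function(mature_n, star_n) {
    data.frame(
      sequence = "x", count = c(mature_n, star_n),
      chrom = "chr1", start = c(104L, 138L), end = c(126L, 160L),
      strand = "+", stringsAsFactors = FALSE)
  }
  m_iv <- c(start = 104, end = 126)
  s_iv <- c(start = 138, end = 160)
  cs <- count_support(mk_hits(5L, 5L), premir, m_iv, s_iv)
  f <- apply_novel_filters(data.frame(
    contaminant_hit = FALSE, mature_count = cs$mature_count,
    star_count = cs$star_count, randfold_p = 0.01))
  expect_true(f$retained)
  cs2 <- count_support(mk_hits(5L, 4L), premir, m_iv, s_iv)
  f2 <- apply_novel_filters(data.frame(
    contaminant_hit = FALSE, mature_count = cs2$mature_count,
    star_count = cs2$star_count, randfold_p = 0.01))
  expect_false(f2$retained)
  expect_equal(f2$reject_reason, "star_support")
  # no reads at all
  empty <- mk_hits(1L, 1L)[0, ]
  cs3 <- count_support(empty, premir, m_iv, s_iv)
  expect_equal(c(cs3$mature_count, cs3$star_count), c(0L, 0L))
})

test_that("overlapping arms are a malformed hairpin", {
  premir <- data.frame(chrom = "chr1", start = 0L, end = 60L, strand = "+")
  expect_error(
    count_support(data.frame(sequence = character(), count = integer(),
                             chrom = character(), start = integer(),
                             end = integer(), strand = character()),
                  premir, c(start = 5, end = 30), c(start = 25, end = 50)),
    "malformed hairpin")
})

test_that("contaminant screen detects embedded contaminant fragments", {
  set.seed(31)
  trna <- random_dna(90)
  pre <- paste0(random_dna(20), substr(trna, 30, 54), random_dna(20))
  expect_true(contaminant_screen(pre, c(tRNA1 = trna)))
  expect_false(contaminant_screen(random_dna(70), character()))
  expect_false(contaminant_screen(random_dna(70), c(tRNA1 = trna)))
})

test_that("novel-miRNA filters apply the strict randfold threshold", {
  cand <- data.frame(
    contaminant_hit = c(FALSE, FALSE, TRUE, FALSE),
    mature_count = c(10L, 10L, 10L, 4L),
    star_count = c(7L, 7L, 7L, 9L),
    randfold_p = c(0.01, 0.05, 0.001, 0.01))
  out <- apply_novel_filters(cand)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$reject_reason,
               c("", "randfold_p", "contaminant", "mature_support"))
})
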