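test_that("UTR proxies follow the downstream-flank conventions", {
  set.seed(41)
  g <- c(chr1 = random_dna(10000))
  plus <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                     strand = "+", kind = "gene", gene_id = "gp")
  u <- extract_utr_proxy(plus, g)
  expect_equal(c(u$start, u$end), c(2000L, 2500L))
  expect_equal(u$sequence, substr(g[["chr1"]], 2001, 2500))
  minus <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                      strand = "-", kind = "gene", gene_id = "gm")
  um <- extract_utr_proxy(minus, g)
  expect_equal(c(um$start, um$end), c(500L, 1000L))
  expect_equal(um$sequence, revcomp(substr(g[["chr1"]], 501, 1000)))
  edge <- data.frame(chrom = "chr1", start = 9000L, end = 9800L,
                     strand = "+", kind = "gene", gene_id = "ge")
  ue <- extract_utr_proxy(edge, g)
  expect_equal(nchar(ue$sequence), 200L) # clipped at the chromosome end
  zero <- data.frame(chrom = "chr1", start = 9000L, end = 10000L,
                     strand = "+", kind = "gene", gene_id = "gz")
  expect_warning(uz <- extract_utr_proxy(zero, g), "skipped")
  expect_null(uz)
})

test_that("strict seed sites are exact reverse complements", {
  mat <- "UGAGGUAGUAGGUUGUAUAGUU" # seed GAGGUAG, complement CTACCTC
  utr <- paste0(strrep("A", 50), "CTACCTC", strrep("A", 43))
  expect_equal(find_seed_sites(mat, utr), 50L)
  utr2 <- paste0("CTACCTC", strrep("G", 60), "CTACCTC")
  expect_equal(find_seed_sites(mat, utr2), c(0L, 67L))
  utr3 <- paste0(strrep("A", 50), "CTACGTC", strrep("A", 43)) # 1 mismatch
  expect_equal(length(find_seed_sites(mat, utr3)), 0L)
})

test_that("duplex scores and energies follow the stated linear models", {
  set.seed(43)
  mat <- random_dna(22)
  # full-length perfect complement: every miRNA base pairs Watson-Crick
  utr <- paste0(random_dna(80), revcomp(mat), random_dna(40))
  o <- find_seed_sites(mat, utr)
  expect_equal(o, 80L + 22L - 8L)
  sc <- score_duplex(mat, utr, o)
  # 7 seed pairs at 3 x 5 each, 15 other pairs at +5
  expect_equal(sc$align_score, 7 * 15 + 15 * 5)
  ch <- strsplit(mat, "")[[1]]
  gc <- sum(ch %in% c("G", "C"))
  expect_equal(sc$duplex_energy, -(3 * gc + 2 * (22 - gc)))
  expect_equal(sc$n_pairs, 22)

  # seed-only site in an unpairable background: score 105, energy -18
  mat2 <- paste0("G", "GAGGTAG", strrep("A", 14))
  utr2 <- paste0(strrep("A", 40), "CTACCTC", strrep("A", 40))
  o2 <- find_seed_sites(mat2, utr2)
  sc2 <- score_duplex(mat2, utr2, o2[1])
  expect_equal(sc2$align_score, 105) # 7 weighted seed pairs only
  expect_equal(sc2$duplex_energy, -18) # 4 GC + 3 AU seed pairs
  expect_equal(sc2$n_pairs, 7)
  expect_lt(sc2$align_score, 140) # rejected by the score threshold
  expect_gt(sc2$duplex_energy, -20) # and by the energy threshold
})

test_that("duplex 3' extension equals exhaustive search on toy cases", {
  set.seed(44)
  for (rep in 1:30) {
    ext_len <- sample(1:6, 1)
    mat <- random_dna(8 + ext_len) # seed + short 3' tail
    up <- random_dna(ext_len + 3)
    utr <- paste0(up, revcomp(substr(mat, 2, 8)), "A")
    o <- nchar(up)
    sc <- score_duplex(mat, utr, o)
    # subtract the fixed seed and 5'-position contributions
    seed_ch <- strsplit(substr(mat, 2, 8), "")[[1]]
    gc <- sum(seed_ch %in% c("G", "C"))
    base_score <- 7 * 15
    p0 <- substr(mat, 1, 1)
    u0 <- substr(utr, o + 8, o + 8)
    t0 <- paste0(p0, u0)
    if (t0 %in% c("AT", "TA", "GC", "CG")) base_score <- base_score + 5
    if (t0 %in% c("GT", "TG")) base_score <- base_score + 1
    a3 <- substr(mat, 9, nchar(mat))
    b3 <- paste(rev(strsplit(substr(utr, 1, o), "")[[1]]), collapse = "")
    expect_equal(sc$align_score - base_score, oracle_duplex_ext(a3, b3),
                 info = paste(mat, utr))
  }
})

test_that("site p-values follow the add-one permutation formula", {
  set.seed(45)
  mat <- random_dna(22)
  utr <- paste0(random_dna(200), revcomp(mat), random_dna(100))
  o <- find_seed_sites(mat, utr)[1]
  e <- score_duplex(mat, utr, o)$duplex_energy
  p <- site_pvalue(mat, utr, e, n_perm = 499)
  expect_equal(p, 1 / 500) # perfect duplex beats every null draw
  p_weak <- site_pvalue(mat, utr, -14, n_perm = 199)
  expect_gt(p_weak, 0.5) # a weak energy is never significant
})

test_that("target prediction retains planted sites and dedups gene pairs", {
  set.seed(46)
  mat <- random_dna(22)
  utr_hit <- list(gene_id = "gHit",
                  sequence = paste0(random_dna(50), revcomp(mat),
                                    random_dna(30), revcomp(mat),
                                    random_dna(20)))
  utr_null <- list(gene_id = "gNull", sequence = random_dna(500))
  mirnas <- data.frame(mirna_id = "mir1", mature_seq = as_rna(mat),
                       stringsAsFactors = FALSE)
  res <- predict_targets(mirnas, list(utr_hit, utr_null))
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$gene_id, "gHit")
  expect_equal(res$pairs$n_sites, 2) # two sites, one gene-level pair
  expect_true(all(res$pairs$best_score >= 140))
  expect_true(all(res$pairs$best_energy <= -20))
  expect_true(all(res$pairs$min_p < 0.01))
})

test_that("UTRs without seed sites yield no predictions", {
  set.seed(47)
  mirnas <- data.frame(mirna_id = "mir1", mature_seq = as_rna(random_dna(22)),
                       stringsAsFactors = FALSE)
  utr <- list(gene_id = "g1", sequence = strrep("A", 500))
  res <- predict_targets(mirnas, list(utr))
  expect_equal(nrow(res$sites), 0)
  expect_equal(nrow(res$pairs), 0)
})
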