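test_that("seed extraction takes 1-based positions 2-8", {
  expect_equal(extract_seed("UGAGGUAGUAGGUUGUAUAGUU"), "GAGGUAG")
  expect_equal(extract_seed("ACGUACGU"), "CGUACGU") # 8 nt boundary
  expect_error(extract_seed("ACGUACG"), "shorter")
  expect_equal(extract_seed("ACGUACGUA", seed_end = 7L), "CGUACG")
})

test_that("seed grouping is by exact seed identity and known matches count", {
  catalog <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4"),
    species_id = c("spA", "spB", "spA", "spA"),
    mature_seq = c("UGAGGUAGUAGGUUGUAUAGUU",  # same seed as m2
                   "AGAGGUAGUCGGUUGUACAGUA",  # same seed, other species
                   "UCAGGUAGUAGGUUGUAUAGUU",  # one seed mismatch
                   "UAACCGUUGUAGGUUGUAUAGG"), # matches the known miR below
    stringsAsFactors = FALSE)
  known <- c(kn1 = "CAACCGUUGUAUAACCGUACGG")
  cl <- seed_match_classes(catalog, known)
  expect_equal(cl$group_id[1], cl$group_id[2])
  expect_false(cl$group_id[3] == cl$group_id[1])
  expect_equal(cl$n_species[1:2], c(2L, 2L))
  expect_true(cl$known_match[4])
  expect_false(any(cl$known_match[1:3]))
})

test_that("seed grouping is order-independent", {
  set.seed(3)
  catalog <- data.frame(
    mirna_id = paste0("m", 1:12),
    species_id = sample(c("spA", "spB", "spC"), 12, TRUE),
    mature_seq = as_rna(replicate(12, paste0("A", random_dna(21)))),
    stringsAsFactors = FALSE)
  a <- seed_match_classes(catalog)
  perm <- sample(12)
  b <- seed_match_classes(catalog[perm, ])
  # membership partition identical regardless of input order
  key <- function(cl) lapply(split(cl$mirna_id, cl$seed), sort)
  expect_equal(key(a), key(b)[names(key(a))])
})

test_that("Karlin-Altschul lambda matches closed forms and oracles", {
  p <- solve_karlin_altschul(c(match = 1, mismatch = -1,
                               gap_open = 5, gap_extend = 2))
  expect_equal(p$lambda, log(3), tolerance = 1e-9) # 0.25 e^l + 0.75 e^-l = 1
  # match +2 / mismatch -3: lambda from the polynomial root of
  # 0.25 y^5 - y^3 + 0.75 = 0 with y = exp(lambda) > 1
  p2 <- solve_karlin_altschul(c(match = 2, mismatch = -3,
                                gap_open = 5, gap_extend = 2))
  roots <- polyroot(c(0.75, 0, 0, -1, 0, 0.25))
  real <- Re(roots[abs(Im(roots)) < 1e-9])
  y <- real[real > 1 + 1e-9]
  expect_equal(p2$lambda, log(y), tolerance = 1e-8)
  expect_gt(p2$k, 0)
  expect_error(solve_karlin_altschul(c(match = 1, mismatch = 1,
                                       gap_open = 5, gap_extend = 2)),
               "invalid scoring")
})

test_that("E-values decrease monotonically in score", {
  p <- solve_karlin_altschul()
  e <- ka_evalue(seq(10, 100, by = 10), m = 70, n = 1e6, p)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > 0))
})

test_that("Smith-Waterman equals the quadratic DP oracle on random pairs", {
  set.seed(8)
  for (rep in 1:50) {
    a <- random_dna(sample(8:30, 1))
    b <- random_dna(sample(8:30, 1))
    expect_equal(smith_waterman(a, b)$score, oracle_sw_score(a, b),
                 info = paste(a, b))
  }
})

test_that("Smith-Waterman alignment statistics are self-consistent", {
  al <- smith_waterman("ACGTACGTGG", "ACGTACGTGG")
  expect_equal(al$score, 20)
  expect_equal(al$identity_pct, 100)
  expect_equal(al$aligned_cols, 10)
  al2 <- smith_waterman("AAAATTTT", "GGGGCCCC")
  expect_equal(al2$score, 0)
})

test_that("homology search finds verbatim planted copies", {
  set.seed(13)
  params <- solve_karlin_altschul()
  pre <- random_dna(70)
  g <- random_dna(20000)
  g_plant <- paste0(substr(g, 1, 5000), pre, substr(g, 5071, 20000))
  hits <- premir_homology_search(pre, list(spX = c(chr1 = g_plant)), params)
  expect_gte(nrow(hits), 1)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$identity_pct, 100)
  expect_lt(best$e_value, 1e-5)
  expect_equal(best$g_start, 5001) # 1-based genomic start
  # reverse-strand planting
  g_rc <- paste0(substr(g, 1, 5000), revcomp(pre), substr(g, 5071, 20000))
  hits_rc <- premir_homology_search(pre, list(spX = c(chr1 = g_rc)), params)
  expect_true(any(hits_rc$strand == "-"))
})

test_that("identity filter rejects diverged copies independently of score", {
  set.seed(14)
  pre <- random_dna(70)
  g <- paste0(random_dna(3000), pre, random_dna(3000))
  params <- solve_karlin_altschul()
  hits_loose <- premir_homology_search(pre, list(spX = c(chr1 = g)), params,
                                       min_identity = 50)
  hits_tight <- premir_homology_search(pre, list(spX = c(chr1 = g)), params,
                                       min_identity = 100.5)
  expect_gte(nrow(hits_loose), 1)
  expect_equal(nrow(hits_tight), 0)
})

test_that("no significant hits arise in unrelated random genomes", {
  set.seed(15)
  params <- solve_karlin_altschul()
  n_hit <- 0
  for (i in 1:20) {
    hits <- premir_homology_search(random_dna(70),
                                   list(spX = c(chr1 = random_dna(20000))),
                                   params)
    if (nrow(hits)) n_hit <- n_hit + 1
  }
  expect_lte(n_hit, 1) # chance hits at e <= 1e-5 are (nearly) absent
})

test_that("upset sets partition the seed groups", {
  set.seed(77)
  catalog <- data.frame(
    mirna_id = paste0("m", 1:6),
    species_id = c("spA", "spB", "spC", "spA", "spB", "spC"),
    mature_seq = as_rna(c(
      paste0("A", "GGGGCCCC", random_dna(13)),
      paste0("A", "GGGGCCCC", random_dna(13)),
      paste0("A", "GGGGCCCC", random_dna(13)),
      paste0("A", "AAAACCCC", random_dna(13)),
      paste0("A", "TTTTCCCC", random_dna(13)),
      paste0("A", "CCCCAAAA", random_dna(13)))),
    stringsAsFactors = FALSE)
  # first three share one seed; the others are species-private
  catalog$mature_seq <- substr(catalog$mature_seq, 1, 22)
  cl <- seed_match_classes(catalog)
  up <- upset_sets(cl)
  expect_equal(sum(up$count), length(unique(cl$group_id)))
  expect_equal(up$count[up$species_set == "spA,spB,spC"], 1L)
  expect_equal(sum(up$count[up$species_set %in% c("spA", "spB", "spC")]), 3L)
})
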