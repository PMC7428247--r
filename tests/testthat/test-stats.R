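test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N=10, D=4, n=5, x=4: E = 2, RF = 2, p_over = 6/252
  universe <- paste0("g", 1:10)
  l2 <- paste0("g", 1:4)
  l1 <- paste0("g", c(1:4, 10))
  r <- hypergeom_enrichment(l1, l2, universe)
  expect_equal(r$x, 4L)
  expect_equal(r$E, 2)
  expect_equal(r$RF, 2)
  oracle <- oracle_hyper_tails(10, 4, 5, 4)
  expect_equal(r$p_over, oracle$p_over, tolerance = 1e-12)
  expect_equal(r$p_under, oracle$p_under, tolerance = 1e-12)
  expect_equal(r$p_over, 6 / 252, tolerance = 1e-12)
})

test_that("representation factor is 1 at the null expectation and 0 when disjoint", {
  universe <- paste0("g", 1:20)
  r <- hypergeom_enrichment(paste0("g", 1:10), paste0("g", c(1:5, 11:15)),
                            universe)
  expect_equal(r$RF, 1) # x = nD/N = 5 exactly
  r2 <- hypergeom_enrichment(paste0("g", 1:10), paste0("g", 11:20), universe)
  expect_equal(r2$RF, 0)
  expect_lt(r2$p_under, 0.01) # strong depletion signal
})

test_that("tail probabilities share the observed point mass", {
  set.seed(51)
  for (rep in 1:20) {
    N <- sample(8:40, 1)
    uni <- paste0("g", 1:N)
    l1 <- sample(uni, sample(2:N, 1))
    l2 <- sample(uni, sample(2:N, 1))
    r <- hypergeom_enrichment(l1, l2, uni)
    expect_gte(r$p_over + r$p_under, 1)
    expect_true(r$p_over > 0 && r$p_over <= 1)
  }
})

test_that("ids outside the universe are an error", {
  expect_error(hypergeom_enrichment(c("a", "zzz"), "a", c("a", "b")),
               "outside the universe")
  expect_error(hypergeom_enrichment("a", "a", character()), "empty universe")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  # independent step-up oracle: min over j >= i of p_(j) * m / j
  set.seed(52)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj_sorted <- rev(cummin(rev(sorted * m / seq_len(m))))
    oracle <- numeric(m)
    oracle[o] <- pmin(adj_sorted, 1)
    expect_equal(bh_adjust(p), oracle)
  }
})

test_that("Welch t-test matches the hand-computed example", {
  r <- expression_ttest(c(1, 2, 3), c(2, 3, 4), transform = "none")
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-9)
  r2 <- expression_ttest(c(5, 5, 5), c(5, 5, 5), transform = "none")
  expect_equal(r2$t, 0)
  expect_equal(r2$p_value, 1)
})

test_that("expression comparison detects a planted 4x ratio", {
  set.seed(53)
  sig <- 0L
  for (rep in 1:50) {
    ls <- rnbinom(30, size = 1 / 0.3, mu = 50)
    hom <- rnbinom(50, size = 1 / 0.3, mu = 200)
    if (expression_ttest(ls, hom)$p_value < 0.001) sig <- sig + 1L
  }
  expect_gte(sig / 50, 0.95)
})

test_that("reciprocal best hits require reciprocity and pass E-value", {
  set.seed(54)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  prot <- function(n) paste(sample(aa, n, TRUE), collapse = "")
  p1 <- prot(120)
  p2 <- prot(120)
  set_a <- c(a1 = p1, a2 = p2)
  set_b <- c(b1 = p1, b2 = prot(120))
  rbh <- reciprocal_best_hits(set_a, set_b)
  expect_true(any(rbh$id_a == "a1" & rbh$id_b == "b1"))
  # reciprocity: a's best is b, but b's best is c -> no (a, b) pair
  near <- function(s, k) { # s with k substitutions
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (i in pos) ch[i] <- sample(setdiff(aa, ch[i]), 1)
    paste(ch, collapse = "")
  }
  set_a2 <- c(a = near(p1, 30), c = p1)
  set_b2 <- c(b = p1)
  rbh2 <- reciprocal_best_hits(set_a2, set_b2)
  expect_false(any(rbh2$id_a == "a"))
  expect_true(any(rbh2$id_a == "c" & rbh2$id_b == "b"))
})

test_that("diverged one-to-one orthologues are recovered", {
  set.seed(55)
  aa <- LETTERS[1:20]
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    ch[hit] <- sample(aa, sum(hit), TRUE)
    paste(ch, collapse = "")
  }
  orig <- replicate(12, paste(sample(aa, 100, TRUE), collapse = ""))
  set_a <- setNames(orig, paste0("a", 1:12))
  set_b <- setNames(vapply(orig, mutate, "", rate = 0.2), paste0("b", 1:12))
  rbh <- reciprocal_best_hits(set_a, set_b)
  correct <- sum(sub("a", "", rbh$id_a) == sub("b", "", rbh$id_b))
  expect_gte(correct / 12, 0.95)
})

test_that("the enrichment battery adjusts within the battery", {
  set.seed(56)
  uni <- paste0("g", 1:200)
  targets <- list(spA = sample(uni, 50), spB = sample(uni, 50))
  lists <- list(young = sample(uni, 40), caste = sample(uni, 40))
  b <- enrichment_battery(targets, lists, uni)
  expect_equal(nrow(b), 4)
  expect_equal(b$p_adj, p.adjust(b$p_over, "BH"))
  expect_true(all(b$RF >= 0))
  expect_true(all(abs(b$RF - b$x / b$E) < 1e-12))
})
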