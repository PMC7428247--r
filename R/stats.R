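# The statistical battery: hypergeometric enrichment with representation
# factors, BH correction, the expression t-test, and reciprocal-best-hit
# orthologue matching for cross-species list comparisons.

#' Hypergeometric over/under-enrichment of two gene lists
#'
#' With universe size `N`, list sizes `n` and `D` and overlap `x`, the
#' expected overlap is `E = n D / N` and the representation factor is
#' `RF = x / E`. `p_over = P[X >= x]` and `p_under = P[X <= x]` for
#' `X ~ Hypergeometric(N, D, n)`, computed with `phyper` in log space.
#'
#' @param list1,list2 character vectors of ids (must be subsets of
#'   `universe`)
#' @param universe character vector of all ids
#' @return one-row data.frame: x, n, D, N, E, RF, p_over, p_under
#' @export
hypergeom_enrichment <- function(list1, list2, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  list1 <- unique(list1)
  list2 <- unique(list2)
  out1 <- setdiff(list1, universe)
  out2 <- setdiff(list2, universe)
  if (length(out1) || length(out2))
    stop("ids outside the universe: ",
         paste(head(c(out1, out2), 10), collapse = ", "))
  N <- length(universe)
  n <- length(list1)
  D <- length(list2)
  x <- length(intersect(list1, list2))
  E <- n * D / N
  p_over <- exp(phyper(x - 1, D, N - D, n, lower.tail = FALSE, log.p = TRUE))
  p_under <- exp(phyper(x, D, N - D, n, lower.tail = TRUE, log.p = TRUE))
  data.frame(x = x, n = n, D = D, N = N, E = E,
             RF = if (E > 0) x / E else NA_real_,
             p_over = p_over, p_under = p_under)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")`); output
#' order matches input.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Compare expression of lineage-specific vs homologous miRNAs
#'
#' Welch two-sample t-test, by default on `log2(RPM + 1)`-transformed
#' values (small-RNA counts are heavy-tailed; set `transform = "none"` for
#' the raw scale). `alternative = "less"` tests the directional hypothesis
#' that lineage-specific miRNAs are expressed lower.
#'
#' @param ls_expr expression of lineage-specific miRNAs (RPM)
#' @param hom_expr expression of homologous miRNAs (RPM)
#' @param transform `"log2"` or `"none"`
#' @param alternative `"two.sided"` (default) or `"less"`
#' @return list with t, df, p_value, estimate (group means on the analysis
#'   scale)
#' @export
expression_ttest <- function(ls_expr, hom_expr,
                             transform = c("log2", "none"),
                             alternative = c("two.sided", "less")) {
  transform <- match.arg(transform)
  alternative <- match.arg(alternative)
  if (length(ls_expr) < 2 || length(hom_expr) < 2)
    stop("each group needs at least 2 values")
  a <- if (transform == "log2") log2(ls_expr + 1) else ls_expr
  b <- if (transform == "log2") log2(hom_expr + 1) else hom_expr
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = NA_real_, p_value = 1,
                estimate = c(mean(a), mean(b))))
  tt <- t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, estimate = unname(tt$estimate))
}

#' Reciprocal-best-hit orthologue pairs between two sequence sets
#'
#' Pairs (a, b) where b is a's best local-alignment hit and a is b's, both
#' with Karlin-Altschul E-value at most `max_evalue`. Scoring is a simple
#' identity matrix over the residue alphabet (config), applied through the
#' package's affine Smith-Waterman.
#'
#' @param set_a,set_b named character vectors of sequences
#' @param scoring match/mismatch/gap scoring for the alignment
#' @param alphabet_size residue alphabet size for the Karlin-Altschul solve
#'   (20 for protein)
#' @param max_evalue reciprocal-hit E-value threshold
#' @return data.frame (id_a, id_b, score_ab, evalue)
#' @export
reciprocal_best_hits <- function(set_a, set_b,
                                 scoring = c(match = 5, mismatch = -2,
                                             gap_open = 6, gap_extend = 2),
                                 alphabet_size = 20L, max_evalue = 1e-5) {
  params <- solve_karlin_altschul(scoring,
                                  base_freqs = rep(1 / alphabet_size,
                                                   alphabet_size))
  na <- length(set_a)
  nb <- length(set_b)
  scores <- matrix(0, na, nb, dimnames = list(names(set_a), names(set_b)))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      al <- .sw_align_cpp(set_a[[i]], set_b[[j]], scoring[["match"]],
                          scoring[["mismatch"]], scoring[["gap_open"]],
                          scoring[["gap_extend"]])
      scores[i, j] <- al$score
    }
  }
  rows <- list()
  for (i in seq_len(na)) {
    j <- which.max(scores[i, ])
    if (which.max(scores[, j]) != i) next
    ev <- ka_evalue(scores[i, j], nchar(set_a[[i]]),
                    sum(nchar(set_b)), params)
    if (ev <= max_evalue)
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = names(set_a)[i], id_b = names(set_b)[j],
        score_ab = scores[i, j], evalue = ev, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id_a = character(), id_b = character(),
                      score_ab = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  `rownames<-`(do.call(rbind, rows), NULL)
}

#' Run an enrichment battery over named gene lists
#'
#' One hypergeometric test per (target list, gene list) pair, with BH
#' adjustment of the over-enrichment p-values within the battery.
#'
#' @param target_lists named list of character vectors (e.g. per-species
#'   targets of lineage-specific miRNAs)
#' @param gene_lists named list of character vectors (e.g. young genes,
#'   caste-biased genes)
#' @param universes either a single character vector shared by all tests or
#'   a named list parallel to `target_lists`
#' @return data.frame with one row per pair: target_list, gene_list, x, n,
#'   D, N, E, RF, p_over, p_under, p_adj
#' @export
enrichment_battery <- function(target_lists, gene_lists, universes) {
  rows <- list()
  for (tn in names(target_lists)) {
    uni <- if (is.list(universes)) universes[[tn]] else universes
    for (gn in names(gene_lists)) {
      r <- hypergeom_enrichment(target_lists[[tn]], gene_lists[[gn]], uni)
      r <- cbind(data.frame(target_list = tn, gene_list = gn,
                            stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- `rownames<-`(do.call(rbind, rows), NULL)
  out$p_adj <- bh_adjust(out$p_over)
  out
}
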