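# End-to-end orchestration: discovery filters -> homology classification ->
# localization -> target prediction -> gene age -> enrichment battery and
# the per-species statistical tests.

#' Pipeline settings
#'
#' @param randfold_shuffles dinucleotide shuffles per candidate in the
#'   structure test (99 resolves the 0.05 threshold at 1/100 granularity)
#' @param min_arm_reads minimum reads on each hairpin arm
#' @param randfold_alpha structure-test threshold (strict `<`)
#' @param seed_end last 1-based seed position
#' @param scoring nucleotide alignment scoring for homology searches
#' @param min_identity,max_evalue,word_size pre-miR homology-search settings
#' @param target target-prediction settings from [target_config()]
#' @return named list of settings
#' @export
pipeline_config <- function(randfold_shuffles = 99L, min_arm_reads = 5L,
                            randfold_alpha = 0.05, seed_end = 8L,
                            scoring = c(match = 2, mismatch = -3,
                                        gap_open = 5, gap_extend = 2),
                            min_identity = 50, max_evalue = 1e-5,
                            word_size = 11L, target = target_config()) {
  as.list(environment())
}

# substring of a chromosome for a 0-based half-open locus, strand-aware
locus_seq <- function(genome, chrom, start, end, strand) {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Run discovery filters for one species
#'
#' QC + exact mapping + arm support + contaminant screen + structure test,
#' then the retention rule. The structure test is only run for candidates
#' that pass the cheaper filters (the retention decision is identical).
#'
#' @param reads read data.frame (`sequence`, `count`)
#' @param genome named character vector of chromosomes
#' @param premirs candidate hairpin loci (chrom, start, end, id, strand)
#' @param contaminants named character vector (may be empty)
#' @param config [pipeline_config()]
#' @return candidate table with support counts, contaminant flag,
#'   randfold p, retention flag and reject reason; mapping fraction in
#'   attribute `mapping_fraction`
#' @export
discover_candidates <- function(reads, genome, premirs, contaminants,
                                config = pipeline_config()) {
  rq <- qc_reads(reads)
  hits <- map_reads_exact(rq, genome)
  n <- nrow(premirs)
  out <- data.frame(id = premirs$id, chrom = premirs$chrom,
                    start = premirs$start, end = premirs$end,
                    strand = premirs$strand,
                    mature_count = 0L, star_count = 0L,
                    contaminant_hit = FALSE, randfold_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pm <- premirs[i, ]
    arms <- locate_arms(pm, hits)
    if (!is.null(arms)) {
      cs <- count_support(hits, pm, arms$mature, arms$star)
      out$mature_count[i] <- cs$mature_count
      out$star_count[i] <- cs$star_count
    }
    pre_seq <- locus_seq(genome, pm$chrom, pm$start, pm$end, pm$strand)
    out$contaminant_hit[i] <- contaminant_screen(pre_seq, contaminants,
                                                 scoring = config$scoring)
    if (!out$contaminant_hit[i] &&
        out$mature_count[i] >= config$min_arm_reads &&
        out$star_count[i] >= config$min_arm_reads) {
      out$randfold_p[i] <- randfold_test(pre_seq, config$randfold_shuffles)
    }
  }
  out <- apply_novel_filters(out, config$min_arm_reads, config$randfold_alpha)
  attr(out, "mapping_fraction") <- attr(hits, "mapping_fraction")
  out
}

#' Run the full comparative pipeline on a synthetic world
#'
#' @param world result of [generate_world()]
#' @param config [pipeline_config()]
#' @param verbose print progress
#' @return list with per-species candidate tables, the cross-species
#'   homology calls (with the per-species tier summary), localization
#'   summaries and intragenic tests, predicted target pairs, gene ages, the
#'   enrichment battery and expression t-tests
#' @export
run_pipeline <- function(world, config = pipeline_config(), verbose = FALSE) {
  species <- world$species
  say <- function(...) if (verbose) message(...)

  # discovery filters per species -----------------------------------------
  candidates <- list()
  rpm <- list()
  for (sp in species) {
    say("discovery: ", sp)
    candidates[[sp]] <- discover_candidates(
      world$reads[[sp]], world$genomes[[sp]], world$premirs[[sp]],
      world$contaminants, config)
    total <- sum(qc_reads(world$reads[[sp]])$count)
    cnt <- candidates[[sp]]$mature_count
    rpm[[sp]] <- setNames(cnt / total * 1e6, candidates[[sp]]$id)
  }

  # cross-species homology classification ----------------------------------
  say("homology classification")
  retained_ids <- unlist(lapply(candidates, function(d) d$id[d$retained]),
                         use.names = FALSE)
  cat_ret <- world$catalog[world$catalog$mirna_id %in% retained_ids, ,
                           drop = FALSE]
  cat_ret$expression <- unlist(rpm, use.names = TRUE)[
    paste0(cat_ret$species_id, ".", cat_ret$mirna_id)]
  params <- solve_karlin_altschul(config$scoring)
  calls <- classify_all(cat_ret, world$known_mirs, world$genomes, params,
                        config$seed_end, config$min_identity,
                        config$max_evalue, config$word_size)

  # localization ------------------------------------------------------------
  say("localization")
  localization <- list()
  chi2 <- list()
  intragenic_flags <- list()
  for (sp in species) {
    feats <- rbind(world$genes[[sp]],
                   world$repeats[[sp]][, c("chrom", "start", "end", "strand",
                                           "kind", "gene_id")])
    prem <- candidates[[sp]][candidates[[sp]]$retained,
                             c("id", "chrom", "start", "end", "strand")]
    localization[[sp]] <- summarize_localization(prem, feats)
    per <- localization[[sp]]$per_premir
    ls_flag <- calls$lineage_specific[match(per$premir_id, calls$mirna_id)]
    intragenic_flags[[sp]] <- data.frame(
      mirna_id = per$premir_id, intragenic = per$intragenic,
      lineage_specific = ls_flag, stringsAsFactors = FALSE)
    chi2[[sp]] <- if (nrow(per) >= 4 && length(unique(ls_flag)) == 2)
      intra_inter_chi2(ls_flag, per$intragenic) else NULL
  }
  pooled <- do.call(rbind, intragenic_flags)
  chi2$pooled <- intra_inter_chi2(pooled$lineage_specific, pooled$intragenic)

  # target prediction for lineage-specific miRNAs ---------------------------
  say("target prediction")
  target_pairs <- list()
  utrs_by_sp <- list()
  for (sp in species) {
    genes_sp <- world$genes[[sp]]
    genes_sp <- genes_sp[genes_sp$kind == "gene", , drop = FALSE]
    utrs <- list()
    for (r in seq_len(nrow(genes_sp))) {
      u <- extract_utr_proxy(genes_sp[r, ], world$genomes[[sp]],
                             config$target$flank_len)
      if (!is.null(u)) utrs[[length(utrs) + 1L]] <- u
    }
    utrs_by_sp[[sp]] <- utrs
    ls_ids <- calls$mirna_id[calls$lineage_specific & calls$species_id == sp]
    mir_df <- data.frame(
      mirna_id = ls_ids,
      mature_seq = world$catalog$mature_seq[match(ls_ids,
                                                  world$catalog$mirna_id)],
      stringsAsFactors = FALSE)
    pt <- predict_targets(mir_df, utrs, config$target)
    target_pairs[[sp]] <- pt$pairs
  }

  # gene ages ----------------------------------------------------------------
  say("gene ages")
  ladder <- clade_ladder(world$ladder)
  ages <- list()
  for (sp in species) {
    gene_ids <- world$genes[[sp]]$gene_id[world$genes[[sp]]$kind == "gene"]
    ages[[sp]] <- assign_gene_ages(gene_ids, world$orthogroups, ladder)
  }

  # enrichment battery -------------------------------------------------------
  say("enrichment battery")
  target_lists <- lapply(target_pairs, function(p) unique(p$gene_id))
  battery_rows <- list()
  for (sp in species) {
    uni <- ages[[sp]]$gene_id
    young <- ages[[sp]]$gene_id[ages[[sp]]$age_label == "Unique"]
    gl <- list(young = young, caste = world$caste_lists[[sp]],
               selection = world$selection_lists[[sp]])
    b <- enrichment_battery(setNames(list(target_lists[[sp]]), sp), gl, uni)
    battery_rows[[sp]] <- b[, setdiff(names(b), "p_adj")]
  }
  battery <- `rownames<-`(do.call(rbind, battery_rows), NULL)
  battery$p_adj <- bh_adjust(battery$p_over)

  # expression comparison -----------------------------------------------------
  ttests <- list()
  for (sp in species) {
    d <- calls[calls$species_id == sp, ]
    if (sum(d$lineage_specific) >= 2 && sum(!d$lineage_specific) >= 2)
      ttests[[sp]] <- expression_ttest(d$expression[d$lineage_specific],
                                       d$expression[!d$lineage_specific])
  }

  list(candidates = candidates, calls = calls,
       summary = attr(calls, "summary"), localization = localization,
       chi2 = chi2, target_pairs = target_pairs, ages = ages,
       battery = battery, ttests = ttests, rpm = rpm)
}

#' Score pipeline output against the planted truth
#'
#' @param result output of [run_pipeline()]
#' @param world the world the pipeline ran on
#' @return list with lineage-specific sensitivity and specificity (over
#'   retained non-decoy candidates), tier recovery of the planted
#'   premir-homolog subclass, estimated vs realized enrichment RF per
#'   species, and the young-gene battery p-values
#' @export
evaluate_recovery <- function(result, world) {
  truth <- world$truth$catalog
  calls <- result$calls
  m <- match(calls$mirna_id, truth$mirna_id)
  true_ls <- startsWith(truth$true_class[m], "lineage_specific")
  pred_ls <- calls$lineage_specific
  not_decoy <- !startsWith(truth$true_class[m], "decoy")
  tp <- sum(true_ls & pred_ls & not_decoy)
  fn <- sum(true_ls & !pred_ls & not_decoy)
  tn <- sum(!true_ls & !pred_ls & not_decoy)
  fp <- sum(!true_ls & pred_ls & not_decoy)

  hom_truth <- truth$true_class[m] == "lineage_specific:premir_homolog"
  hom_rec <- if (any(hom_truth))
    mean(calls$tier[hom_truth] == "premir_homolog") else NA_real_

  young_rows <- result$battery[result$battery$gene_list == "young", ]
  rf_est <- setNames(young_rows$RF, young_rows$target_list)
  rf_true <- world$truth$realized_rf[names(rf_est)]

  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       homolog_tier_recovery = hom_rec,
       rf_estimated = rf_est, rf_realized = rf_true,
       rf_abs_error = abs(rf_est - rf_true),
       young_p_over = setNames(young_rows$p_over, young_rows$target_list))
}
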