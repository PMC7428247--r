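# Synthetic multi-species world with planted homology structure, expression
# effects, genomic context and target-age enrichment. Every downstream stage
# of the pipeline can be scored against the truth manifest returned here.

#' Configuration for a synthetic world
#'
#' Defaults emulate the study conditions of a six-species brain small-RNA
#' comparison: ~60 shared seed families plus 30 lineage-specific miRNAs per
#' species expressed at a quarter of the shared mean, placement dominated by
#' intergenic and intronic loci, and lineage-specific targets enriched among
#' young ("Unique") genes at a representation factor of 1.8.
#'
#' @param n_species number of focal species
#' @param genome_length genome length per species (nt)
#' @param n_genes gene models per species
#' @param n_shared_mirna_families shared seed families across the clade
#' @param n_lineage_specific_per_species lineage-specific miRNAs per species
#' @param lineage_specific_expression_ratio mean expression of
#'   lineage-specific relative to shared miRNAs (0 < ratio < 1)
#' @param planted_target_rf_young representation factor of young genes
#'   among lineage-specific targets (>= 1)
#' @param gene_age_distribution named probabilities over age labels
#'   (ladder labels plus "Unique"); must sum to 1
#' @param rng_seed integer seed; the world is a deterministic function of
#'   the configuration
#' @param carriage probability a shared family is carried by a species
#' @param unique_fraction fraction of lineage-specific miRNAs with no
#'   genomic homologue anywhere (the rest get a planted diverged pre-miR
#'   copy in one other genome)
#' @param placement category proportions for pre-miR loci
#'   (intergenic/intron/exon/repeat)
#' @param nb_dispersion negative-binomial dispersion of read counts
#' @param star_thinning binomial thinning rate for star-arm reads
#' @param shared_expression_mean mean mature read count of shared miRNAs
#' @param n_known known insect mature miRNAs in the reference set
#' @param known_family_fraction fraction of shared families whose seed
#'   matches a known miRNA
#' @param n_targets_per_species planted lineage-specific target genes per
#'   species
#' @param n_contaminants rRNA/tRNA-like contaminant sequences
#' @param n_decoys_per_species contaminant-derived decoy hairpins per
#'   species
#' @param n_copy_accessions rows of the miRNA copy-number matrix
#' @return named list of settings (class `world_config`)
#' @export
world_config <- function(n_species = 6L, genome_length = 500000L,
                         n_genes = 400L, n_shared_mirna_families = 60L,
                         n_lineage_specific_per_species = 30L,
                         lineage_specific_expression_ratio = 0.25,
                         planted_target_rf_young = 1.8,
                         gene_age_distribution = c(
                           Vertebrata = 0.35, Metazoa = 0.10,
                           Arthropoda = 0.08, Insecta = 0.07,
                           Holometabola = 0.06, Hymenoptera = 0.06,
                           Aculeata = 0.04, Apoidea = 0.04, Unique = 0.20),
                         rng_seed = 1L, carriage = 0.85,
                         unique_fraction = 0.5,
                         placement = c(intergenic = 0.45, intron = 0.35,
                                       exon = 0.05, repeats = 0.15),
                         nb_dispersion = 0.3, star_thinning = 0.2,
                         shared_expression_mean = 200,
                         n_known = 40L, known_family_fraction = 0.7,
                         n_targets_per_species = 100L, n_contaminants = 5L,
                         n_decoys_per_species = 2L,
                         n_copy_accessions = 50L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$gene_age_distribution) - 1) > 1e-8)
    stop("gene_age_distribution must sum to 1")
  counts <- c(n_species, genome_length, n_genes, n_shared_mirna_families,
              n_lineage_specific_per_species, n_known, n_targets_per_species)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (lineage_specific_expression_ratio <= 0 ||
      lineage_specific_expression_ratio >= 1)
    stop("lineage_specific_expression_ratio must be in (0, 1)")
  if (planted_target_rf_young < 1)
    stop("planted_target_rf_young must be >= 1")
  structure(cfg, class = "world_config")
}

# draw a previously unused 7-mer seed, updating the used-seed registry env
draw_seed <- function(registry) {
  repeat {
    s <- random_dna(7)
    if (is.null(registry$used[[s]])) {
      registry$used[[s]] <- TRUE
      return(s)
    }
  }
}

# mature sequence (DNA letters) with the given seed at 1-based positions 2-8
mature_with_seed <- function(seed, len = 22L) {
  m <- seq_chars(random_dna(len))
  m[2:8] <- seq_chars(seed)
  paste(m, collapse = "")
}

# mutate k positions of a sequence, optionally protecting an index range
mutate_seq <- function(seq, k, protect = integer()) {
  ch <- seq_chars(seq)
  cand <- setdiff(seq_along(ch), protect)
  pos <- sample(cand, min(k, length(cand)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# hairpin precursor from a mature arm: pad + mature + loop + star + pad,
# star = reverse complement of the mature with two point mutations
build_premir <- function(mature, loop_len = 12L, pad = 4L) {
  star <- mutate_seq(revcomp(mature), 2L)
  list(seq = paste0(random_dna(pad), mature, random_dna(loop_len), star,
                    random_dna(pad)),
       mature_rel = c(start = pad, end = pad + nchar(mature)),
       star_rel = c(start = pad + nchar(mature) + loop_len,
                    end = pad + nchar(mature) + loop_len + nchar(star)))
}

#' Select planted target genes at a prescribed representation factor
#'
#' Draws `n_targets` genes so that the expected young-gene overlap `x`
#' satisfies `x / E = rf_target` with `E = n D / N` (`D` young genes in a
#' universe of `N`); each selected gene is assigned one lineage-specific
#' miRNA. The realized representation factor is attached as attribute
#' `realized_rf`.
#'
#' @param gene_ids universe of gene ids
#' @param age_labels age label per gene (same order)
#' @param mirna_ids lineage-specific miRNA ids to spread over the targets
#' @param rf_target representation factor for young ("Unique") genes
#' @param n_targets number of target genes to select
#' @return data.frame (gene_id, mirna_id, is_young), attr `realized_rf`
#' @export
plant_enrichment <- function(gene_ids, age_labels, mirna_ids, rf_target,
                             n_targets) {
  N <- length(gene_ids)
  young <- gene_ids[age_labels == "Unique"]
  D <- length(young)
  if (D == 0) stop("no young genes to enrich")
  p_young <- rf_target * D / N
  if (p_young > 1)
    stop("infeasible rf_target: rf * D / N = ", round(p_young, 3), " > 1")
  if (rf_target == 1) {
    # null case: a uniform subset, placement independent of gene age
    sel <- sample(gene_ids, n_targets)
    x <- sum(sel %in% young)
    is_young <- sel %in% young
  } else {
    x <- rbinom(1L, n_targets, p_young) # E[x] = rf * n * D / N
    if (x > D || (n_targets - x) > (N - D))
      stop("infeasible rf_target: required overlap exceeds available genes")
    sel <- c(sample(young, x), sample(setdiff(gene_ids, young), n_targets - x))
    is_young <- c(rep(TRUE, x), rep(FALSE, n_targets - x))
  }
  out <- data.frame(gene_id = sel,
                    mirna_id = sample(mirna_ids, n_targets, replace = TRUE),
                    is_young = is_young,
                    stringsAsFactors = FALSE)
  attr(out, "realized_rf") <- (x / n_targets) * N / D
  out
}

# sequential allocator over the intergenic slack region of a genome
make_allocator <- function(start, limit) {
  env <- new.env(parent = emptyenv())
  env$cursor <- start
  function(len) {
    pos <- env$cursor + sample(10:50, 1)
    if (pos + len > limit)
      stop("genome too small to place requested features; increase ",
           "genome_length to at least ", pos + len + 1000L)
    env$cursor <- pos + len
    pos
  }
}

#' Generate a synthetic multi-species world
#'
#' Builds per-species genomes with gene models and repeats, a miRNA
#' complement with planted shared seed families and lineage-specific
#' miRNAs (with lower expression), small-RNA read sets, orthogroups
#' inducing a gene-age distribution, planted seed-complementary target
#' sites enriched downstream of young genes, a phylogeny with sociality
#' scores and a copy-number matrix — plus the truth manifest against which
#' recovery is measured. Deterministic given `config$rng_seed`.
#'
#' @param config a [world_config()]
#' @return list with genomes, genes, repeats, premirs, reads, catalog,
#'   known_mirs, contaminants, orthogroups, ladder, tree, sociality,
#'   copy_matrix, caste_lists, selection_lists, truth, config
#' @export
generate_world <- function(config = world_config()) {
  set.seed(config$rng_seed)
  nsp <- config$n_species
  species <- sprintf("sp%02d", seq_len(nsp))

  # phylogeny, sociality, copy-number matrix ------------------------------
  tree <- ape::rcoal(nsp, tip.label = species)
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  sociality <- setNames(sample(0:3, nsp, replace = TRUE), species)
  if (length(unique(sociality)) == 1L)
    sociality[1] <- (sociality[1] + 1) %% 4
  acc <- sprintf("acc%03d", seq_len(config$n_copy_accessions))
  copy_matrix <- matrix(0L, config$n_copy_accessions, nsp,
                        dimnames = list(acc, species))
  half <- floor(config$n_copy_accessions / 2)
  for (i in seq_len(config$n_copy_accessions)) {
    copy_matrix[i, ] <- if (i == 1L) {
      as.integer(1 + sociality) # planted monotone relation
    } else if (i <= half + 1L) {
      rep(sample(1:2, 1), nsp) # conserved single/double copy
    } else {
      as.integer(rpois(nsp, 1.3))
    }
  }

  # seeds, known set, shared families -------------------------------------
  registry <- new.env(parent = emptyenv())
  registry$used <- new.env(parent = emptyenv())
  known_seeds <- replicate(config$n_known, draw_seed(registry))
  known_mirs <- setNames(as_rna(vapply(known_seeds, mature_with_seed,
                                       character(1))),
                         sprintf("known_mir_%03d", seq_len(config$n_known)))
  nfam <- config$n_shared_mirna_families
  n_known_fam <- round(config$known_family_fraction * nfam)
  fam_seed <- c(known_seeds[seq_len(min(n_known_fam, config$n_known))],
                replicate(max(0, nfam - n_known_fam), draw_seed(registry)))
  fam_carried <- lapply(seq_len(nfam), function(f) {
    carried <- species[runif(nsp) < config$carriage]
    if (length(carried) < 2) carried <- sample(species, 2)
    carried
  })

  # per-species containers -------------------------------------------------
  genomes <- list()
  genes <- list()
  repeats <- list()
  premirs <- list()
  reads <- list()
  catalog_rows <- list()
  allocators <- list()
  gene_ages <- list()
  flank_iv <- list() # per species: gene_id -> c(start, end) of the flank
  contaminants <- setNames(replicate(config$n_contaminants, random_dna(120)),
                           c(sprintf("rRNA_%d", seq_len(ceiling(config$n_contaminants / 2))),
                             sprintf("tRNA_%d", seq_len(floor(config$n_contaminants / 2)))))

  exon_len <- 180L; intron_len <- 140L
  gene_len <- 2L * exon_len + intron_len
  flank_len <- 500L
  age_labels_all <- names(config$gene_age_distribution)

  for (sp in species) {
    L <- config$genome_length
    gseq <- seq_chars(random_dna(L))
    cursor <- 0L
    grows <- list()
    fl <- list()
    for (g in seq_len(config$n_genes)) {
      gap <- sample(30:130, 1)
      strand <- sample(c("+", "-"), 1)
      block_start <- cursor + gap
      if (strand == "+") {
        gstart <- block_start
        fstart <- gstart + gene_len
      } else {
        fstart <- block_start
        gstart <- fstart + flank_len
      }
      gend <- gstart + gene_len
      cursor <- block_start + gene_len + flank_len
      if (cursor > L - 2000L)
        stop("genome too small for ", config$n_genes, " gene models; ",
             "increase genome_length")
      gid <- sprintf("%s_g%04d", sp, g)
      grows[[g]] <- data.frame(
        chrom = "chr1",
        start = c(gstart, gstart, gstart + exon_len + intron_len),
        end = c(gend, gstart + exon_len, gend),
        strand = strand, kind = c("gene", "exon", "exon"), gene_id = gid,
        stringsAsFactors = FALSE)
      fl[[gid]] <- c(start = if (strand == "+") fstart else fstart,
                     end = if (strand == "+") fstart + flank_len else
                       fstart + flank_len)
    }
    gdf <- do.call(rbind, grows)
    gdf <- rbind(gdf, derive_introns(gdf[gdf$kind == "exon", ]))
    alloc <- make_allocator(cursor + 100L, L - 100L)
    # repeats in the slack region; half TE-labelled, half uncharacterized
    rep_names <- c("LINE/R2", "LTR/Gypsy", "DNA/TcMar", "Unknown",
                   "Simple_repeat", "rnd-1_family-42")
    rrows <- lapply(seq_len(30), function(r) {
      len <- sample(120:250, 1)
      pos <- alloc(len)
      data.frame(chrom = "chr1", start = pos, end = pos + len,
                 name = sample(rep_names, 1), strand = sample(c("+", "-"), 1),
                 stringsAsFactors = FALSE)
    })
    rdf <- do.call(rbind, rrows)
    is_te <- grepl("LINE|SINE|LTR|DNA|Helitron|RC|Penelope", rdf$name)
    rdf$kind <- ifelse(is_te, "transposable_element", "uncharacterized_repeat")
    rdf$gene_id <- ""

    genomes[[sp]] <- gseq # still a char vector; finalized below
    genes[[sp]] <- gdf
    repeats[[sp]] <- rdf
    allocators[[sp]] <- alloc
    flank_iv[[sp]] <- fl
    gene_ages[[sp]] <- data.frame(
      gene_id = sprintf("%s_g%04d", sp, seq_len(config$n_genes)),
      age_label = sample(age_labels_all, config$n_genes, replace = TRUE,
                         prob = config$gene_age_distribution),
      stringsAsFactors = FALSE)
  }

  used_repeats <- lapply(setNames(species, species), function(sp) integer())

  # place one pre-miR locus for a species; returns the BED row
  place_premir <- function(sp, id, hp, host_pool) {
    cat_probs <- config$placement
    cat <- sample(names(cat_probs), 1, prob = cat_probs)
    plen <- nchar(hp$seq)
    gdf <- genes[[sp]]
    if (cat == "intron" || cat == "exon") {
      host <- host_pool$take(sp)
      if (is.null(host)) cat <- "intergenic"
    }
    if (cat == "intron") {
      hrow <- gdf[gdf$gene_id == host & gdf$kind == "intron", ][1, ]
      pos <- hrow$start + sample(0:(intron_len - plen), 1)
      strand <- if (runif(1) < 0.8) hrow$strand else setdiff(c("+", "-"), hrow$strand)
    } else if (cat == "exon") {
      hrow <- gdf[gdf$gene_id == host & gdf$kind == "exon", ][1, ]
      pos <- hrow$start + sample(0:(exon_len - plen), 1)
      strand <- if (runif(1) < 0.8) hrow$strand else setdiff(c("+", "-"), hrow$strand)
    } else if (cat == "repeats") {
      rdf <- repeats[[sp]]
      free <- setdiff(which(rdf$end - rdf$start >= plen),
                      used_repeats[[sp]])
      if (!length(free)) {
        pos <- allocators[[sp]](plen)
        strand <- sample(c("+", "-"), 1)
      } else {
        ridx <- if (length(free) == 1) free else sample(free, 1)
        used_repeats[[sp]] <<- c(used_repeats[[sp]], ridx)
        pos <- rdf$start[ridx] +
          sample(0:(rdf$end[ridx] - rdf$start[ridx] - plen), 1)
        strand <- sample(c("+", "-"), 1)
      }
    } else {
      pos <- allocators[[sp]](plen)
      strand <- sample(c("+", "-"), 1)
    }
    ins <- if (strand == "+") hp$seq else revcomp(hp$seq)
    genomes[[sp]][(pos + 1):(pos + plen)] <<- seq_chars(ins)
    data.frame(chrom = "chr1", start = pos, end = pos + plen, id = id,
               strand = strand, category = cat, stringsAsFactors = FALSE)
  }
  # host genes are used at most once to keep hosted loci disjoint
  host_pool <- local({
    pools <- lapply(setNames(species, species), function(sp)
      sample(genes[[sp]]$gene_id[genes[[sp]]$kind == "gene"]))
    used <- setNames(rep(0L, nsp), species)
    list(take = function(sp) {
      used[[sp]] <<- used[[sp]] + 1L
      if (used[[sp]] > length(pools[[sp]])) NULL else pools[[sp]][used[[sp]]]
    })
  })

  premir_rows <- setNames(vector("list", nsp), species)
  nb_size <- 1 / config$nb_dispersion
  ls_mu <- config$shared_expression_mean * config$lineage_specific_expression_ratio

  # shared families ---------------------------------------------------------
  for (f in seq_len(nfam)) {
    fam_id <- sprintf("fam%03d", f)
    for (sp in fam_carried[[f]]) {
      mid <- sprintf("%s_%s", sp, fam_id)
      mature <- mature_with_seed(fam_seed[f])
      hp <- build_premir(mature)
      bed <- place_premir(sp, mid, hp, host_pool)
      premir_rows[[sp]] <- c(premir_rows[[sp]], list(bed))
      catalog_rows[[length(catalog_rows) + 1L]] <- data.frame(
        mirna_id = mid, species_id = sp, mature_seq = as_rna(mature),
        star_seq = as_rna(substr(hp$seq, hp$star_rel["start"] + 1,
                                 hp$star_rel["end"])),
        premir_seq = hp$seq, chrom = bed$chrom, start = bed$start,
        end = bed$end, strand = bed$strand, category = bed$category,
        true_class = paste0("shared:", fam_id),
        true_mu = config$shared_expression_mean, stringsAsFactors = FALSE)
    }
  }

  # lineage-specific miRNAs -------------------------------------------------
  n_ls <- config$n_lineage_specific_per_species
  n_unique <- round(config$unique_fraction * n_ls)
  homolog_plants <- list()
  for (sp in species) {
    for (k in seq_len(n_ls)) {
      mid <- sprintf("%s_ls%02d", sp, k)
      subclass <- if (k <= n_unique) "unique" else "premir_homolog"
      mature <- mature_with_seed(draw_seed(registry))
      hp <- build_premir(mature)
      bed <- place_premir(sp, mid, hp, host_pool)
      premir_rows[[sp]] <- c(premir_rows[[sp]], list(bed))
      catalog_rows[[length(catalog_rows) + 1L]] <- data.frame(
        mirna_id = mid, species_id = sp, mature_seq = as_rna(mature),
        star_seq = as_rna(substr(hp$seq, hp$star_rel["start"] + 1,
                                 hp$star_rel["end"])),
        premir_seq = hp$seq, chrom = bed$chrom, start = bed$start,
        end = bed$end, strand = bed$strand, category = bed$category,
        true_class = paste0("lineage_specific:", subclass),
        true_mu = ls_mu, stringsAsFactors = FALSE)
      if (subclass == "premir_homolog") {
        other <- sample(setdiff(species, sp), 1)
        # diverged, unexpressed genomic copy: ~84% identity with a
        # protected exact core so the word-seeded search can anchor
        copy <- mutate_seq(hp$seq, 10L, protect = 20:36)
        homolog_plants[[length(homolog_plants) + 1L]] <-
          list(sp = other, seq = copy)
      }
    }
  }
  for (hpb in homolog_plants) {
    plen <- nchar(hpb$seq)
    pos <- allocators[[hpb$sp]](plen)
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") hpb$seq else revcomp(hpb$seq)
    genomes[[hpb$sp]][(pos + 1):(pos + plen)] <- seq_chars(ins)
  }

  # contaminant decoy hairpins ---------------------------------------------
  for (sp in species) {
    for (d in seq_len(config$n_decoys_per_species)) {
      mid <- sprintf("%s_decoy%d", sp, d)
      ct <- contaminants[[sample(length(contaminants), 1)]]
      off <- sample(0:(nchar(ct) - 30), 1)
      core <- substr(ct, off + 1, off + 30)
      fake_mature <- substr(core, 1, 22)
      seqd <- paste0(random_dna(4), core, random_dna(30))
      hp <- list(seq = seqd, mature_rel = c(start = 4L, end = 26L),
                 star_rel = c(start = 38L, end = 60L))
      bed <- place_premir(sp, mid, hp, host_pool)
      premir_rows[[sp]] <- c(premir_rows[[sp]], list(bed))
      catalog_rows[[length(catalog_rows) + 1L]] <- data.frame(
        mirna_id = mid, species_id = sp, mature_seq = as_rna(fake_mature),
        star_seq = as_rna(substr(seqd, 39, 60)),
        premir_seq = seqd, chrom = bed$chrom, start = bed$start,
        end = bed$end, strand = bed$strand, category = bed$category,
        true_class = "decoy:contaminant", true_mu = 30,
        stringsAsFactors = FALSE)
    }
  }
  catalog <- `rownames<-`(do.call(rbind, catalog_rows), NULL)
  premirs <- lapply(premir_rows, function(rs) `rownames<-`(do.call(rbind, rs), NULL))

  # planted target sites ----------------------------------------------------
  planted_sites <- list()
  realized_rf <- setNames(numeric(nsp), species)
  mature_len <- 22L
  for (sp in species) {
    ages <- gene_ages[[sp]]
    ls_ids <- catalog$mirna_id[catalog$species_id == sp &
                                 startsWith(catalog$true_class, "lineage_specific")]
    plan <- plant_enrichment(ages$gene_id, ages$age_label, ls_ids,
                             config$planted_target_rf_young,
                             config$n_targets_per_species)
    realized_rf[sp] <- attr(plan, "realized_rf")
    gdf <- genes[[sp]]
    for (r in seq_len(nrow(plan))) {
      gid <- plan$gene_id[r]
      mat <- as_dna(catalog$mature_seq[catalog$mirna_id == plan$mirna_id[r]])
      grow <- gdf[gdf$gene_id == gid & gdf$kind == "gene", ]
      utr_off <- sample(20:(flank_len - mature_len - 20), 1)
      if (grow$strand == "+") {
        fs <- grow$end
        # proxy is the forward strand: implant revcomp(mature) directly
        gpos <- fs + utr_off
        genomes[[sp]][(gpos + 1):(gpos + mature_len)] <- seq_chars(revcomp(mat))
      } else {
        fe <- grow$start
        # proxy is the reverse complement of [start-500, start):
        # implant the mature itself so the proxy reads revcomp(mature)
        gpos <- fe - utr_off - mature_len
        genomes[[sp]][(gpos + 1):(gpos + mature_len)] <- seq_chars(mat)
      }
      planted_sites[[length(planted_sites) + 1L]] <- data.frame(
        species_id = sp, gene_id = gid, mirna_id = plan$mirna_id[r],
        utr_offset = utr_off,
        seed_offset = utr_off + mature_len - 8L,
        is_young = plan$is_young[r], stringsAsFactors = FALSE)
    }
  }
  planted_sites <- `rownames<-`(do.call(rbind, planted_sites), NULL)

  # reads -------------------------------------------------------------------
  for (sp in species) {
    cat_sp <- catalog[catalog$species_id == sp, , drop = FALSE]
    rrows <- list()
    for (i in seq_len(nrow(cat_sp))) {
      mc <- rnbinom(1, size = nb_size, mu = cat_sp$true_mu[i])
      sc <- rbinom(1, mc, config$star_thinning)
      if (mc > 0)
        rrows[[length(rrows) + 1L]] <- data.frame(
          sequence = cat_sp$mature_seq[i], count = mc,
          stringsAsFactors = FALSE)
      if (sc > 0)
        rrows[[length(rrows) + 1L]] <- data.frame(
          sequence = cat_sp$star_seq[i], count = sc,
          stringsAsFactors = FALSE)
    }
    # junk reads exercising QC: too short, and non-standard bases
    rrows[[length(rrows) + 1L]] <- data.frame(
      sequence = as_rna(random_dna(15)), count = 12L, stringsAsFactors = FALSE)
    junk <- seq_chars(random_dna(20)); junk[5] <- "N"
    rrows[[length(rrows) + 1L]] <- data.frame(
      sequence = as_rna(paste(junk, collapse = "")), count = 7L,
      stringsAsFactors = FALSE)
    reads[[sp]] <- `rownames<-`(do.call(rbind, rrows), NULL)
  }

  # orthogroups and the clade ladder ----------------------------------------
  externals <- c(Vertebrata = "Homo_sapiens", Metazoa = "Caenorhabditis_elegans",
                 Arthropoda = "Daphnia_pulex", Insecta = "Acyrthosiphon_pisum",
                 Holometabola = "Drosophila_melanogaster",
                 Hymenoptera = "Nasonia_vitripennis",
                 Aculeata = "Polistes_dominula", Apoidea = "Apis_dorsata")
  og_rows <- list()
  ogi <- 0L
  for (sp in species) {
    ages <- gene_ages[[sp]]
    for (r in which(ages$age_label != "Unique")) {
      ogi <- ogi + 1L
      og <- sprintf("OG%06d", ogi)
      ext_sp <- externals[[ages$age_label[r]]]
      og_rows[[length(og_rows) + 1L]] <- data.frame(
        orthogroup_id = og,
        gene_id = c(ages$gene_id[r], paste0(ext_sp, "_", og)),
        species_id = c(sp, ext_sp), stringsAsFactors = FALSE)
    }
  }
  orthogroups <- `rownames<-`(do.call(rbind, og_rows), NULL)
  ladder_df <- data.frame(
    species_id = c(species, unname(externals)),
    most_specific_clade = c(rep("Apoidea", nsp), names(externals)),
    stringsAsFactors = FALSE)

  # unrelated gene lists for the null batteries ------------------------------
  caste_lists <- lapply(setNames(species, species), function(sp)
    sample(gene_ages[[sp]]$gene_id, 60))
  selection_lists <- lapply(setNames(species, species), function(sp)
    sample(gene_ages[[sp]]$gene_id, 60))

  genomes <- lapply(genomes, function(g) c(chr1 = paste(g, collapse = "")))

  truth <- list(
    catalog = catalog[, c("mirna_id", "species_id", "true_class", "true_mu")],
    gene_ages = gene_ages,
    planted_sites = planted_sites,
    realized_rf = realized_rf,
    planted_copy_accession = acc[1])

  list(config = config, species = species, genomes = genomes, genes = genes,
       repeats = repeats, premirs = premirs, reads = reads,
       catalog = catalog, known_mirs = known_mirs,
       contaminants = contaminants, orthogroups = orthogroups,
       ladder = ladder_df, tree = tree, sociality = sociality,
       copy_matrix = copy_matrix, caste_lists = caste_lists,
       selection_lists = selection_lists, truth = truth)
}

#' Write a synthetic world to disk as plain-text files
#'
#' Per species: genome FASTA, gene GFF3, repeat BED6, pre-miR BED6, reads
#' FASTA (collapsed, `id_xCOUNT` headers) and mature FASTA. Shared files:
#' known miRNAs, contaminants, orthogroups, clade ladder, newick tree,
#' sociality and copy-number TSVs, config and truth JSON.
#'
#' @param world result of [generate_world()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, paste0(...))
  for (sp in world$species) {
    write_fasta(world$genomes[[sp]], fp(sp, "_genome.fa"))
    write_gff3_genes(world$genes[[sp]], fp(sp, "_genes.gff3"))
    write_bed6(world$repeats[[sp]], fp(sp, "_repeats.bed"))
    write_bed6(world$premirs[[sp]], fp(sp, "_premirs.bed"))
    rd <- world$reads[[sp]]
    write_fasta(setNames(rd$sequence,
                         sprintf("%s_read%04d_x%d", sp, seq_len(nrow(rd)),
                                 rd$count)),
                fp(sp, "_reads.fa"))
    cat_sp <- world$catalog[world$catalog$species_id == sp, ]
    write_fasta(setNames(cat_sp$mature_seq, cat_sp$mirna_id),
                fp(sp, "_mature.fa"))
  }
  write_fasta(world$known_mirs, fp("known_mirs.fa"))
  write_fasta(world$contaminants, fp("contaminants.fa"))
  write_tsv(world$orthogroups, fp("orthogroups.tsv"))
  write_tsv(world$ladder, fp("ladder.tsv"))
  ape::write.tree(world$tree, fp("tree.nwk"))
  write_tsv(data.frame(species_id = names(world$sociality),
                       level = unname(world$sociality)),
            fp("sociality.tsv"))
  write_tsv(data.frame(accession = rownames(world$copy_matrix),
                       world$copy_matrix, check.names = FALSE),
            fp("copy_number.tsv"))
  cfg <- world$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, fp("config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(world$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
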