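test_that("world generation is deterministic given the seed", {
  w1 <- generate_world(tiny_config())
  w2 <- generate_world(tiny_config())
  expect_identical(w1$genomes, w2$genomes)
  expect_identical(w1$catalog, w2$catalog)
  expect_identical(w1$truth$planted_sites, w2$truth$planted_sites)
  w3 <- generate_world(tiny_config(seed = 202L))
  expect_false(identical(w1$genomes, w3$genomes))
})

test_that("worlds round-trip byte-identically through write_world", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(generate_world(tiny_config()), d1)
  write_world(generate_world(tiny_config()), d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("world files re-read into consistent structures", {
  w <- tiny_world()
  d <- withr::local_tempdir()
  write_world(w, d)
  sp <- w$species[1]
  g <- read_fasta(file.path(d, paste0(sp, "_genome.fa")))
  expect_identical(g[["chr1"]], w$genomes[[sp]][["chr1"]])
  feats <- read_gff3_genes(file.path(d, paste0(sp, "_genes.gff3")))
  genes_in <- w$genes[[sp]][w$genes[[sp]]$kind == "gene", ]
  genes_out <- feats[feats$kind == "gene", ]
  expect_setequal(genes_out$gene_id, genes_in$gene_id)
  m <- match(genes_in$gene_id, genes_out$gene_id)
  expect_equal(genes_out$start[m], genes_in$start)
  expect_equal(genes_out$end[m], genes_in$end)
  tr <- read_newick(file.path(d, "tree.nwk"))
  expect_setequal(tr$tip.label, w$species)
  og <- read_orthogroups(file.path(d, "orthogroups.tsv"))
  expect_identical(og, w$orthogroups)
  cm <- read_copy_number(file.path(d, "copy_number.tsv"))
  expect_equal(cm, w$copy_matrix)
})

test_that("shared family seeds recur across species, lineage-specific never", {
  w <- tiny_world()
  cat <- w$catalog
  cat$seed <- extract_seed(cat$mature_seq)
  shared <- cat[startsWith(cat$true_class, "shared"), ]
  for (fam in unique(shared$true_class)) {
    members <- shared[shared$true_class == fam, ]
    expect_equal(length(unique(members$seed)), 1L)
    expect_gte(length(unique(members$species_id)), 2L)
  }
  ls <- cat[startsWith(cat$true_class, "lineage_specific"), ]
  # exhaustive: no lineage-specific seed collides with any shared seed
  expect_length(intersect(ls$seed, shared$seed), 0)
  expect_equal(anyDuplicated(ls$seed), 0L)
  known_seeds <- extract_seed(w$known_mirs)
  expect_length(intersect(ls$seed, known_seeds), 0)
})

test_that("planted sites carry the exact seed reverse complement", {
  w <- tiny_world()
  for (r in sample(nrow(w$truth$planted_sites), 40)) {
    site <- w$truth$planted_sites[r, ]
    sp <- site$species_id
    gene <- w$genes[[sp]][w$genes[[sp]]$gene_id == site$gene_id &
                            w$genes[[sp]]$kind == "gene", ]
    u <- extract_utr_proxy(gene, w$genomes[[sp]])
    mature <- w$catalog$mature_seq[w$catalog$mirna_id == site$mirna_id]
    seed_rc <- revcomp(extract_seed(mature))
    expect_identical(substr(u$sequence, site$seed_offset + 1,
                            site$seed_offset + 7), seed_rc)
    # and the full site is the mature's reverse complement
    expect_identical(substr(u$sequence, site$utr_offset + 1,
                            site$utr_offset + 22), revcomp(as_dna(mature)))
  }
})

test_that("lineage-specific expression means scale by the configured ratio", {
  w <- tiny_world()
  cat <- w$truth$catalog
  mu_ls <- cat$true_mu[startsWith(cat$true_class, "lineage_specific")]
  mu_sh <- cat$true_mu[startsWith(cat$true_class, "shared")]
  expect_equal(mean(mu_ls) / mean(mu_sh),
               w$config$lineage_specific_expression_ratio)
  # realized read counts follow within sampling error (pooled species)
  reads <- do.call(rbind, w$reads)
  obs <- function(cls) {
    ids <- cat$mirna_id[startsWith(cat$true_class, cls)]
    seqs <- w$catalog$mature_seq[match(ids, w$catalog$mirna_id)]
    mean(vapply(seqs, function(s) sum(reads$count[reads$sequence == s]),
                numeric(1)))
  }
  ratio <- obs("lineage_specific") / obs("shared")
  expect_gt(ratio, 0.12)
  expect_lt(ratio, 0.45)
})

test_that("enrichment planting hits the requested representation factor", {
  set.seed(71)
  genes <- paste0("g", 1:400)
  ages <- c(rep("Unique", 80), rep("Vertebrata", 320))
  xs <- replicate(200, {
    plan <- plant_enrichment(genes, ages, paste0("m", 1:10), 1.8, 100)
    sum(plan$is_young)
  })
  # E[x] = rf * n * D / N = 1.8 * 100 * 80 / 400 = 36
  expect_equal(mean(xs), 36, tolerance = 0.06)
  expect_error(plant_enrichment(genes, ages, "m1", 6.0, 100), "infeasible")
})

test_that("null planting is independent of gene age", {
  set.seed(72)
  genes <- paste0("g", 1:400)
  ages <- c(rep("Unique", 80), rep("Vertebrata", 320))
  xs <- replicate(300, {
    plan <- plant_enrichment(genes, ages, paste0("m", 1:10), 1.0, 100)
    sum(plan$is_young)
  })
  expect_equal(mean(xs), 20, tolerance = 0.05) # nD/N = 20
  # uniform subsets: variance matches the hypergeometric, not the binomial
  v_hyper <- 100 * 0.2 * 0.8 * 300 / 399
  expect_lt(abs(var(xs) - v_hyper) / v_hyper, 0.35)
})

test_that("precursor placement categories follow the configured mix", {
  w <- tiny_world()
  tab <- table(w$catalog$category)
  expect_gt(tab[["intergenic"]], tab[["exon"]])
  expect_gt(tab[["intron"]], tab[["exon"]])
  expect_setequal(names(tab), c("intergenic", "intron", "exon", "repeats"))
})
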