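# A small synthetic world (3 species) shared across test files; generated
# once per test run and memoized.

.world_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 101L) {
  world_config(n_species = 3L, genome_length = 120000L, n_genes = 80L,
               n_shared_mirna_families = 10L,
               n_lineage_specific_per_species = 6L,
               n_targets_per_species = 25L, n_known = 10L,
               n_copy_accessions = 10L, rng_seed = seed)
}

tiny_world <- function() {
  if (is.null(.world_cache$world))
    .world_cache$world <- generate_world(tiny_config())
  .world_cache$world
}

tiny_result <- function() {
  if (is.null(.world_cache$result))
    .world_cache$result <- run_pipeline(tiny_world())
  .world_cache$result
}
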