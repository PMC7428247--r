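{
  "n_species": 3,
  "genome_length": 120000,
  "n_genes": 80,
  "n_shared_mirna_families": 10,
  "n_lineage_specific_per_species": 6,
  "n_targets_per_species": 25,
  "n_known": 10,
  "n_copy_accessions": 10
}
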