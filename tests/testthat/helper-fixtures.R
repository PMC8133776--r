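# Shared desk-scale fixture: one small genome bundle reused across test
# files (built once per test run; ~1 s).
small_params <- function(seed = 42L) {
  sim_params(genome_length = 60000L, n_te_families = 2L, te_length = 800L,
             cluster_length = 10000L,
             n_dispersed_insertions_per_family = 2L,
             n_cluster_fragments_per_family = 2L,
             n_genes = 6L, gene_length = 1000L, n_mirna_loci = 3L,
             n_blacklist_loci = 2L, seed = seed)
}
.small_bundle <- simulate_genome(small_params())
small_bundle <- function() .small_bundle
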