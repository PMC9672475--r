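# Shared fixtures, generated in code. The small world keeps unit tests fast;
# acceptance tests use the default (400-gene) study regime.

.world_cache <- new.env(parent = emptyenv())

small_world_params <- function(seed = 42, ...) {
  world_params(n_genes = 120, fraction_tlm = 0.3, n_pathways = 12,
               n_complexes = 12, n_go_terms = 15, seed = seed, ...)
}

small_world <- function(seed = 42) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(small_world_params(seed = seed))
  .world_cache[[key]]
}

default_world <- function(seed = 1) {
  key <- paste0("d", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(world_params(seed = seed))
  .world_cache[[key]]
}

write_tsv_fixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small deterministic feature table for scaler/selection tests.
toy_feature_table <- function(values, family = "gi_proportion",
                              species = "cerevisiae") {
  feats <- data.frame(id = colnames(values), source = "KEGG",
                      set_id = colnames(values), family = family)
  feature_table(values, feats, species = species)
}
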