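# Fixtures built in code: a tiny hand-made collection with known structure,
# and small planted-signal specs used across test files.

# 6 genes x 8 arrays in 2 experiments; rows CAT1..CAT3 share an obvious
# linear trend, BG1..BG3 do not.
tiny_collection <- function() {
  trend <- c(1, 2, 3, 4, 2, 4, 6, 8)
  values <- rbind(
    CAT1 = trend + 0.01 * c(1, -1, 1, -1, 1, -1, 1, -1),
    CAT2 = 2 * trend + 0.5,
    CAT3 = trend + 0.02 * c(-1, 1, -1, 1, -1, 1, -1, 1),
    BG1 = c(5, 1, 4, 2, 8, 1, 9, 2),
    BG2 = c(2, 9, 1, 7, 3, 8, 2, 6),
    BG3 = c(4, 4, 1, 9, 2, 5, 7, 1))
  colnames(values) <- paste0("a", 1:8)
  map <- experiment_map(paste0("a", 1:8), rep(c("EA", "EB"), each = 4L))
  expression_collection(values, map)
}

tiny_partition <- function() {
  gene_partition(c("CAT1", "CAT2", "CAT3"), c("BG1", "BG2", "BG3"))
}

# Small planted collection: quick enough for per-module tests.
small_planted <- function(seed, n_relevant = 4L, n_irrelevant = 8L,
                          signal_sd = 2, n_category = 20L,
                          n_background = 60L) {
  generate_collection(synthetic_spec(
    n_category_genes = n_category, n_background_genes = n_background,
    n_relevant = n_relevant, n_irrelevant = n_irrelevant,
    background_block_size = 10L, signal_sd = signal_sd, rng_seed = seed))
}

# Pure-noise collection (no planted signal anywhere).
null_collection <- function(seed, n_category = 8L, n_background = 24L,
                            n_experiments = 6L) {
  generate_collection(synthetic_spec(
    n_category_genes = n_category, n_background_genes = n_background,
    n_relevant = 1L, n_irrelevant = n_experiments - 1L,
    background_block_size = 8L, signal_sd = 0, rng_seed = seed))
}
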