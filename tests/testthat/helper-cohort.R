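# Shared synthetic cohorts, generated once per test run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key = "default", cfg = NULL) {
  if (is.null(.cohort_cache[[key]])) {
    if (is.null(cfg)) cfg <- synth_config(n_samples = 1000, seed = 7)
    .cohort_cache[[key]] <- simulate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

tiny_collection <- function() {
  gene_set_collection(list(A = c("g1", "g2", "g3"),
                           B = c("g2", "g3", "g4"),
                           C = c("g5", "g6")),
                      universe = paste0("g", 1:8))
}

# Overlapping collection over a synthetic universe, for permutation tests.
overlapping_collection <- function(n_genes = 200, n_sets = 10, size = 40,
                                   seed = 11) {
  set.seed(seed)
  universe <- sprintf("g%03d", seq_len(n_genes))
  # consecutive windows with 50% stride give heavy pairwise overlap
  stride <- size / 2
  sets <- lapply(seq_len(n_sets), function(k) {
    start <- ((k - 1) * stride) %% (n_genes - size)
    universe[seq(start + 1, start + size)]
  })
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  gene_set_collection(sets, universe = universe)
}
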