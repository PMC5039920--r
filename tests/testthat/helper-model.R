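# A modest QC model shared by several test files; built once per
# session (30 cases per class keeps it quick while staying accurate).
.qc_cache <- new.env(parent = emptyenv())

cached_qc_model <- function() {
  if (is.null(.qc_cache$model)) {
    corpus <- suppressMessages(
      build_training_corpus(n_positive = 30L, n_negative = 30L, seed = 77L))
    .qc_cache$corpus <- corpus
    .qc_cache$model <- train_qc(corpus, folds = 5L, seed = 77L)
  }
  .qc_cache$model
}

cached_qc_corpus <- function() {
  cached_qc_model()
  .qc_cache$corpus
}

# A "failed immunoprecipitation" case: replicate 1 carries no signal
# (drawn flat at the control mean), replicate 2 is a normal enriched
# profile over the same windows.
failed_ip_counts <- function(n_windows = 3000L, seed = 5150L) {
  good <- simulate_chip(sim_config(n_windows = n_windows, n_chrom = 1L,
                                   r = 2L, seed = seed))
  flat <- simulate_chip(sim_config(n_windows = n_windows, n_chrom = 1L,
                                   r = 1L, state_means = c(4, 4, 4),
                                   control_mean = 4, seed = seed + 1L))
  counts <- cbind(control_counts(good$counts),
                  chip_counts(flat$counts),
                  chip_counts(good$counts)[, 2L])
  colnames(counts) <- c("control1", "chip1", "chip2")
  count_matrix(good$counts$grid, counts, c("control", "chip", "chip"))
}
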