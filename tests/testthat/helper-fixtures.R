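# Shared fixtures, generated in code. The "study trace" is the default
# acquisition configuration (2000 Hz, 20-450 Hz band, bursts 2-4 mV /
# 150-400 ms) lengthened to 45 s so that 600-sample windows number 150.
study_gen_config <- function(seed = 1L) {
  gen_config(duration_s = 45, n_bursts = 24, seed = seed)
}

.cache <- new.env()

study_trace <- function(seed = 1L) {
  key <- paste0("trace_", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- synthesize(study_gen_config(seed))
  .cache[[key]]
}

study_features <- function(seed = 1L) {
  key <- paste0("feats_", seed)
  if (is.null(.cache[[key]])) {
    tr <- study_trace(seed)
    grid <- make_grid(length(tr$samples_mv), 600, 0)
    .cache[[key]] <- list(
      grid = grid,
      features = feature_table(segment(tr, grid)),
      truth = truth_window_labels(tr, grid))
  }
  .cache[[key]]
}
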