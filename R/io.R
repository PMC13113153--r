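#' Sample-stream I/O, the end-to-end pipeline, and test fixtures
#'
#' Plain-CSV interchange for sampled traces
#' (`sample_index,time_s,value_mv[,active]`), a driver that runs
#' simulate -> quantize -> window -> features -> auto-label -> benchmark
#' from one configuration, and small deterministic fixtures used by the
#' test-suite.
#'
#' @name workbench_io
NULL

#' Write a trace to CSV
#'
#' Columns `sample_index` (0-based), `time_s`, `value_mv` and `active`
#' (0/1, present when the trace carries an activation mask).
#'
#' @param trace An `emg_trace`.
#' @param path Output path.
#' @export
write_samples_csv <- function(trace, path) {
  stopifnot(inherits(trace, "emg_trace"))
  n <- length(trace$samples_mv)
  df <- data.frame(sample_index = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) / trace$fs_hz,
                   value_mv = trace$samples_mv)
  if (!is.null(trace$activation_mask))
    df$active <- as.integer(trace$activation_mask)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Accepts the full dialect written by [write_samples_csv()] or any CSV
#' with a single `value_mv` (or `value`) column; sample indices are then
#' synthesized. The sampling rate is declared by the caller, not stored
#' in the file.
#'
#' @param path CSV path.
#' @param fs_hz Declared sampling rate (Hz).
#' @return An `emg_trace` (without pure/artifact decomposition; the
#'   activation mask is present only when the file has an `active`
#'   column).
#' @export
read_samples_csv <- function(path, fs_hz) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("schema error: empty sample file")
  vcol <- intersect(c("value_mv", "value"), names(df))
  if (length(vcol) == 0)
    stop("schema error: no value_mv (or value) column in ", path)
  v <- df[[vcol[1]]]
  bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
  if (length(bad) > 0)
    stop("non-numeric sample value at row ", bad[1])
  mask <- if ("active" %in% names(df)) df$active != 0 else NULL
  structure(list(samples_mv = as.numeric(v), fs_hz = fs_hz,
                 activation_mask = mask,
                 bursts = data.frame(onset_s = numeric(0),
                                     duration_s = numeric(0),
                                     peak_amplitude_mv = numeric(0)),
                 pure_mv = NULL, artifact_mv = NULL, envelope_mv = NULL,
                 config = NULL),
            class = "emg_trace")
}

#' Run configuration for the end-to-end pipeline
#'
#' @param generator A [gen_config()].
#' @param quantizer A [quantizer_spec()] (default 10-bit over +-5 mV).
#' @param window_len Window length in samples (default 600).
#' @param overlap Fractional window overlap (default 0, non-overlapping).
#' @param zc_deadband_mv Zero-crossing dead-band (mV).
#' @param classifiers Registry names to benchmark.
#' @param cv_seed Fold-shuffle seed (default 42).
#' @param master_seed Master seed; overrides the generator seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = gen_config(),
                       quantizer = quantizer_spec(10),
                       window_len = 600, overlap = 0,
                       zc_deadband_mv = 0.1,
                       classifiers = c("knn", "gradient_boosting",
                                       "random_forest"),
                       cv_seed = 42, master_seed = NULL) {
  if (!is.null(master_seed)) generator$seed <- as.integer(master_seed)
  if (window_len > round(generator$fs_hz * generator$duration_s))
    stop("window_len exceeds the generated stream length")
  structure(list(generator = generator, quantizer = quantizer,
                 window_len = window_len, overlap = overlap,
                 zc_deadband_mv = zc_deadband_mv,
                 classifiers = classifiers, cv_seed = cv_seed),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate -> quantize -> window -> features -> composite auto-label ->
#' stratified 5-fold benchmark for every configured classifier. The
#' report records the resolved seed, the window count, the label split
#' and per-classifier mean/sd metrics; everything is reproducible from
#' the configuration alone.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  trace <- synthesize(config$generator)
  q <- quantize(trace$samples_mv, config$quantizer)
  qtrace <- trace
  qtrace$samples_mv <- q$reconstructed
  grid <- make_grid(length(qtrace$samples_mv), config$window_len,
                    config$overlap)
  windows <- segment(qtrace, grid)
  feats <- feature_table(windows, zc_deadband_mv = config$zc_deadband_mv)
  lab <- auto_label(feats)
  truth <- truth_window_labels(trace, grid)
  results <- lapply(config$classifiers, function(nm) {
    evaluate(classifier_registry(nm), feats, lab$labels,
             cv_plan(seed = config$cv_seed))
  })
  names(results) <- config$classifiers
  structure(list(config = config,
                 seed = config$generator$seed,
                 n_windows = length(grid$starts),
                 n_active = sum(lab$labels),
                 label_truth_agreement = mean(lab$labels == truth),
                 features = feats, labels = lab$labels,
                 thresholds = lab$thresholds,
                 cv = results),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d: %d windows (%d active), label/truth agreement %.3f\n",
              x$seed, x$n_windows, x$n_active, x$label_truth_agreement))
  for (nm in names(x$cv))
    cat(sprintf("  %-18s accuracy %.3f +/- %.3f\n", nm,
                x$cv[[nm]]$mean["accuracy"], x$cv[[nm]]$sd["accuracy"]))
  invisible(x)
}

#' Deterministic test fixtures
#'
#' Small, seed-fixed objects shared by the test-suite: `tiny_trace`
#' (1200 samples, 2 bursts at 2000 Hz), `alt_window` (the `[1, -1, 1,
#' -1]` hand-computed feature window) and `confusion_2x2` (TP 3, FP 1,
#' FN 2, TN 4).
#'
#' @param name Fixture name.
#' @return The fixture object.
#' @export
fixture <- function(name) {
  switch(name,
    tiny_trace = synthesize(gen_config(fs_hz = 2000, duration_s = 0.6,
                                       n_bursts = 2,
                                       burst_dur_range_s = c(0.10, 0.15),
                                       min_gap_s = 0.05, seed = 99L)),
    alt_window = c(1, -1, 1, -1),
    confusion_2x2 = matrix(c(3, 2, 1, 4), 2, 2, byrow = TRUE,
                           dimnames = list(true = c("pos", "neg"),
                                           predicted = c("pos", "neg"))),
    stop("unknown fixture: ", name))
}
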