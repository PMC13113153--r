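#' Acquisition-channel models: quantization and rate conversion
#'
#' Models the analog-to-digital front end of an EMG acquisition system:
#' a uniform midtread quantizer over a symmetric full-scale range, and a
#' rational-rate polyphase resampler with a Kaiser-windowed anti-aliasing
#' filter. Sweep drivers measure reconstruction MSE against the
#' unquantized (or high-rate ground-truth) signal and, for bit depth,
#' downstream classification accuracy.
#'
#' @name acquisition
NULL

#' Uniform midtread quantizer specification
#'
#' `2^bits` codes over the symmetric range `[-full_scale_mv, +full_scale_mv]`
#' with step `delta = 2 * full_scale_mv / (2^bits - 1)`. The midtread
#' convention places a reconstruction level exactly at zero (code
#' `2^(bits-1)`), so silence quantizes without error; out-of-range input
#' clips to the extreme codes.
#'
#' @param bits Bit depth (>= 1; the study sweeps 3--12).
#' @param full_scale_mv Half-range of the converter (mV).
#' @return An object of class `quantizer_spec`.
#' @export
quantizer_spec <- function(bits, full_scale_mv = 5.0) {
  if (bits < 1) stop("bits must be >= 1")
  if (full_scale_mv <= 0) stop("full_scale_mv must be > 0")
  structure(list(bits = as.integer(bits), full_scale_mv = full_scale_mv,
                 delta_mv = 2 * full_scale_mv / (2^bits - 1),
                 mode = "midtread"),
            class = "quantizer_spec")
}

#' Quantize a sample sequence
#'
#' @param samples Numeric vector (mV).
#' @param spec A [quantizer_spec()].
#' @return List with `codes` (integers in `[0, 2^bits - 1]`) and
#'   `reconstructed` (mV).
#' @export
quantize <- function(samples, spec) {
  stopifnot(inherits(spec, "quantizer_spec"))
  if (length(samples) == 0)
    return(list(codes = integer(0), reconstructed = numeric(0)))
  offset <- 2^(spec$bits - 1)
  codes <- round(samples / spec$delta_mv) + offset
  codes <- pmin(pmax(codes, 0), 2^spec$bits - 1)
  list(codes = as.integer(codes),
       reconstructed = (codes - offset) * spec$delta_mv)
}

#' Quantization-MSE sweep over bit depth
#'
#' For each bit depth, quantizes the trace and records the mean squared
#' error (mV^2) against the original samples.
#'
#' @param trace An `emg_trace` or numeric vector (mV).
#' @param bits_list Integer vector of bit depths.
#' @param full_scale_mv Converter half-range (mV).
#' @return A data.frame of class `sweep_result` with columns
#'   `bits`, `mse_mv2`.
#' @export
bit_depth_sweep <- function(trace, bits_list = 3:12, full_scale_mv = 5.0) {
  x <- if (inherits(trace, "emg_trace")) trace$samples_mv else trace
  if (length(bits_list) == 0) stop("bits_list must be non-empty")
  bits_list <- sort(unique(as.integer(bits_list)))
  mse <- vapply(bits_list, function(b) {
    q <- quantize(x, quantizer_spec(b, full_scale_mv))
    mean((q$reconstructed - x)^2)
  }, numeric(1))
  structure(data.frame(bits = bits_list, mse_mv2 = mse),
            class = c("sweep_result", "data.frame"))
}

# Kaiser-windowed lowpass FIR prototype for rational resampling by p/q,
# designed in the p-fold upsampled domain (cutoff pi/max(p, q), gain p).
# Half-length 10 taps per polyphase branch, the usual resample_poly sizing.
kaiser_lowpass <- function(p, q, beta = 5.0) {
  m <- max(p, q)
  half <- 10L * m
  n <- 2L * half + 1L
  k <- seq(-half, half)
  fc <- 1 / m                       # cycles per sample, two-sided cutoff
  h <- fc * sinc_(fc * k)
  h * signal::kaiser(n, beta) * p
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# FFT-based linear convolution keeping the centered (zero-delay) part.
conv_same <- function(x, h) {
  half <- (length(h) - 1L) %/% 2L
  y <- stats::convolve(x, rev(h), type = "open")
  y[(half + 1L):(half + length(x))]
}

#' Rational-rate resampling specification
#'
#' @param target_fs_hz Output rate (Hz).
#' @param kaiser_beta Kaiser window shape parameter of the anti-aliasing /
#'   interpolation filter.
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(target_fs_hz, kaiser_beta = 5.0) {
  if (target_fs_hz <= 0) stop("target_fs_hz must be > 0")
  structure(list(target_fs_hz = target_fs_hz, kaiser_beta = kaiser_beta),
            class = "resample_spec")
}

#' Resample a trace to a new rate
#'
#' Rational-rate conversion: zero-stuff by `p`, filter with a Kaiser-windowed
#' sinc lowpass cut at the lower of the two Nyquist frequencies (strict
#' anti-aliasing before decimation), then keep every `q`-th sample. The
#' activation mask is carried over by nearest-time lookup; the
#' pure/artifact decomposition is dropped (the channel observes only their
#' sum).
#'
#' @param trace An `emg_trace`.
#' @param spec A [resample_spec()] (or a numeric target rate in Hz).
#' @return An `emg_trace` at the target rate.
#' @export
resample_trace <- function(trace, spec) {
  stopifnot(inherits(trace, "emg_trace"))
  if (is.numeric(spec)) spec <- resample_spec(spec)
  fs_in <- trace$fs_hz
  fs_out <- spec$target_fs_hz
  if (fs_out == fs_in) {
    out <- trace
    out$pure_mv <- out$artifact_mv <- out$envelope_mv <- NULL
    return(out)
  }
  r <- rational_ratio(fs_out, fs_in)
  y <- resample_vector(trace$samples_mv, r$p, r$q, spec$kaiser_beta)
  n_out <- length(y)
  t_out <- (seq_len(n_out) - 1) / fs_out
  idx <- pmin(pmax(round(t_out * fs_in) + 1, 1), length(trace$activation_mask))
  structure(list(samples_mv = y, fs_hz = fs_out,
                 activation_mask = trace$activation_mask[idx],
                 bursts = trace$bursts,
                 pure_mv = NULL, artifact_mv = NULL, envelope_mv = NULL,
                 config = trace$config),
            class = "emg_trace")
}

rational_ratio <- function(fs_out, fs_in, tol = 1e-9) {
  # reduce fs_out/fs_in to lowest terms; rates are expected to be integers
  scale <- 1
  while (abs(fs_out * scale - round(fs_out * scale)) > tol ||
         abs(fs_in * scale - round(fs_in * scale)) > tol) {
    scale <- scale * 10
    if (scale > 1e6) stop("sampling-rate ratio is not rational within tolerance")
  }
  a <- round(fs_out * scale); b <- round(fs_in * scale)
  g <- gcd_(a, b)
  list(p = a / g, q = b / g)
}

gcd_ <- function(a, b) if (b == 0) a else gcd_(b, a %% b)

resample_vector <- function(x, p, q, beta = 5.0) {
  n_out <- floor(length(x) * p / q)
  up <- numeric(length(x) * p)
  up[seq(1, length(up), by = p)] <- x
  h <- kaiser_lowpass(p, q, beta)
  y <- conv_same(up, h)
  y[seq(1, by = q, length.out = n_out)]
}

#' Sampling-rate sweep against a high-rate ground truth
#'
#' For each candidate rate: anti-aliased downsampling from the reference
#' trace, uniform quantization at `quant_bits`, polyphase upsampling back
#' to the reference rate, and MSE against the ground-truth samples on the
#' reference grid.
#'
#' @param ground_truth An `emg_trace` at the reference (high) rate,
#'   typically 20 kHz.
#' @param rates_hz Candidate rates (Hz), all below the reference rate.
#' @param quant_bits Bit depth applied after downsampling (default 8).
#' @param full_scale_mv Converter half-range (mV).
#' @param kaiser_beta Kaiser window parameter.
#' @return A `sweep_result` data.frame with columns `rate_hz`, `mse_mv2`.
#' @export
sampling_rate_sweep <- function(ground_truth, rates_hz, quant_bits = 8,
                                full_scale_mv = 5.0, kaiser_beta = 5.0) {
  stopifnot(inherits(ground_truth, "emg_trace"))
  fs_ref <- ground_truth$fs_hz
  if (any(rates_hz >= fs_ref))
    stop("all candidate rates must be below the reference rate")
  rates_hz <- sort(rates_hz)
  x <- ground_truth$samples_mv
  qs <- quantizer_spec(quant_bits, full_scale_mv)
  mse <- vapply(rates_hz, function(fs) {
    r <- rational_ratio(fs, fs_ref)
    down <- resample_vector(x, r$p, r$q, kaiser_beta)
    down <- quantize(down, qs)$reconstructed
    back <- resample_vector(down, r$q, r$p, kaiser_beta)
    m <- min(length(back), length(x))
    mean((back[seq_len(m)] - x[seq_len(m)])^2)
  }, numeric(1))
  structure(data.frame(rate_hz = rates_hz, mse_mv2 = mse),
            class = c("sweep_result", "data.frame"))
}

#' Classification accuracy versus quantizer bit depth
#'
#' Runs the downstream pipeline at each bit depth: quantize the stream,
#' segment into windows, extract the 12 time-domain features, and evaluate
#' a registry classifier under stratified 5-fold cross-validation. Labels
#' are fixed from the *unquantized* reference (composite auto-labels), so
#' accuracy changes reflect feature degradation alone.
#'
#' @param trace An `emg_trace`.
#' @param bits_list Integer vector of bit depths.
#' @param classifier_name Name from the classifier registry
#'   (see [classifier_registry()]).
#' @param window_len Window length in samples.
#' @param full_scale_mv Converter half-range (mV).
#' @param cv_seed Fold-shuffle seed.
#' @param zc_deadband_mv Zero-crossing dead-band (mV).
#' @return A `sweep_result` data.frame with columns `bits`, `mse_mv2`,
#'   `accuracy`.
#' @export
accuracy_vs_bits <- function(trace, bits_list = 3:12,
                             classifier_name = "random_forest",
                             window_len = 600, full_scale_mv = 5.0,
                             cv_seed = 42, zc_deadband_mv = 0.1) {
  stopifnot(inherits(trace, "emg_trace"))
  bits_list <- sort(unique(as.integer(bits_list)))
  grid <- make_grid(length(trace$samples_mv), window_len, 0)
  ref_windows <- segment(trace, grid)
  ref_feats <- feature_table(ref_windows, zc_deadband_mv = zc_deadband_mv)
  labels <- auto_label(ref_feats)$labels
  if (length(unique(labels)) < 2)
    stop("reference labeling produced a single class; lengthen the stream")
  cfg <- classifier_registry(classifier_name)  # errors on unknown names
  plan <- cv_plan(seed = cv_seed)
  res <- vapply(bits_list, function(b) {
    q <- quantize(trace$samples_mv, quantizer_spec(b, full_scale_mv))
    mse <- mean((q$reconstructed - trace$samples_mv)^2)
    qtr <- trace
    qtr$samples_mv <- q$reconstructed
    feats <- feature_table(segment(qtr, grid), zc_deadband_mv = zc_deadband_mv)
    cv <- evaluate(cfg, feats, labels, plan)
    c(mse, cv$mean["accuracy"])
  }, numeric(2))
  structure(data.frame(bits = bits_list, mse_mv2 = res[1, ],
                       accuracy = res[2, ]),
            class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", nrow(x), " settings\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
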