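#' Synthetic surface-EMG generation
#'
#' The generator models surface EMG as wide-sense-stationary colored noise
#' (white Gaussian noise shaped by a 4th-order Butterworth bandpass,
#' 20--450 Hz) amplitude-modulated by a sum of Gaussian burst envelopes,
#' with additive measurement artifacts: thermal white noise, 60 Hz
#' powerline interference, low-frequency baseline drift and sparse
#' motion-artifact spikes. Each burst has a randomized peak amplitude
#' (2--4 mV) and duration (150--400 ms); the modulating noise is scaled to
#' unit RMS so that the burst amplitude parameter is the envelope peak in
#' millivolts.
#'
#' @name siggen
NULL

#' Artifact configuration
#'
#' Parameters of the additive artifact term: thermal white noise, mains
#' interference, baseline drift, and sparse high-amplitude spikes.
#'
#' @param white_sigma_mv Standard deviation of white Gaussian noise (mV).
#' @param powerline_amp_mv Amplitude of the mains sinusoid (mV).
#' @param powerline_hz Mains frequency (Hz).
#' @param drift_amp_mv Amplitude of the baseline-drift sinusoid (mV).
#' @param drift_hz Drift frequency (Hz).
#' @param spike_amp_mv Absolute amplitude of motion-artifact spikes (mV).
#' @param spike_prob Per-sample probability of a spike.
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(white_sigma_mv = 0.05,
                            powerline_amp_mv = 0.2,
                            powerline_hz = 60,
                            drift_amp_mv = 0.1,
                            drift_hz = 1.5,
                            spike_amp_mv = 3.0,
                            spike_prob = 0.001) {
  amps <- c(white_sigma_mv, powerline_amp_mv, drift_amp_mv, spike_amp_mv)
  if (any(amps < 0)) stop("artifact amplitudes must be >= 0")
  if (spike_prob < 0 || spike_prob > 1) stop("spike_prob must be in [0, 1]")
  structure(list(white_sigma_mv = white_sigma_mv,
                 powerline_amp_mv = powerline_amp_mv,
                 powerline_hz = powerline_hz,
                 drift_amp_mv = drift_amp_mv,
                 drift_hz = drift_hz,
                 spike_amp_mv = spike_amp_mv,
                 spike_prob = spike_prob),
            class = "artifact_config")
}

#' Generator configuration
#'
#' Full configuration of the synthetic EMG stream. Defaults reproduce the
#' standard study stream: 15 s at 2000 Hz (30,000 samples) with 8 muscle
#' activation bursts; a high-fidelity 20 kHz variant is used as analog
#' ground truth for the resampling sweep.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Stream duration (seconds).
#' @param n_bursts Number of activation bursts.
#' @param burst_amp_range_mv Range of burst peak amplitudes (mV).
#' @param burst_dur_range_s Range of burst durations (seconds).
#' @param min_gap_s Minimum rest gap between consecutive bursts (seconds).
#' @param band_low_hz,band_high_hz Bandpass edges of the colored noise (Hz).
#' @param filter_order Butterworth order.
#' @param artifacts An [artifact_config()].
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(fs_hz = 2000,
                       duration_s = 15,
                       n_bursts = 8,
                       burst_amp_range_mv = c(2.0, 4.0),
                       burst_dur_range_s = c(0.150, 0.400),
                       min_gap_s = 0.100,
                       band_low_hz = 20,
                       band_high_hz = 450,
                       filter_order = 4,
                       artifacts = artifact_config(),
                       seed = 1L) {
  if (band_high_hz >= fs_hz / 2)
    stop("band_high_hz must be below the Nyquist frequency fs_hz/2")
  if (band_low_hz <= 0 || band_low_hz >= band_high_hz)
    stop("require 0 < band_low_hz < band_high_hz")
  if (duration_s <= max(burst_dur_range_s))
    stop("duration_s must exceed the maximum burst duration")
  if (n_bursts < 0) stop("n_bursts must be >= 0")
  stopifnot(inherits(artifacts, "artifact_config"))
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 n_bursts = n_bursts,
                 burst_amp_range_mv = burst_amp_range_mv,
                 burst_dur_range_s = burst_dur_range_s,
                 min_gap_s = min_gap_s,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = filter_order,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "gen_config")
}

#' Design the bandpass filter that colors the EMG noise floor
#'
#' Butterworth bandpass in second-order-section-free `Arma` form via
#' [signal::butter()]. Band edges are the -3 dB points.
#'
#' @param order Filter order.
#' @param low_hz,high_hz Passband edges (Hz).
#' @param fs_hz Sampling rate (Hz).
#' @return A `signal::Arma` filter object.
#' @export
design_bandpass <- function(order, low_hz, high_hz, fs_hz) {
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("require 0 < low_hz < high_hz")
  if (high_hz >= fs_hz / 2)
    stop("high_hz must be below the Nyquist frequency fs_hz/2")
  signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
}

# Substream seeds: derive independent per-component seeds from the master
# seed so toggling one component does not shift the draws of another.
substream_seed <- function(seed, name) {
  offs <- c(bursts = 101L, noise = 211L, white = 307L, spikes = 401L,
            shuffle = 503L)
  if (!name %in% names(offs)) stop("unknown substream: ", name)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[name]]
}

#' Draw burst specifications
#'
#' Durations and peak amplitudes are uniform over their configured ranges;
#' onsets are placed by a spacing sampler that guarantees a minimum rest
#' gap between consecutive bursts. Bursts are returned sorted by onset.
#'
#' @param config A [gen_config()].
#' @return A data.frame with columns `onset_s`, `duration_s`,
#'   `peak_amplitude_mv`, one row per burst.
#' @export
draw_bursts <- function(config) {
  nb <- config$n_bursts
  if (nb == 0)
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_amplitude_mv = numeric(0)))
  withr_seed <- substream_seed(config$seed, "bursts")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  dur_b <- stats::runif(nb, config$burst_dur_range_s[1], config$burst_dur_range_s[2])
  amp <- stats::runif(nb, config$burst_amp_range_mv[1], config$burst_amp_range_mv[2])
  free <- config$duration_s - sum(dur_b) - (nb + 1) * config$min_gap_s
  if (free < 0)
    stop("duration_s too short to place ", nb,
         " bursts with the minimum inter-burst gap")
  # split the free time into nb+1 random gaps (Dirichlet via sorted uniforms)
  cuts <- sort(stats::runif(nb))
  gaps <- diff(c(0, cuts, 1)) * free + config$min_gap_s
  onsets <- cumsum(gaps[seq_len(nb)]) + cumsum(c(0, dur_b[-nb]))
  data.frame(onset_s = onsets, duration_s = dur_b, peak_amplitude_mv = amp)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Summed Gaussian envelopes and the activation mask. sigma = duration/6 so
# +-3 sigma spans exactly [onset, onset + duration]; support truncated there.
burst_envelope <- function(t, bursts) {
  env <- numeric(length(t))
  mask <- logical(length(t))
  if (nrow(bursts) == 0) return(list(envelope = env, mask = mask))
  for (k in seq_len(nrow(bursts))) {
    s <- bursts$duration_s[k] / 6
    c0 <- bursts$onset_s[k] + bursts$duration_s[k] / 2
    idx <- which(t >= c0 - 3 * s & t <= c0 + 3 * s)
    env[idx] <- env[idx] +
      bursts$peak_amplitude_mv[k] * exp(-(t[idx] - c0)^2 / (2 * s^2))
    mask[idx] <- TRUE
  }
  list(envelope = env, mask = mask)
}

#' Synthesize a surface-EMG trace
#'
#' Produces the full signal: band-limited unit-RMS colored noise modulated
#' by the summed burst envelopes (the "pure" physiological component),
#' plus the additive artifact term. The per-sample decomposition and the
#' envelope-derived activation mask are retained on the returned object.
#'
#' @param config A [gen_config()].
#' @return An object of class `emg_trace`: a list with `samples_mv`,
#'   `fs_hz`, `activation_mask`, `bursts`, `pure_mv`, `artifact_mv`,
#'   `envelope_mv` and `config`.
#' @export
#' @examples
#' tr <- synthesize(gen_config(duration_s = 2, n_bursts = 2, seed = 7))
#' print(tr)
synthesize <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  n <- round(config$fs_hz * config$duration_s)
  t <- (seq_len(n) - 1) / config$fs_hz
  bursts <- draw_bursts(config)
  if (nrow(bursts) > 0 &&
      any(bursts$onset_s + bursts$duration_s > config$duration_s + 1e-9))
    stop("burst extends past the end of the trace")
  env <- burst_envelope(t, bursts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # colored-noise carrier, scaled to unit RMS so A_k is the envelope peak
  set.seed(substream_seed(config$seed, "noise"))
  bf <- design_bandpass(config$filter_order, config$band_low_hz,
                        config$band_high_hz, config$fs_hz)
  carrier <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
  carrier <- carrier / sqrt(mean(carrier^2))
  pure <- carrier * env$envelope

  a <- config$artifacts
  set.seed(substream_seed(config$seed, "white"))
  artifact <- stats::rnorm(n, 0, a$white_sigma_mv) +
    a$powerline_amp_mv * sin(2 * pi * a$powerline_hz * t) +
    a$drift_amp_mv * sin(2 * pi * a$drift_hz * t)
  set.seed(substream_seed(config$seed, "spikes"))
  hit <- stats::runif(n) < a$spike_prob
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  artifact <- artifact + ifelse(hit, sgn * a$spike_amp_mv, 0)

  structure(list(samples_mv = pure + artifact,
                 fs_hz = config$fs_hz,
                 activation_mask = env$mask,
                 bursts = bursts,
                 pure_mv = pure,
                 artifact_mv = artifact,
                 envelope_mv = env$envelope,
                 config = config),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %d samples at %g Hz (%.3f s), %d bursts\n",
              length(x$samples_mv), x$fs_hz,
              length(x$samples_mv) / x$fs_hz, nrow(x$bursts)))
  cat(sprintf("  active samples: %.1f%%; range [%.3f, %.3f] mV\n",
              100 * mean(x$activation_mask),
              min(x$samples_mv), max(x$samples_mv)))
  if (!is.null(x$pure_mv)) {
    s <- try(measure_snr(x), silent = TRUE)
    if (!inherits(s, "try-error"))
      cat(sprintf("  burst SNR: %.1f dB\n", s))
  }
  invisible(x)
}

#' Burst signal-to-noise ratio
#'
#' Ratio (in dB) of the mean power of the pure physiological component
#' over activation-mask samples to the mean power of the additive
#' artifact component over the whole trace:
#' `10 * log10(mean(pure[mask]^2) / mean(artifact^2))`.
#'
#' @param trace An `emg_trace` retaining its pure/artifact decomposition.
#' @return SNR in decibels.
#' @export
measure_snr <- function(trace) {
  stopifnot(inherits(trace, "emg_trace"))
  if (is.null(trace$pure_mv) || is.null(trace$artifact_mv))
    stop("trace does not retain its pure/artifact decomposition")
  if (!any(trace$activation_mask))
    stop("SNR undefined: empty activation mask")
  p_sig <- mean(trace$pure_mv[trace$activation_mask]^2)
  p_art <- mean(trace$artifact_mv^2)
  if (p_sig == 0) stop("SNR undefined: pure component has zero power")
  10 * log10(p_sig / p_art)
}

#' Ground-truth window labels from the activation mask
#'
#' A window is labeled active (1) when at least `active_fraction` of its
#' samples fall inside a burst's envelope support.
#'
#' @param trace An `emg_trace`.
#' @param grid A [make_grid()] window grid (or a vector of 1-based start
#'   indices together with `window_len`).
#' @param window_len Window length in samples (ignored when `grid` is a
#'   `window_grid`).
#' @param active_fraction Minimum active-sample fraction (default 0.5,
#'   inclusive).
#' @return Integer vector of 0/1 labels, one per window.
#' @export
truth_window_labels <- function(trace, grid, window_len = NULL,
                                active_fraction = 0.5) {
  stopifnot(inherits(trace, "emg_trace"))
  if (inherits(grid, "window_grid")) {
    starts <- grid$starts
    window_len <- grid$window_len
  } else starts <- grid
  n <- length(trace$activation_mask)
  if (any(starts < 1) || any(starts + window_len - 1 > n))
    stop("window out of trace bounds")
  vapply(starts, function(s) {
    frac <- mean(trace$activation_mask[s:(s + window_len - 1)])
    as.integer(frac >= active_fraction)
  }, integer(1))
}
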