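test_that("bandpass design passes the EMG band and rejects out-of-band tones", {
  # direct transfer-function evaluation at e^{j 2 pi f / fs}
  gain_db <- function(flt, f, fs) {
    vapply(f, function(fi) {
      z <- exp(-1i * 2 * pi * fi / fs)
      h <- sum(flt$b * z^(seq_along(flt$b) - 1)) /
           sum(flt$a * z^(seq_along(flt$a) - 1))
      20 * log10(Mod(h))
    }, numeric(1))
  }
  flt <- design_bandpass(4, 20, 450, 2000)
  g <- gain_db(flt, c(10, 235, 900), 2000)
  expect_gt(g[2] - g[1], 20)
  expect_gt(g[2] - g[3], 20)

  flt20k <- design_bandpass(4, 20, 450, 20000)
  g2 <- gain_db(flt20k, c(200, 1000), 20000)
  expect_gt(g2[1], g2[2])

  expect_error(design_bandpass(4, 450, 20, 2000), "low_hz < high_hz")
  expect_error(design_bandpass(4, 20, 1200, 2000), "Nyquist")
})

test_that("burst draws respect amplitude/duration ranges, ordering and gaps", {
  expect_equal(nrow(draw_bursts(gen_config(n_bursts = 0))), 0)
  for (s in 1:20) {
    b <- draw_bursts(gen_config(seed = s))
    expect_true(all(b$peak_amplitude_mv >= 2 & b$peak_amplitude_mv <= 4))
    expect_true(all(b$duration_s >= 0.150 & b$duration_s <= 0.400))
    expect_false(is.unsorted(b$onset_s))
    ends <- b$onset_s + b$duration_s
    expect_true(all(b$onset_s[-1] - ends[-nrow(b)] >= 0.1 - 1e-9))
    expect_true(all(ends <= 15))
  }
  expect_identical(draw_bursts(gen_config(seed = 5)),
                   draw_bursts(gen_config(seed = 5)))
  expect_error(draw_bursts(gen_config(duration_s = 1, n_bursts = 10)),
               "too short")
})

test_that("synthesis is deterministic in the seed and additive in its components", {
  cfg <- gen_config(duration_s = 2, n_bursts = 2, seed = 11)
  t1 <- synthesize(cfg)
  t2 <- synthesize(cfg)
  expect_identical(t1$samples_mv, t2$samples_mv)
  expect_equal(length(t1$samples_mv), 4000)
  expect_equal(t1$samples_mv, t1$pure_mv + t1$artifact_mv)

  t3 <- synthesize(gen_config(duration_s = 2, n_bursts = 2, seed = 12))
  expect_gt(max(abs(t1$samples_mv - t3$samples_mv)), 0)

  silent <- synthesize(gen_config(
    duration_s = 2, n_bursts = 0, seed = 1,
    artifacts = artifact_config(white_sigma_mv = 0, powerline_amp_mv = 0,
                                drift_amp_mv = 0, spike_amp_mv = 0,
                                spike_prob = 0)))
  expect_equal(max(abs(silent$samples_mv)), 0)
})

test_that("activation mask has one true-run per disjoint burst", {
  for (s in 1:5) {
    tr <- synthesize(gen_config(seed = s))
    runs <- rle(tr$activation_mask)
    expect_equal(sum(runs$values), nrow(tr$bursts))
  }
})

test_that("SNR follows its closed form and rejects degenerate traces", {
  # hand-built decomposition: pure power 1 on the mask, artifact power 0.1
  tr <- structure(list(samples_mv = numeric(8), fs_hz = 10,
                       activation_mask = rep(c(TRUE, FALSE), each = 4),
                       bursts = data.frame(),
                       pure_mv = c(1, -1, 1, -1, 0, 0, 0, 0),
                       artifact_mv = rep(sqrt(0.1), 8)),
                  class = "emg_trace")
  expect_equal(measure_snr(tr), 10.0)

  tr$pure_mv <- numeric(8)
  expect_error(measure_snr(tr), "zero power")
  tr$activation_mask <- rep(FALSE, 8)
  expect_error(measure_snr(tr), "empty activation mask")
})

test_that("default generator hits the 15-20 dB burst SNR band over 20 seeds", {
  snrs <- vapply(1:20, function(s) measure_snr(synthesize(gen_config(seed = s))),
                 numeric(1))
  expect_gte(mean(snrs), 15)
  expect_lte(mean(snrs), 20)
})

test_that("pure component is band-limited to 20-450 Hz (>= 90% of power)", {
  tr <- synthesize(gen_config(duration_s = 30, seed = 2, n_bursts = 16))
  sp <- stats::spec.pgram(stats::ts(tr$pure_mv, frequency = tr$fs_hz),
                          plot = FALSE, taper = 0)
  frac <- sum(sp$spec[sp$freq >= 20 & sp$freq <= 450]) / sum(sp$spec)
  expect_gte(frac, 0.90)
})

test_that("burst amplitude parameter bounds the pure component's RMS envelope", {
  # A_k is the peak of the modulation envelope; the 100-ms moving RMS of
  # the pure component must stay within 1.5x the largest burst amplitude
  for (s in 1:5) {
    tr <- synthesize(gen_config(seed = s))
    w <- round(0.1 * tr$fs_hz)
    mv <- sqrt(stats::filter(tr$pure_mv^2, rep(1 / w, w), sides = 2))
    expect_lte(max(mv, na.rm = TRUE), 1.5 * max(tr$bursts$peak_amplitude_mv))
  }
})

test_that("envelope truth labels windows by their active-sample fraction", {
  tr <- synthesize(gen_config(duration_s = 2, n_bursts = 1, seed = 3))
  b <- tr$bursts
  inside_start <- round(b$onset_s * tr$fs_hz) + 5
  wl <- round(b$duration_s * tr$fs_hz) - 10
  expect_equal(truth_window_labels(tr, inside_start, wl), 1L)
  expect_equal(truth_window_labels(tr, 1L, 50L), 0L)

  # exactly half the samples active -> labeled active (>= rule)
  half <- structure(list(activation_mask = rep(c(FALSE, TRUE), each = 5)),
                    class = "emg_trace")
  expect_equal(truth_window_labels(half, 1L, 10L), 1L)
  expect_error(truth_window_labels(tr, 4000L, 100L), "bounds")
})
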