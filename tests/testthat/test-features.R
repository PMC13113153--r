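test_that("hand-computed features of the alternating window are exact", {
  fv <- extract_features(fixture("alt_window"), zc_deadband_mv = 0)
  expect_equal(fv[["mean"]], 0)
  expect_equal(fv[["rms"]], 1)
  expect_equal(fv[["mav"]], 1)
  expect_equal(fv[["energy"]], 4)
  expect_equal(fv[["range"]], 2)
  expect_equal(fv[["waveform_length"]], 6)
  expect_equal(fv[["zero_crossings"]], 3)

  cv <- extract_features(rep(2.5, 10))
  expect_equal(cv[["std"]], 0)
  expect_equal(cv[["variance"]], 0)
  expect_equal(cv[["zero_crossings"]], 0)
  expect_equal(cv[["waveform_length"]], 0)
  expect_equal(cv[["skewness"]], 0)
  expect_error(extract_features(1), "length >= 2")
})

test_that("feature identities hold on random windows", {
  set.seed(7)
  for (i in 1:500) {
    w <- stats::rnorm(sample(10:100, 1), sd = stats::runif(1, 0.01, 3))
    fv <- extract_features(w)
    expect_equal(fv[["variance"]], fv[["std"]]^2, tolerance = 1e-10)
    expect_equal(fv[["energy"]], length(w) * fv[["rms"]]^2, tolerance = 1e-10)
    expect_equal(fv[["range"]], fv[["max"]] - fv[["min"]], tolerance = 1e-12)
    expect_lte(fv[["mav"]], fv[["rms"]] + 1e-12)
    expect_gte(fv[["waveform_length"]], 0)
    expect_true(fv[["zero_crossings"]] >= 0 &&
                fv[["zero_crossings"]] <= length(w) - 1)
  }
})

test_that("dead-band zero crossings count only supra-threshold sign changes", {
  expect_equal(zero_crossings(c(1, -1, 1, -1), 0), 3)
  expect_equal(zero_crossings(rep(c(0.05, -0.05), 10), 0.1), 0)

  # 60 Hz sine, 600 samples at 2000 Hz: the continuous wave crosses zero
  # 2 f T = 36 times in [0, 0.3 s); the crossing at t = 0 falls on the
  # first sample (exactly zero, excluded by the dead-band rule), so the
  # discrete count is 35 -- confirmed by an index-by-index loop oracle
  x <- sin(2 * pi * 60 * (0:599) / 2000)
  brute <- 0
  for (i in 1:599)
    if (sign(x[i]) != sign(x[i + 1]) && abs(x[i]) > 0 && abs(x[i + 1]) > 0)
      brute <- brute + 1
  expect_equal(zero_crossings(x, 0), brute)
  expect_equal(brute, 35)
  expect_lte(brute, 2 * 60 * 0.3)
})

test_that("rest windows show fewer dead-band crossings than active windows", {
  sf <- study_features(1)
  zc <- sf$features$zero_crossings
  expect_lt(stats::median(zc[sf$truth == 0]), stats::median(zc[sf$truth == 1]))
})

test_that("correlation screen flags duplicates and spares independent noise", {
  set.seed(8)
  tab <- data.frame(a = stats::rnorm(1000))
  tab$b <- tab$a
  tab$c <- stats::rnorm(1000)
  scr <- correlation_screen(tab)
  expect_true(any(scr$flagged$feature_a == "a" & scr$flagged$feature_b == "b"))
  expect_equal(scr$flagged$r[scr$flagged$feature_a == "a" &
                             scr$flagged$feature_b == "b"], 1)
  expect_lt(abs(scr$matrix["a", "c"]), 0.2)
  expect_false(any(scr$flagged$feature_b == "c" | scr$flagged$feature_a == "c"))

  tab$d <- 1
  scr2 <- correlation_screen(tab)
  expect_match(scr2$warnings, "zero-variance")
  expect_false(any(scr2$flagged$feature_a == "d" | scr2$flagged$feature_b == "d"))
  expect_error(correlation_screen(tab[1:2, ]), "3 rows")
})

test_that("variance and std are near-perfectly correlated across real windows", {
  sf <- study_features(1)
  r <- stats::cor(sf$features$variance, sf$features$std)
  expect_gt(r, 0.9)
  scr <- correlation_screen(sf$features)
  pair <- scr$flagged$feature_a == "std" & scr$flagged$feature_b == "variance" |
          scr$flagged$feature_a == "variance" & scr$flagged$feature_b == "std"
  expect_true(any(pair))
})

test_that("percentile thresholds use the linear-interpolation convention", {
  tab <- data.frame(rms = 1:100, energy = 1:100, std = 1:100)
  th <- percentile_thresholds(tab)
  expect_equal(th$rms_p75, 75.25)
  expect_equal(th$energy_p80, 80.2)
  expect_equal(th$std_p70, 70.3)

  flat <- data.frame(rms = rep(3, 10), energy = rep(4, 10), std = rep(5, 10))
  thf <- percentile_thresholds(flat)
  expect_equal(thf$rms_p75, 3)

  set.seed(9)
  shuf <- tab[sample(100), ]
  expect_equal(percentile_thresholds(shuf), th)
})

test_that("composite label requires all four criteria strictly", {
  th <- structure(list(rms_p75 = 1, energy_p80 = 10, std_p70 = 1,
                       zc_threshold = 20), class = "threshold_set")
  active <- c(rms = 2, energy = 20, std = 2, zero_crossings = 30)
  rest <- c(rms = 0.5, energy = 5, std = 0.5, zero_crossings = 3)
  boundary <- c(rms = 2, energy = 20, std = 2, zero_crossings = 20)
  expect_equal(composite_label(active, th), 1L)
  expect_equal(composite_label(rest, th), 0L)
  expect_equal(composite_label(boundary, th), 0L)  # strict > at exactly 20
})

test_that("composite labels agree with envelope truth across seeds", {
  agree <- vapply(1:10, function(s) {
    tr <- synthesize(gen_config(seed = s))
    grid <- make_grid(length(tr$samples_mv), 600, 0)
    feats <- feature_table(segment(tr, grid))
    mean(auto_label(feats)$labels == truth_window_labels(tr, grid))
  }, numeric(1))
  expect_gte(mean(agree), 0.90)
})

test_that("fisher ratio matches its closed form and rejects degenerate groups", {
  expect_equal(fisher_ratio(c(0, 1), c(2, 3)), 8)
  expect_equal(fisher_ratio(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(fisher_ratio(c(1, 1), c(1, 1)), "degenerate")
  expect_error(fisher_ratio(1, c(1, 2)), "at least 2")
})

test_that("threshold sweep scores perfectly separable labels at 1.0", {
  # synthetic population: rest windows with tiny features, active large
  # 10 active among 60: the active share sits below every percentile
  # cutoff (75th/80th/70th), as in a mostly-resting recording
  set.seed(10)
  n_rest <- 50; n_act <- 10
  truth <- rep(c(0, 1), times = c(n_rest, n_act))
  tab <- data.frame(
    rms = c(stats::runif(n_rest, 0, 0.1), stats::runif(n_act, 1, 2)),
    energy = c(stats::runif(n_rest, 0, 1), stats::runif(n_act, 50, 80)),
    std = c(stats::runif(n_rest, 0, 0.1), stats::runif(n_act, 1, 2)),
    zero_crossings = c(sample(0:5, n_rest, TRUE), sample(60:90, n_act, TRUE)))
  sw <- sensitivity_sweep(tab, truth)
  expect_equal(sw$zc_threshold, seq(10, 35, by = 5))
  expect_true(any(sw$accuracy == 1.0))
  expect_true(all(sw$false_pos_rate >= 0 & sw$false_pos_rate <= 1))
  expect_true(all(sw$fisher_ratio > 0))
  expect_error(sensitivity_sweep(tab, rep(1, n_rest + n_act)), "single class")
})
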