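#' Time-domain EMG features and composite auto-labeling
#'
#' Twelve Hudgins-style per-window features: mean, standard deviation,
#' max, min, variance, range, RMS, energy (sum of squares), mean absolute
#' value, waveform length, dead-band zero crossings, and skewness.
#' Windows are auto-labeled active/rest by a composite rule that requires
#' simultaneously elevated RMS (> 75th percentile), energy (> 80th
#' percentile), standard deviation (> 70th percentile) and zero crossings
#' (> 20). Percentile cutoffs are computed once on the labeling
#' population.
#'
#' @name features
NULL

feature_names <- c("mean", "std", "max", "min", "variance", "range",
                   "rms", "energy", "mav", "waveform_length",
                   "zero_crossings", "skewness")

#' Dead-band zero-crossing count
#'
#' Counts sign changes between consecutive samples where both samples
#' exceed the dead-band in absolute value. The dead-band suppresses
#' crossings induced by low-amplitude baseline noise; raw counting is
#' `deadband_mv = 0`.
#'
#' @param window Numeric vector (mV), length >= 2.
#' @param deadband_mv Dead-band amplitude (mV).
#' @return Integer count in `[0, length(window) - 1]`.
#' @export
zero_crossings <- function(window, deadband_mv = 0.1) {
  if (length(window) < 2) stop("window must have length >= 2")
  a <- window[-length(window)]
  b <- window[-1]
  sum(sign(a) != sign(b) & abs(a) > deadband_mv & abs(b) > deadband_mv)
}

#' Extract the 12 time-domain features from one window
#'
#' Variance, standard deviation and skewness use the population (divide
#' by n) convention; skewness of a zero-variance window is defined as 0.
#'
#' @param window Numeric vector (mV), length >= 2.
#' @param zc_deadband_mv Zero-crossing dead-band (mV).
#' @return Named numeric vector of the 12 features.
#' @export
extract_features <- function(window, zc_deadband_mv = 0.1) {
  if (length(window) < 2) stop("window must have length >= 2")
  n <- length(window)
  mu <- mean(window)
  m2 <- mean((window - mu)^2)
  m3 <- mean((window - mu)^3)
  c(mean = mu,
    std = sqrt(m2),
    max = max(window),
    min = min(window),
    variance = m2,
    range = max(window) - min(window),
    rms = sqrt(mean(window^2)),
    energy = sum(window^2),
    mav = mean(abs(window)),
    waveform_length = sum(abs(diff(window))),
    zero_crossings = zero_crossings(window, zc_deadband_mv),
    skewness = if (m2 == 0) 0 else m3 / m2^1.5)
}

#' Feature table for a set of windows
#'
#' @param windows Matrix, one window per row (as returned by [segment()]).
#' @param zc_deadband_mv Zero-crossing dead-band (mV).
#' @return A data.frame, one row per window, columns the 12 features.
#' @export
feature_table <- function(windows, zc_deadband_mv = 0.1) {
  stopifnot(is.matrix(windows))
  ft <- t(apply(windows, 1, extract_features, zc_deadband_mv = zc_deadband_mv))
  as.data.frame(ft)
}

#' Pairwise-correlation redundancy screen
#'
#' Pearson correlation of all feature pairs; pairs with `|r| > cutoff`
#' are flagged as redundant. Zero-variance columns yield undefined
#' correlations, reported as warnings and never flagged.
#'
#' @param feature_table Data.frame of features (>= 3 rows).
#' @param cutoff Absolute-correlation flag threshold (default 0.95).
#' @return List with `flagged` (data.frame of feature pairs and r),
#'   `matrix` (full correlation matrix) and `warnings` (character).
#' @export
correlation_screen <- function(feature_table, cutoff = 0.95) {
  if (nrow(feature_table) < 3) stop("need at least 3 rows")
  warns <- character(0)
  degenerate <- vapply(feature_table, function(col) stats::var(col) == 0,
                       logical(1))
  if (any(degenerate))
    warns <- paste0("zero-variance column: ",
                    names(feature_table)[degenerate])
  cm <- suppressWarnings(stats::cor(as.matrix(feature_table)))
  pairs <- which(upper.tri(cm) & !is.na(cm) & abs(cm) > cutoff,
                 arr.ind = TRUE)
  flagged <- data.frame(
    feature_a = colnames(cm)[pairs[, 1]],
    feature_b = colnames(cm)[pairs[, 2]],
    r = cm[pairs])
  list(flagged = flagged, matrix = cm, warnings = warns)
}

#' Percentile thresholds for the composite labeler
#'
#' Linear-interpolation (type 7) percentiles of the RMS, energy and
#' standard-deviation columns, computed over the whole labeling
#' population.
#'
#' @param feature_table Data.frame with `rms`, `energy`, `std` columns
#'   (>= 2 rows).
#' @param zc_threshold Zero-crossing count threshold (default 20).
#' @return An object of class `threshold_set`.
#' @export
percentile_thresholds <- function(feature_table, zc_threshold = 20) {
  if (nrow(feature_table) < 2) stop("need at least 2 rows")
  structure(list(
    rms_p75 = unname(stats::quantile(feature_table$rms, 0.75, type = 7)),
    energy_p80 = unname(stats::quantile(feature_table$energy, 0.80, type = 7)),
    std_p70 = unname(stats::quantile(feature_table$std, 0.70, type = 7)),
    zc_threshold = zc_threshold),
    class = "threshold_set")
}

#' Composite activity label for one feature vector
#'
#' Active (1) iff all four criteria hold strictly: zero crossings above
#' the count threshold, and RMS, energy and standard deviation above
#' their percentile cutoffs.
#'
#' @param fv Named numeric feature vector (from [extract_features()]).
#' @param th A [percentile_thresholds()] threshold set.
#' @return 0 or 1.
#' @export
composite_label <- function(fv, th) {
  stopifnot(inherits(th, "threshold_set"))
  as.integer(fv[["zero_crossings"]] > th$zc_threshold &&
             fv[["rms"]] > th$rms_p75 &&
             fv[["energy"]] > th$energy_p80 &&
             fv[["std"]] > th$std_p70)
}

#' Auto-label a feature table with the composite rule
#'
#' @param feature_table Data.frame of the 12 features.
#' @param zc_threshold Zero-crossing threshold (default 20).
#' @param thresholds Optional frozen [percentile_thresholds()]; when NULL
#'   the percentile cutoffs are computed on `feature_table` itself.
#' @return List with `labels` (0/1 integer vector) and `thresholds`.
#' @export
auto_label <- function(feature_table, zc_threshold = 20, thresholds = NULL) {
  th <- if (is.null(thresholds))
    percentile_thresholds(feature_table, zc_threshold)
  else thresholds
  labels <- as.integer(
    feature_table$zero_crossings > th$zc_threshold &
    feature_table$rms > th$rms_p75 &
    feature_table$energy > th$energy_p80 &
    feature_table$std > th$std_p70)
  list(labels = labels, thresholds = th)
}

#' Fisher discriminant ratio
#'
#' `(mean_a - mean_b)^2 / (var_a + var_b)` with population variances;
#' measures one-dimensional separability of two groups.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return Non-negative real.
#' @export
fisher_ratio <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 values")
  pvar <- function(x) mean((x - mean(x))^2)
  denom <- pvar(group_a) + pvar(group_b)
  if (denom == 0) stop("degenerate input: both groups are constant")
  (mean(group_a) - mean(group_b))^2 / denom
}

#' Zero-crossing threshold sensitivity sweep
#'
#' Recomputes the composite labels for each candidate zero-crossing
#' threshold (percentile cutoffs held fixed) and scores them against the
#' envelope-derived ground truth. The Fisher ratio of the zero-crossing
#' feature between the two truth classes is reported alongside.
#'
#' @param feature_table Data.frame of the 12 features.
#' @param truth_labels 0/1 ground-truth labels (from
#'   [truth_window_labels()]).
#' @param zc_grid Candidate thresholds (default 10--35 by 5).
#' @return A data.frame with columns `zc_threshold`, `accuracy`, `f1`,
#'   `false_pos_rate`, `false_neg_rate`, `fisher_ratio`.
#' @export
sensitivity_sweep <- function(feature_table, truth_labels,
                              zc_grid = seq(10, 35, by = 5)) {
  if (length(unique(truth_labels)) < 2)
    stop("truth labels contain a single class; F1 undefined")
  th0 <- percentile_thresholds(feature_table)
  fr <- fisher_ratio(feature_table$zero_crossings[truth_labels == 1],
                     feature_table$zero_crossings[truth_labels == 0])
  rows <- lapply(zc_grid, function(z) {
    th <- th0; th$zc_threshold <- z
    lab <- auto_label(feature_table, thresholds = th)$labels
    tp <- sum(lab == 1 & truth_labels == 1)
    fp <- sum(lab == 1 & truth_labels == 0)
    fn <- sum(lab == 0 & truth_labels == 1)
    tn <- sum(lab == 0 & truth_labels == 0)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(zc_threshold = z,
               accuracy = (tp + tn) / length(lab),
               f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
               false_pos_rate = if (fp + tn == 0) 0 else fp / (fp + tn),
               false_neg_rate = if (fn + tp == 0) 0 else fn / (fn + tp),
               fisher_ratio = fr)
  })
  do.call(rbind, rows)
}
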