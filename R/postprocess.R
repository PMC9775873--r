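# Robust cleanup and windowing of the beat-level features: moving-median MAD
# outlier rejection, trailing-window averaging, an HRDN-stability exclusion,
# and optional baseline normalization.

#' Moving-window scaled-MAD outlier rejection
#'
#' Flags values that deviate from the median of a centred moving window by
#' more than `k` scaled median absolute deviations, where the scaled MAD is
#' `1.4826 * median(|A - median(A)|)` for the window's values `A`. Windows
#' shrink symmetrically at the edges of the series. `NA` values are neither
#' used in the window statistics nor retained.
#'
#' @param x Numeric per-beat feature series.
#' @param window Window size in beats (default 20; the window spans
#'   `floor((window-1)/2)` beats before to `ceiling((window-1)/2)` after the
#'   current one).
#' @param k Rejection multiplier in scaled MADs (default 3).
#' @return Logical vector: `TRUE` where the value is retained. `NA` inputs
#'   give `FALSE`.
#' @export
reject_outliers_mad <- function(x, window = 20, k = 3) {
  n <- length(x)
  if (n == 0L) return(logical(0))
  before <- floor((window - 1) / 2)
  after <- ceiling((window - 1) / 2)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    win <- x[max(1L, i - before):min(n, i + after)]
    med <- stats::median(win, na.rm = TRUE)
    smad <- scaled_mad(win)
    keep[i] <- abs(x[i] - med) <= k * smad
  }
  keep
}

#' Trailing moving average of beat features over overlapping windows
#'
#' Averages each retained beat value over trailing time windows of length
#' `window` seconds whose right edges advance by `window * (1 - overlap)`
#' seconds (default: 20 s windows, 90% overlap, hence a 2 s hop). Windows are
#' half-open `(t - window, t]`. A feature's window mean is `NA` when fewer
#' than `min_beats` retained values fall in the window.
#'
#' @param features A `beat_features` data frame.
#' @param retain Logical matrix (beats x features, columns named as
#'   `FEATURE_NAMES`) from the MAD rejection step; `NULL` retains everything.
#' @param window Window length, seconds.
#' @param overlap Fractional overlap of adjacent windows in \[0, 1).
#' @param min_beats Minimum retained beats per window and feature.
#' @return A data frame with `window_time` (right edge, seconds) and one
#'   column per feature (window means).
#' @export
moving_average <- function(features, retain = NULL, window = 20,
                           overlap = 0.9, min_beats = 5) {
  hop <- window * (1 - overlap)
  stopifnot(hop > 0)
  bt <- features$beat_time
  t_last <- max(bt, na.rm = TRUE)
  edges <- seq(window, t_last + hop, by = hop)
  edges <- edges[edges - window <= t_last]
  nw <- length(edges)
  out <- data.frame(window_time = edges)
  for (f in FEATURE_NAMES) {
    v <- features[[f]]
    if (!is.null(retain)) v[!retain[, f]] <- NA_real_
    ok <- !is.na(v)
    vz <- ifelse(ok, v, 0)
    cs <- c(0, cumsum(vz))
    cc <- c(0, cumsum(ok))
    hi <- findInterval(edges, bt)                      # bt <= t
    lo <- findInterval(edges - window, bt)             # bt <= t - window
    cnt <- cc[hi + 1L] - cc[lo + 1L]
    mean_v <- (cs[hi + 1L] - cs[lo + 1L]) / cnt
    mean_v[cnt < min_beats] <- NA_real_
    out[[f]] <- mean_v
  }
  out
}

#' Centred moving standard deviation of the HRDN window means
#'
#' Computes the standard deviation of the HRDN feature averages over a
#' centred span of adjacent windows (default 21: ten windows either side),
#' shrinking symmetrically at the edges, and marks windows invalid wherever
#' it exceeds `threshold`. All features of an invalid window are excluded
#' together. The threshold is an empirically tuned stability cut; the
#' default of 0.02 s is this package's choice.
#'
#' @param hrdn_means Numeric vector of per-window HRDN means, seconds.
#' @param span Number of adjacent windows in the centred span (odd).
#' @param threshold Exclusion threshold on the moving SD, seconds.
#' @return A list with `moving_std` (numeric) and `valid` (logical; `FALSE`
#'   where the moving SD exceeds `threshold`).
#' @export
hrdn_std_exclusion <- function(hrdn_means, span = 21, threshold = 0.02) {
  if (span %% 2 == 0) stop_invalid("`span` must be odd (got %d)", span)
  n <- length(hrdn_means)
  half <- (span - 1) / 2
  mstd <- vapply(seq_len(n), function(i) {
    win <- hrdn_means[max(1L, i - half):min(n, i + half)]
    win <- win[!is.na(win)]
    if (length(win) < 2L) return(NA_real_)
    stats::sd(win)
  }, numeric(1))
  valid <- is.na(mstd) | mstd <= threshold
  list(moving_std = mstd, valid = valid)
}

#' Normalize windowed features by their baseline-phase means
#'
#' Divides every feature column by its mean over the valid windows of the
#' baseline phase, yielding dimensionless features expressed relative to the
#' subject's normovolemic state. Errors if a feature has no valid baseline
#' windows or a zero baseline mean.
#'
#' @param fs_tab A `feature_series` data frame from [postprocess_features()]
#'   (or any data frame with `window_time`, feature columns and `valid`).
#' @param baseline_end End of the baseline phase, seconds (windows with
#'   `window_time <= baseline_end` are baseline).
#' @return The table with feature columns normalized; the per-feature
#'   baseline means are attached as attribute `baseline_means`.
#' @export
baseline_normalize <- function(fs_tab, baseline_end) {
  base <- fs_tab$window_time <= baseline_end & fs_tab$valid
  means <- numeric(0)
  for (f in FEATURE_NAMES) {
    bv <- fs_tab[[f]][base]
    bv <- bv[!is.na(bv)]
    if (length(bv) == 0L)
      stop_invalid("no valid baseline windows for feature %s", f)
    m <- mean(bv)
    if (!is.finite(m) || m == 0)
      stop_invalid("baseline mean of feature %s is zero or undefined", f)
    fs_tab[[f]] <- fs_tab[[f]] / m
    means[f] <- m
  }
  attr(fs_tab, "baseline_means") <- means
  fs_tab
}

#' Full post-processing of a beat-level feature table
#'
#' Runs the cleanup chain: per-feature moving-MAD outlier rejection, trailing
#' moving-average windowing, the centred HRDN moving-SD exclusion, and
#' (optionally) baseline normalization. Bookkeeping fractions of removed data
#' are attached as attributes.
#'
#' @param features A `beat_features` data frame.
#' @param mad_window,mad_k MAD rejection parameters (beats, multiplier).
#' @param window,overlap,min_beats Averaging parameters, see
#'   [moving_average()].
#' @param std_span,std_threshold HRDN-stability parameters, see
#'   [hrdn_std_exclusion()].
#' @param normalize Either `"none"` or `"baseline"`.
#' @param baseline_end Required when `normalize = "baseline"`.
#' @return A data frame of class `feature_series`: `window_time`, the nine
#'   feature means, `hrdn_moving_std`, `valid`; attributes
#'   `excluded_fraction_mad` and `excluded_fraction_std`.
#' @export
postprocess_features <- function(features,
                                 mad_window = 20, mad_k = 3,
                                 window = 20, overlap = 0.9, min_beats = 5,
                                 std_span = 21, std_threshold = 0.02,
                                 normalize = c("none", "baseline"),
                                 baseline_end = NULL) {
  normalize <- match.arg(normalize)
  retain <- sapply(FEATURE_NAMES, function(f)
    reject_outliers_mad(features[[f]], mad_window, mad_k))
  avail <- !is.na(as.matrix(features[FEATURE_NAMES]))
  n_avail <- sum(avail)
  frac_mad <- if (n_avail > 0) sum(avail & !retain) / n_avail else 0

  out <- moving_average(features, retain, window, overlap, min_beats)
  ex <- hrdn_std_exclusion(out$HRDN, std_span, std_threshold)
  out$hrdn_moving_std <- ex$moving_std
  out$valid <- ex$valid & !is.na(out$HRDN)
  frac_std <- if (nrow(out) > 0) mean(!ex$valid) else 0

  if (normalize == "baseline") {
    if (is.null(baseline_end))
      stop_invalid("`baseline_end` is required for baseline normalization")
    out <- baseline_normalize(out, baseline_end)
  }
  attr(out, "excluded_fraction_mad") <- frac_mad
  attr(out, "excluded_fraction_std") <- frac_std
  class(out) <- c("feature_series", "data.frame")
  out
}
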