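# Signal conditioning ahead of landmark detection: lowpass denoising,
# finite-difference derivatives, and trailing-window standardization.

#' Zero-phase FIR lowpass denoising
#'
#' Smooths the raw ABP trace with a 512th-order linear-phase FIR lowpass
#' filter (Hamming window design, 12 Hz cutoff by default) applied with zero
#' phase: the symmetric kernel is centred on each sample, with reflect
#' padding of one filter order at both ends so the output has the same length
#' as the input and no edge transients inside the record.
#'
#' @param raw Numeric vector of ABP samples, mmHg.
#' @param fs Sampling rate, Hz.
#' @param order Filter order (kernel length is `order + 1`).
#' @param cutoff Cutoff frequency, Hz; must satisfy `fs > 2 * cutoff`.
#' @return Denoised series, same length as `raw`.
#' @export
lowpass_denoise <- function(raw, fs, order = 512, cutoff = 12) {
  if (fs <= 2 * cutoff)
    stop_invalid("`fs` (%g Hz) must exceed twice the cutoff (%g Hz)", fs, cutoff)
  n <- length(raw)
  if (n <= order)
    stop_invalid("signal of length %d is too short for a filter of order %d; need at least %d samples",
                 n, order, order + 1L)
  kern <- as.numeric(signal::fir1(order, cutoff / (fs / 2), type = "low"))
  kern <- kern / sum(kern)   # exact unit DC gain
  # reflect padding by one filter order at each end
  pad <- order
  x <- c(raw[(pad + 1):2], raw, raw[(n - 1):(n - pad)])
  y <- stats::filter(x, kern, method = "convolution", sides = 2)
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Finite-difference derivative approximations
#'
#' First differences for the slope (`d1[i] = x[i+1] - x[i]`, last value
#' replicated) and the central second difference for the curvature
#' (`d2[i] = x[i+1] - 2 x[i] + x[i-1]`, edges replicated). Units are signal
#' units per sample (and per sample squared): landmark logic depends only on
#' sign patterns and peak locations, which any uniform scaling preserves.
#'
#' @param x Numeric series of length >= 3.
#' @return A list with components `d1` and `d2`, same length as `x`.
#' @export
finite_differences <- function(x) {
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 samples for finite differences")
  d1 <- c(diff(x), x[n] - x[n - 1L])
  d2i <- diff(x, differences = 2L)
  d2 <- c(d2i[1L], d2i, d2i[n - 2L])
  list(d1 = d1, d2 = d2)
}

#' Trailing-window z-score standardization
#'
#' Standardizes each sample against the mean and standard deviation of the
#' trailing window ending at (and including) that sample:
#' `out[i] = (x[i] - mean(window)) / sd(window)`. This detrends slow baseline
#' drift and removes amplitude scaling ahead of landmark detection. Windows
#' are shrunk at the start of the record; the index of the first sample with
#' a complete window is returned as the `valid_from` attribute. Windows with
#' near-zero spread (sd below `1e-9` in signal units, e.g. flatline segments)
#' produce 0.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param window Trailing window length, seconds (default 2).
#' @return Standardized series with attribute `valid_from`.
#' @export
trailing_zscore <- function(x, fs, window = 2) {
  n <- length(x)
  w <- as.integer(round(window * fs))
  if (w < 2L) stop_invalid("`window` must span at least 2 samples")
  w <- min(w, n)
  # centre on the global mean before accumulating: keeps the running sums
  # well conditioned and makes flatline windows exactly degenerate
  x0 <- x - mean(x)
  cs <- c(0, cumsum(x0))
  cs2 <- c(0, cumsum(x0 * x0))
  idx <- seq_len(n)
  lo <- pmax(idx - w, 0L)              # exclusive lower bound
  cnt <- idx - lo
  s1 <- cs[idx + 1L] - cs[lo + 1L]
  s2 <- cs2[idx + 1L] - cs2[lo + 1L]
  mu <- s1 / cnt
  # sample variance with n-1 denominator; guard tiny negatives from rounding
  varv <- pmax((s2 - cnt * mu * mu) / pmax(cnt - 1, 1), 0)
  sdv <- sqrt(varv)
  out <- (x0 - mu) / sdv
  out[!is.finite(out) | sdv < 1e-9] <- 0
  attr(out, "valid_from") <- w
  out
}

#' Run all pre-processing for one recording
#'
#' Applies [lowpass_denoise()], [finite_differences()] and
#' [trailing_zscore()] (to the denoised signal and both derivatives),
#' returning every conditioned series on the input time base. Landmark
#' *timing* detection downstream runs on the standardized series, while
#' feature *amplitudes* in mmHg are read from the unstandardized denoised
#' signal.
#'
#' @param raw Numeric ABP series, mmHg.
#' @param fs Sampling rate, Hz.
#' @param order,cutoff Filter parameters, see [lowpass_denoise()].
#' @param z_window Trailing z-score window, seconds.
#' @return A list of class `processed_signals`: `fs`, `denoised`, `d1`, `d2`,
#'   `z_denoised`, `z_d1`, `z_d2`, `valid_from`.
#' @export
preprocess_signals <- function(raw, fs, order = 512, cutoff = 12,
                               z_window = 2) {
  den <- lowpass_denoise(raw, fs, order = order, cutoff = cutoff)
  dd <- finite_differences(den)
  zden <- trailing_zscore(den, fs, z_window)
  zd1 <- trailing_zscore(dd$d1, fs, z_window)
  zd2 <- trailing_zscore(dd$d2, fs, z_window)
  structure(list(
    fs = fs, denoised = den, d1 = dd$d1, d2 = dd$d2,
    z_denoised = as.numeric(zden), z_d1 = as.numeric(zd1),
    z_d2 = as.numeric(zd2),
    valid_from = attr(zden, "valid_from")
  ), class = "processed_signals")
}
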