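# Per-beat pulse-morphology features. Amplitudes are read from the denoised
# (unstandardized) signal so they stay in mmHg.
#
#   PPI  peak-to-peak interval            t_F - t_C          [s]
#   HRV  RMSSD of PPI over 10 beats                          [s]
#   HRDN half-rise to dicrotic notch      t_D - t_B          [s]
#   SBP  systolic pressure                W_C                [mmHg]
#   DBP  end-of-pulse (diastolic) value   W_E                [mmHg]
#   PP   pulse pressure                   W_C - W_A          [mmHg]
#   PA   pulse area                       integral A..E of W [mmHg s]
#   IPA  inflection point area ratio      int D..E / int A..D
#   SI   shock index                      60 / (PPI * SBP)

FEATURE_NAMES <- c("PPI", "HRV", "HRDN", "SBP", "DBP", "PP", "PA", "IPA", "SI")

#' Trailing-window RMSSD of the peak-to-peak intervals
#'
#' Root mean square of successive differences of PPI over the trailing
#' `window` beats (including the current beat). Values are `NA` until
#' `window` beats have accumulated, and wherever any PPI in the window is
#' missing.
#'
#' @param ppi Numeric vector of per-beat peak-to-peak intervals, seconds.
#' @param window Number of beats in the trailing window (default 10).
#' @return Numeric vector of the same length as `ppi`.
#' @export
#' @examples
#' compute_hrv(c(0.8, 0.9), window = 2)  # NA, 0.1
compute_hrv <- function(ppi, window = 10) {
  n <- length(ppi)
  vapply(seq_len(n), function(i) {
    if (i < window) return(NA_real_)
    dd <- diff(ppi[(i - window + 1L):i])
    if (anyNA(dd)) return(NA_real_)
    sqrt(mean(dd^2))
  }, numeric(1))
}

#' Compute the nine morphology features for every beat
#'
#' Evaluates the feature formulas above on a fiducial table and the denoised
#' pressure series. Features that depend on a missing landmark (e.g. HRDN or
#' IPA on a beat without a notch) are `NA` rather than fabricated; the
#' companion logical columns `valid_*` summarize availability.
#'
#' @param fid A `beat_fiducials` data frame from [detect_landmarks()].
#' @param denoised Denoised ABP series, mmHg.
#' @param fs Sampling rate, Hz.
#' @param hrv_window Beats in the trailing RMSSD window.
#' @return A data frame of class `beat_features` with `beat_time` (the beat
#'   onset, seconds), the nine feature columns, and `n_valid` per row.
#' @export
compute_beat_features <- function(fid, denoised, fs, hrv_window = 10) {
  nb <- nrow(fid)
  ppi <- fid$t_F - fid$t_C
  hrdn <- fid$t_D - fid$t_B
  sbp <- fid$W_C
  dbp <- fid$W_E
  pp <- fid$W_C - fid$W_A
  si <- 60 / (ppi * sbp)
  pa <- rep(NA_real_, nb)
  ipa <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    if (is.na(fid$t_A[i]) || is.na(fid$t_E[i])) next
    a <- fid$t_A[i] * fs + 1
    e <- fid$t_E[i] * fs + 1
    pa[i] <- trapz_between(denoised, a, e, fs)
    if (!is.na(fid$t_D[i])) {
      d <- fid$t_D[i] * fs + 1
      pre <- trapz_between(denoised, a, d, fs)
      post <- trapz_between(denoised, d, e, fs)
      if (pre > 0) ipa[i] <- post / pre
    }
  }
  # beats flagged malformed contribute no features at all
  bad <- !is.na(fid$exclusion_reason) & fid$exclusion_reason == "malformed_beat"
  for (v in c("ppi", "hrdn", "sbp", "dbp", "pp", "si", "pa", "ipa"))
    assign(v, replace(get(v), bad, NA_real_))
  hrv <- compute_hrv(ppi, hrv_window)
  out <- data.frame(
    beat = fid$beat, beat_time = fid$t_A,
    PPI = ppi, HRV = hrv, HRDN = hrdn, SBP = sbp, DBP = dbp,
    PP = pp, PA = pa, IPA = ipa, SI = si,
    stringsAsFactors = FALSE
  )
  out$n_valid <- rowSums(!is.na(out[FEATURE_NAMES]))
  class(out) <- c("beat_features", "data.frame")
  out
}
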