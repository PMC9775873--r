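# Beat segmentation and fiducial-point detection on the conditioned ABP
# signal. Landmarks per beat: (A) pulse onset, (B) systolic half-rise,
# (C) systolic peak, (D) dicrotic notch, (E) end of pulse (next onset),
# (F) systolic peak of the successive pulse.

#' Segment the ABP signal into beats
#'
#' Detects pulse onsets (point A, the pre-upstroke foot) from the
#' standardized first derivative: candidate upstrokes are local maxima of the
#' slope exceeding `slope_thresh` standard scores, pruned to a configurable
#' minimum beat spacing (taller upstrokes win), anchored to the local
#' pressure minimum immediately preceding each upstroke, and validated by
#' requiring the onset-to-peak rise to exceed `rise_frac` of the session's
#' robust amplitude range (so detection is invariant to affine amplitude
#' scaling). A flat or too-short signal yields an empty result.
#'
#' @param signals A `processed_signals` object from [preprocess_signals()].
#' @param min_rr,max_rr Physiologic bounds on the inter-onset interval,
#'   seconds.
#' @param slope_thresh Minimum standardized slope of an upstroke.
#' @param rise_frac Minimum onset-to-peak rise as a fraction of the robust
#'   (1st--99th percentile) amplitude range of the whole record.
#' @return Integer vector of onset sample indices (strictly increasing).
#' @export
segment_beats <- function(signals, min_rr = 0.3, max_rr = 2.0,
                          slope_thresh = 1.0, rise_frac = 0.25) {
  den <- signals$denoised
  fs <- signals$fs
  n <- length(den)
  if (n < 2 * fs) return(integer(0))
  pk <- local_maxima(signals$d1)
  pk <- pk[signals$z_d1[pk] > slope_thresh]
  if (length(pk) == 0L) return(integer(0))
  pk <- prune_peaks_min_distance(pk, signals$z_d1[pk],
                                 as.integer(round(min_rr * fs)))
  rng <- stats::quantile(den, c(0.01, 0.99), names = FALSE)
  amp <- rng[2] - rng[1]
  if (amp < 1e-12) return(integer(0))
  back <- as.integer(round(0.25 * fs))
  onsets <- integer(length(pk))
  keep <- logical(length(pk))
  for (j in seq_along(pk)) {
    u <- pk[j]
    lo <- max(1L, u - back)
    o <- lo + which.min(den[lo:u]) - 1L
    # validate: rise from the foot over the following upstroke
    hi <- min(n, u + back)
    rise <- max(den[u:hi]) - den[o]
    if (rise >= rise_frac * amp) {
      onsets[j] <- o
      keep[j] <- TRUE
    }
  }
  onsets <- sort(unique(onsets[keep]))
  if (length(onsets) > 1L) {
    # enforce the minimum inter-onset spacing after foot anchoring
    out <- onsets[1L]
    for (o in onsets[-1L]) {
      if ((o - out[length(out)]) / fs >= min_rr) out <- c(out, o)
    }
    onsets <- out
  }
  onsets
}

#' Select the dicrotic notch among first-derivative candidates
#'
#' Applies the credible-range rule: among candidate notches (first-derivative
#' peaks) whose time lies within `range` (default 15--40%) of the
#' peak-to-peak interval measured from the pulse onset, the maximally
#' prominent one is selected; ties go to the earliest candidate. Returns
#' `NULL` when no candidate qualifies (the beat is then excluded).
#'
#' @param candidates Data frame with columns `time` (seconds) and
#'   `prominence` (standardized first-derivative prominence).
#' @param t_A Pulse onset time, seconds.
#' @param ppi Peak-to-peak interval of the beat, seconds.
#' @param range Credible window as a fraction of `ppi` (length-2 vector).
#' @param min_prominence Candidates below this prominence are ignored.
#' @return The chosen candidate row (a one-row data frame), or `NULL`.
#' @export
select_dicrotic_notch <- function(candidates, t_A, ppi,
                                  range = c(0.15, 0.40),
                                  min_prominence = 0) {
  if (is.null(candidates) || nrow(candidates) == 0L || ppi <= 0) return(NULL)
  frac <- (candidates$time - t_A) / ppi
  ok <- frac >= range[1] & frac <= range[2] &
    candidates$prominence >= min_prominence
  if (!any(ok)) return(NULL)
  cand <- candidates[ok, , drop = FALSE]
  best <- which(cand$prominence == max(cand$prominence))
  cand[best[which.min(cand$time[best])], , drop = FALSE]
}

#' Locate all fiducial landmarks for every beat
#'
#' For each segmented beat: the systolic peak C is the maximal denoised
#' sample within the beat; the half-rise B is the first upstroke crossing of
#' `(W_A + W_C)/2` (linearly interpolated between samples); the dicrotic
#' notch D comes from [select_dicrotic_notch()] applied to the
#' first-derivative peaks after C, then refined to the local pressure minimum
#' immediately preceding the chosen derivative peak; E is the onset of the
#' successive pulse and F its systolic peak. Beats with an unresolvable
#' landmark are emitted with an `exclusion_reason` (`"no_notch_candidate"` or
#' `"malformed_beat"`) rather than dropped, and the final beat of a record
#' (which has no successive peak, hence no PPI) is always marked
#' `"malformed_beat"`.
#'
#' @param signals A `processed_signals` object.
#' @param onsets Onset indices from [segment_beats()] (computed when `NULL`).
#' @param notch_range Credible notch window as a fraction of PPI.
#' @param min_prominence Minimum standardized-derivative prominence of a
#'   notch candidate.
#' @param min_pulse_frac Minimum beat amplitude (onset to peak) as a fraction
#'   of the record's robust amplitude range; smaller beats are marked
#'   malformed.
#' @param ... Passed to [segment_beats()] when `onsets` is `NULL`.
#' @return A data frame of class `beat_fiducials`, one row per beat, with
#'   columns `beat`, `t_A` .. `t_F` (seconds), `W_A`, `W_C`, `W_D`, `W_E`
#'   (mmHg), `notch_found`, `exclusion_reason` (`NA` when fully resolved).
#' @export
detect_landmarks <- function(signals, onsets = NULL,
                             notch_range = c(0.15, 0.40),
                             min_prominence = 0.25,
                             min_pulse_frac = 0.25, ...) {
  if (is.null(onsets)) onsets <- segment_beats(signals, ...)
  den <- signals$denoised
  fs <- signals$fs
  n <- length(den)
  nb <- length(onsets)
  empty <- data.frame(
    beat = integer(0), t_A = numeric(0), t_B = numeric(0), t_C = numeric(0),
    t_D = numeric(0), t_E = numeric(0), t_F = numeric(0),
    W_A = numeric(0), W_C = numeric(0), W_D = numeric(0), W_E = numeric(0),
    notch_found = logical(0), exclusion_reason = character(0),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("beat_fiducials", "data.frame")
  if (nb < 2L) return(empty)

  rng <- stats::quantile(den, c(0.01, 0.99), names = FALSE)
  amp <- rng[2] - rng[1]

  # systolic peak index for each beat: global max within [onset, next onset)
  ends <- c(onsets[-1L], min(n, onsets[nb] + as.integer(round(1.5 * fs))))
  peaks <- integer(nb)
  for (i in seq_len(nb)) {
    a <- onsets[i]; b <- max(a + 1L, ends[i] - 1L)
    peaks[i] <- a + which.max(den[a:b]) - 1L
  }

  t_of <- function(i) (i - 1) / fs
  t_A <- t_of(onsets)
  t_B <- t_C <- t_D <- t_E <- t_F <- rep(NA_real_, nb)
  W_A <- den[onsets]
  W_C <- W_D <- W_E <- rep(NA_real_, nb)
  notch_found <- logical(nb)
  reason <- rep(NA_character_, nb)

  for (i in seq_len(nb)) {
    if (i == nb) {
      reason[i] <- "malformed_beat"   # no successive peak -> no PPI
      next
    }
    a <- onsets[i]
    e <- onsets[i + 1L]
    cidx <- peaks[i]
    t_E[i] <- t_of(e)
    W_E[i] <- den[e]
    t_C[i] <- t_of(cidx)
    W_C[i] <- den[cidx]
    t_F[i] <- t_of(peaks[i + 1L])
    if (cidx <= a || den[cidx] - den[a] < min_pulse_frac * amp) {
      reason[i] <- "malformed_beat"
      next
    }
    # B: first crossing of the half-rise level between A and C
    half <- (den[a] + den[cidx]) / 2
    j <- which(den[a:cidx] >= half)[1L]
    if (is.na(j) || j == 1L) {
      reason[i] <- "malformed_beat"
      next
    }
    j_abs <- a + j - 1L
    fr <- (half - den[j_abs - 1L]) / (den[j_abs] - den[j_abs - 1L])
    t_B[i] <- t_of(j_abs - 1L) + fr / fs

    ppi <- t_F[i] - t_C[i]
    # notch candidates: local maxima of the standardized first derivative
    # strictly inside (C, E); prominence on the same series
    zseg <- signals$z_d1[cidx:e]
    cand_rel <- if (e - cidx >= 3L) local_maxima(zseg) else integer(0)
    chosen <- NULL
    if (length(cand_rel) > 0L) {
      cand_abs <- cidx + cand_rel - 1L
      prom <- peak_prominence(zseg, cand_rel)
      chosen <- select_dicrotic_notch(
        data.frame(time = t_of(cand_abs), prominence = prom, idx = cand_abs),
        t_A = t_A[i], ppi = ppi, range = notch_range,
        min_prominence = min_prominence)
    }
    if (!is.null(chosen)) {
      # refine D to the local pressure minimum preceding the derivative peak
      j <- chosen$idx[1L]
      while (j > cidx + 1L && den[j - 1L] < den[j]) j <- j - 1L
      if ((t_of(j) - t_A[i]) / ppi >= notch_range[1]) {
        t_D[i] <- t_of(j)
        W_D[i] <- den[j]
        notch_found[i] <- TRUE
      }
    }
    if (!notch_found[i]) reason[i] <- "no_notch_candidate"
  }
  out <- data.frame(
    beat = seq_len(nb), t_A = t_A, t_B = t_B, t_C = t_C, t_D = t_D,
    t_E = t_E, t_F = t_F, W_A = W_A, W_C = W_C, W_D = W_D, W_E = W_E,
    notch_found = notch_found, exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("beat_fiducials", "data.frame")
  out
}
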