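# Synthetic ABP session generator. Builds beat-by-beat waveforms whose pulse
# morphology tracks the reference compensatory reserve, together with a truth
# table of every landmark and feature so the downstream pipeline can be
# validated without access to human recordings.

# Pulse template construction.
#
# The landmarks must survive the pipeline's zero-phase 12 Hz lowpass with
# their locations intact, which dictates the local geometry: extrema that
# are locally symmetric (equal slopes at a V/Lambda junction, or matched
# curvature on both sides of a smooth minimum) are preserved exactly by
# convolution with a symmetric kernel, while flat or one-sidedly sharp
# corners drift or ring. The template therefore uses blended
# cosine/quadratic/linear rise segments whose junction slopes are matched:
#   - pulse onset: V junction, diastolic end-slope = upstroke foot slope;
#   - systolic peak: Lambda junction with a small matched slope;
#   - dicrotic notch: C1 minimum with curvature balanced on both sides
#     (the notch-to-dicrotic-peak gap is half the peak-to-notch fall span).
#
# Rise mixing weights: mostly half-cosine, a little quadratic (sets the
# foot slope) and linear (sets the peak slope).
RISE_A_COS <- 0.90
RISE_A_QUAD <- 0.06
RISE_A_LIN <- 0.04
FOOT_MATCH <- 2.2   # diastolic-to-upstroke slope ratio at the onset V

# unit rise r(u): r(0) = 0, r(1) = 1, r'(0) = 2*A_QUAD + A_LIN,
# r'(1) = A_LIN
unit_rise <- function(u) {
  RISE_A_COS * (0.5 - 0.5 * cos(pi * u)) +
    RISE_A_QUAD * u * (2 - u) + RISE_A_LIN * u
}

# Fraction of the onset-to-peak time at which the systolic half-rise occurs
# (r(u) = 1/2); a fixed constant of the template, solved once.
half_rise_frac <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- stats::uniroot(function(u) unit_rise(u) - 0.5, c(0.2, 0.8),
                               tol = 1e-12)$root
    cache
  }
})

# Time from the dicrotic notch to the dicrotic wave peak. Half of the
# systolic-peak-to-notch fall span balances the curvature on both sides of
# the notch.
dicrotic_gap_for <- function(hrdn, t_pk) {
  fall <- half_rise_frac() * t_pk + hrdn - t_pk
  min(max(0.5 * fall, 0.03), 0.12)
}

# Evaluate the unit pulse shape s(tau) in [0, 1] for tau in [0, period):
# blended rise to the systolic peak, cosine fall to the notch (start slope
# matched to the rise's peak slope), half-cosine dicrotic wave, and a
# cosine/quadratic diastolic decay whose end slope matches the next foot's
# upstroke slope. A "no_notch" artifact replaces everything after the peak
# by a single monotone decay.
pulse_shape <- function(tau, period, t_pk, hrdn, gap,
                        notch_level = 0.40, dicrotic_level = 0.55,
                        artifact = "none") {
  s <- numeric(length(tau))
  foot_slope <- 2 * RISE_A_QUAD + RISE_A_LIN    # per unit of t_pk
  up <- tau >= 0 & tau < t_pk
  s[up] <- unit_rise(tau[up] / t_pk)

  # Diastolic decay from level h at time ts to 0 at the end of the beat:
  # a half-cosine fall onto a short linear run-in whose slope overmatches
  # the upstroke foot slope by FOOT_MATCH. The upstroke side of the onset V
  # steepens away from the junction while a matched-slope decay flattens,
  # which would let the smoothed minimum drift into the decay; the linear,
  # slightly steeper run-in keeps the filtered minimum on the true foot.
  eval_decay <- function(tt, ts, h) {
    out <- numeric(length(tt))
    t_v <- min(0.05, 0.3 * (period - ts))
    v0 <- min(FOOT_MATCH * foot_slope * t_v / t_pk, 0.5 * h)
    t_lin <- period - t_v
    main <- tt < t_lin
    out[main] <- v0 + (h - v0) *
      (0.5 - 0.5 * cos(pi * (t_lin - tt[main]) / (t_lin - ts)))
    out[!main] <- v0 * (period - tt[!main]) / t_v
    out
  }

  if (artifact == "no_notch") {
    dn <- tau >= t_pk & tau < period
    s[dn] <- eval_decay(tau[dn], t_pk, 1)
    return(s)
  }
  t_n <- half_rise_frac() * t_pk + hrdn
  t_dw <- t_n + gap
  t_fall <- t_n - t_pk
  # fall start slope matched to the rise's peak slope (Lambda junction)
  bq <- min(max(RISE_A_LIN * t_fall / (2 * (1 - notch_level) * t_pk), 0), 0.3)
  seg2 <- tau >= t_pk & tau < t_n
  v <- (tau[seg2] - t_pk) / t_fall
  s[seg2] <- 1 - (1 - notch_level) *
    ((1 - bq) * (0.5 - 0.5 * cos(pi * v)) + bq * v * (2 - v))
  seg3 <- tau >= t_n & tau < t_dw
  s[seg3] <- notch_level + (dicrotic_level - notch_level) *
    (0.5 - 0.5 * cos(pi * (tau[seg3] - t_n) / gap))
  seg4 <- tau >= t_dw & tau < period
  s[seg4] <- eval_decay(tau[seg4], t_dw, dicrotic_level)
  s
}

# Trapezoidal integral over irregularly spaced samples.
trapz_irregular <- function(t, v) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (v[-n] + v[-1L])) / 2
}

#' Flat protocol trace at a constant compensatory reserve
#'
#' Convenience constructor for controlled experiments: a chamber-pressure
#' trace held constant so that the reference CRM is `crm` throughout.
#'
#' @param duration Session length, seconds.
#' @param crm Constant CRM percentage in \[0, 100\].
#' @param pmax Session maximum pressure magnitude, mmHg.
#' @param sample_interval Trace sample spacing, seconds.
#' @return An `lbnp_trace` data frame (phase label `"baseline"`).
#' @export
constant_crm_protocol <- function(duration, crm = 100, pmax = 60,
                                  sample_interval = 1) {
  p <- pmax * (1 - crm / 100)
  times <- seq(0, duration, by = sample_interval)
  out <- data.frame(time_s = times,
                    pressure_mmhg = rep(p, length(times)),
                    phase = "baseline", stringsAsFactors = FALSE)
  attr(out, "pmax") <- pmax
  attr(out, "down_rate") <- NA_real_
  attr(out, "up_rate") <- NA_real_
  class(out) <- c("lbnp_trace", "data.frame")
  out
}

#' Synthesize an ABP recording for one LBNP session
#'
#' Generates a continuous ABP waveform beat by beat. For each beat the
#' reference CRM at the beat onset is mapped to pulse-morphology parameters
#' via [crm_to_morphology()]; beat-level jitter is added to the period and to
#' the true HRDN; occasional artifact beats (a missing dicrotic notch, or an
#' amplitude spike) are injected at `subject$artifact_rate` per minute; and
#' the assembled clean waveform receives slow sinusoidal baseline drift plus
#' additive white measurement noise. Identical seeds reproduce the output
#' bit for bit.
#'
#' @param trace An `lbnp_trace` protocol (see [build_protocol()]).
#' @param subject A [subject_physiology()] object.
#' @param fs Sampling rate, Hz (default 500).
#' @param seed Integer seed for all beat-level randomness.
#' @param session_id Identifier stored in the recording metadata.
#' @return A list of class `abp_recording` with elements `abp` (mmHg samples,
#'   sample i at time (i-1)/fs), `fs`, `trace`, `meta` (subject/session ids,
#'   ramp rates, pmax), and `truth` -- a data frame with one row per complete
#'   synthesized beat: onset/half-rise/peak/notch times, the true values of
#'   all nine morphology features, the reference CRM at the beat, and the
#'   artifact label.
#' @export
synthesize_session <- function(trace, subject, fs = 500, seed = 1,
                               session_id = "sess1") {
  stopifnot(is.data.frame(trace), nrow(trace) >= 2L)
  if (fs <= 50) stop_invalid("`fs` must comfortably exceed the waveform bandwidth")
  set.seed(seed)
  t_end <- trace$time_s[nrow(trace)]
  n_samples <- floor(t_end * fs)
  w <- numeric(n_samples)

  max_beats <- ceiling(t_end / 0.3) + 1L
  onset <- t_half <- t_peak <- t_notch <- period <- numeric(max_beats)
  sbp <- dbp <- pp <- pa <- ipa <- crm_v <- numeric(max_beats)
  artifact <- character(max_beats)

  p_artifact_min <- subject$artifact_rate / 60
  crmfun <- stats::approxfun(trace$time_s, compute_reference_crm(trace), rule = 2)
  t0 <- 0
  k <- 0L
  while (TRUE) {
    crm <- crmfun(t0)
    m <- crm_to_morphology(crm, subject)
    per <- m$period + stats::rnorm(1, 0, subject$jitter_sd)
    per <- min(max(per, 0.35), 2.0)
    if (t0 + per > t_end) break
    hrdn <- m$hrdn + stats::rnorm(1, 0, subject$hrdn_noise_sd)
    t_pk <- m$systolic_peak_time
    beta <- half_rise_frac()
    # keep the notch and dicrotic wave strictly inside the beat
    hrdn <- min(max(hrdn, (1 - beta) * t_pk + 0.05),
                per - beta * t_pk - 0.15)
    gap <- dicrotic_gap_for(hrdn, t_pk)
    art <- "none"
    if (stats::runif(1) < p_artifact_min * per) {
      art <- if (stats::runif(1) < 0.5) "no_notch" else "spike"
    }
    ppb <- m$pulse_pressure * if (art == "spike") 1.7 else 1

    i0 <- as.integer(ceiling(t0 * fs - 1e-9)) + 1L
    i1 <- min(as.integer(ceiling((t0 + per) * fs - 1e-9)), n_samples)
    if (i0 <= i1) {
      tau <- (seq.int(i0, i1) - 1) / fs - t0
      s <- pulse_shape(tau, per, t_pk, hrdn, gap,
                       m$notch_level, m$dicrotic_level, artifact = art)
      seg <- m$diastolic_level + ppb * s
      w[i0:i1] <- seg
    } else {
      seg <- numeric(0)
    }

    k <- k + 1L
    onset[k] <- t0
    t_half[k] <- t0 + beta * t_pk
    t_peak[k] <- t0 + t_pk
    t_notch[k] <- if (art == "no_notch") NA_real_ else t0 + beta * t_pk + hrdn
    period[k] <- per
    crm_v[k] <- crm
    artifact[k] <- art
    sbp[k] <- m$diastolic_level + ppb
    dbp[k] <- m$diastolic_level
    pp[k] <- ppb
    # true areas from the clean segment, with exact end values (s = 0)
    tt <- c(t0, (seq.int(i0, i1) - 1) / fs, t0 + per)
    vv <- c(m$diastolic_level, seg, m$diastolic_level)
    pa[k] <- trapz_irregular(tt, vv)
    if (art == "no_notch") {
      ipa[k] <- NA_real_
    } else {
      tn_abs <- t_notch[k]
      wn <- m$diastolic_level + ppb * m$notch_level
      pre <- tt <= tn_abs
      a1 <- trapz_irregular(c(tt[pre], tn_abs), c(vv[pre], wn))
      a2 <- trapz_irregular(c(tn_abs, tt[!pre]), c(wn, vv[!pre]))
      ipa[k] <- a2 / a1
    }
    t0 <- t0 + per
  }

  keep <- seq_len(k)
  truth <- data.frame(
    beat = keep,
    t_onset = onset[keep], t_half_rise = t_half[keep],
    t_peak = t_peak[keep], t_notch = t_notch[keep],
    period = period[keep], crm = crm_v[keep],
    artifact = artifact[keep],
    sbp = sbp[keep], dbp = dbp[keep], pp = pp[keep],
    pa = pa[keep], ipa = ipa[keep],
    stringsAsFactors = FALSE
  )
  # peak-to-peak interval (PPI = next systolic peak minus this one)
  truth$ppi <- c(diff(truth$t_peak), NA_real_)
  truth$hrdn <- truth$t_notch - truth$t_half_rise
  truth$si <- 60 / (truth$ppi * truth$sbp)
  # trailing 10-beat RMSSD of true PPI
  truth$hrv <- vapply(seq_len(nrow(truth)), function(i) {
    if (i < 10L) return(NA_real_)
    dd <- diff(truth$ppi[(i - 9L):i])
    if (anyNA(dd)) return(NA_real_)
    sqrt(mean(dd^2))
  }, numeric(1))

  # slow baseline drift + white measurement noise
  tgrid <- (seq_len(n_samples) - 1) / fs
  if (subject$drift_amplitude > 0)
    w <- w + subject$drift_amplitude * sin(2 * pi * tgrid / 45)
  if (subject$waveform_noise_sd > 0)
    w <- w + stats::rnorm(n_samples, 0, subject$waveform_noise_sd)

  structure(list(
    abp = w, fs = fs, trace = trace, truth = truth,
    meta = list(subject_id = subject$subject_id, session_id = session_id,
                down_rate = attr(trace, "down_rate"),
                up_rate = attr(trace, "up_rate"),
                pmax = attr(trace, "pmax"))
  ), class = "abp_recording")
}

#' @export
print.abp_recording <- function(x, ...) {
  cat(sprintf("<abp_recording> subject %s, session %s: %.1f min at %g Hz, %d beats\n",
              x$meta$subject_id, x$meta$session_id,
              length(x$abp) / x$fs / 60, x$fs, nrow(x$truth)))
  invisible(x)
}

#' Plan a ramped-LBNP study cohort
#'
#' Lays out the session schedule of the ramped-LBNP study design: each
#' subject performs one depressurization-only session at an assigned ramp
#' rate drawn from \{3, 6, 9\} mmHg/min, followed by three down/up ramp
#' sessions at that same depressurization rate, with the first
#' repressurization at the assigned rate and the remaining two at the other
#' two rates in random order. Each subject's tolerance pressure (the session
#' `pmax`) is drawn uniformly from `pmax_range`.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param seed Integer seed for rate assignment and tolerance draws.
#' @param pmax_range Range of subject tolerance pressures, mmHg.
#' @return A data frame with one row per session: `subject_idx`,
#'   `session_id`, `down_rate`, `up_rate` (`NA` for the depressurization-only
#'   session) and `pmax`.
#' @export
study_cohort_plan <- function(n_subjects = 13, seed = 1,
                              pmax_range = c(55, 85)) {
  set.seed(seed)
  rates <- c(3, 6, 9)
  rows <- lapply(seq_len(n_subjects), function(i) {
    r0 <- sample(rates, 1)
    others <- sample(setdiff(rates, r0))
    pmax <- stats::runif(1, pmax_range[1], pmax_range[2])
    data.frame(
      subject_idx = i,
      session_id = sprintf("S%02d_%d", i, 1:4),
      down_rate = r0,
      up_rate = c(NA_real_, r0, others),
      pmax = pmax,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
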