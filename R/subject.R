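# Virtual-subject physiology and the mapping from compensatory reserve to
# pulse morphology parameters.

#' Define a virtual subject's baseline physiology
#'
#' Bundles the baseline hemodynamics and response sensitivities that drive the
#' synthetic ABP generator. As the compensatory reserve falls from 100% to 0%
#' the generator raises heart rate (tachycardia), narrows pulse pressure
#' (reduced stroke volume with vasoconstriction), and shortens the
#' ejected-to-reflected-wave delay -- hence the half-rise-to-dicrotic-notch
#' time (HRDN) -- in proportion to the subject's `*_gain` sensitivities.
#'
#' @param subject_id Character or integer identifier.
#' @param baseline_heart_rate Resting heart rate, beats/min.
#' @param baseline_dbp Resting diastolic pressure, mmHg.
#' @param baseline_pp Resting pulse pressure, mmHg (SBP = DBP + PP).
#' @param baseline_hrdn Resting half-rise to dicrotic notch time, seconds
#'   (must lie in (0.15, 0.45)).
#' @param hr_gain Fractional heart-rate rise at full deficit (CRM = 0).
#' @param pp_gain Fractional pulse-pressure fall at full deficit.
#' @param hrdn_gain Fractional HRDN shortening at full deficit.
#' @param waveform_noise_sd Additive white waveform noise SD, mmHg.
#' @param jitter_sd Beat-to-beat period jitter SD, seconds.
#' @param hrdn_noise_sd Beat-level HRDN noise SD, seconds.
#' @param artifact_rate Expected artifact beats per minute.
#' @param drift_amplitude Amplitude of slow baseline drift, mmHg.
#'
#' @return A list of class `subject_physiology`.
#' @export
subject_physiology <- function(subject_id,
                               baseline_heart_rate = 65,
                               baseline_dbp = 72,
                               baseline_pp = 46,
                               baseline_hrdn = 0.20,
                               hr_gain = 0.5,
                               pp_gain = 0.30,
                               hrdn_gain = 0.45,
                               waveform_noise_sd = 1,
                               jitter_sd = 0.010,
                               hrdn_noise_sd = 0.010,
                               artifact_rate = 1,
                               drift_amplitude = 1.5) {
  if (baseline_dbp <= 0 || baseline_pp <= 0)
    stop_invalid("baseline pressures must be positive (SBP > DBP > 0)")
  if (baseline_hrdn <= 0.15 || baseline_hrdn >= 0.45)
    stop_invalid("`baseline_hrdn` must lie in (0.15, 0.45) s")
  if (any(c(hr_gain, pp_gain, hrdn_gain) < 0))
    stop_invalid("response gains must be nonnegative")
  structure(list(
    subject_id = as.character(subject_id),
    baseline_heart_rate = baseline_heart_rate,
    baseline_dbp = baseline_dbp,
    baseline_pp = baseline_pp,
    baseline_sbp = baseline_dbp + baseline_pp,
    baseline_hrdn = baseline_hrdn,
    hr_gain = hr_gain,
    pp_gain = pp_gain,
    hrdn_gain = hrdn_gain,
    waveform_noise_sd = waveform_noise_sd,
    jitter_sd = jitter_sd,
    hrdn_noise_sd = hrdn_noise_sd,
    artifact_rate = artifact_rate,
    drift_amplitude = drift_amplitude
  ), class = "subject_physiology")
}

#' Sample a cohort of virtual subjects
#'
#' Draws `n` virtual subjects with baseline parameters from plausible resting
#' ranges for healthy adults: heart rate U(60, 72) bpm, DBP U(65, 80) mmHg,
#' pulse pressure U(40, 55) mmHg, HRDN N(0.20, 0.008) s (truncated to
#' \[0.18, 0.22\]), and response gains with modest spread. The narrow HRDN
#' spread reflects that absolute HRDN is informative across subjects without
#' per-subject baseline normalization.
#'
#' @param n Number of subjects.
#' @param seed Integer seed for the cohort draw.
#' @param ... Overrides passed on to every [subject_physiology()] call
#'   (e.g. `artifact_rate = 0` or zeroed gains for controlled experiments).
#' @return A list of `subject_physiology` objects.
#' @export
sample_cohort <- function(n, seed = 1, ...) {
  set.seed(seed)
  overrides <- list(...)
  lapply(seq_len(n), function(i) {
    draw <- list(
      subject_id = sprintf("S%02d", i),
      baseline_heart_rate = stats::runif(1, 60, 72),
      baseline_dbp = stats::runif(1, 65, 80),
      baseline_pp = stats::runif(1, 40, 55),
      baseline_hrdn = min(max(stats::rnorm(1, 0.20, 0.008), 0.18), 0.22),
      hr_gain = stats::runif(1, 0.45, 0.55),
      pp_gain = stats::runif(1, 0.25, 0.35),
      hrdn_gain = min(max(stats::rnorm(1, 0.45, 0.04), 0.32), 0.58)
    )
    draw[names(overrides)] <- overrides
    do.call(subject_physiology, draw)
  })
}

#' Map compensatory reserve to pulse-morphology parameters
#'
#' Strictly monotone mapping from CRM (percent) to the beat template
#' parameters: as CRM falls from 100 to 0 the cardiac period shortens, pulse
#' pressure narrows, and the true HRDN (ejected-to-reflected-wave delay proxy)
#' shortens. At CRM = 100 all parameters equal the subject baseline.
#'
#' @param crm CRM percentage in \[0, 100\] (scalar).
#' @param subject A [subject_physiology()] object.
#' @return A list of class `pulse_morph_params` with elements `period`,
#'   `systolic_peak_time` (time from pulse onset to the systolic peak, s),
#'   `hrdn` (true half-rise to notch delay, s), `dicrotic_gap` (notch to
#'   dicrotic-wave-peak time, s), `pulse_pressure` and `diastolic_level`
#'   (mmHg), `notch_level` and `dicrotic_level` (fractions of pulse pressure).
#' @export
crm_to_morphology <- function(crm, subject) {
  if (!is.numeric(crm) || length(crm) != 1L || is.na(crm) || crm < 0 || crm > 100)
    stop_invalid("`crm` must be a single value in [0, 100] percent")
  d <- (100 - crm) / 100
  period0 <- 60 / subject$baseline_heart_rate
  period <- period0 / (1 + subject$hr_gain * d)
  pp <- subject$baseline_pp * (1 - subject$pp_gain * d)
  hrdn <- subject$baseline_hrdn * (1 - subject$hrdn_gain * d)
  # the systolic upstroke shrinks mildly with the period so landmark
  # fractions of the beat stay physiologic at high heart rates
  scl <- sqrt(period / 0.9)
  t_pk <- min(max(0.11 * scl, 0.07), 0.14)
  structure(list(
    period = period,
    systolic_peak_time = t_pk,
    hrdn = hrdn,
    dicrotic_gap = dicrotic_gap_for(hrdn, t_pk),
    pulse_pressure = pp,
    diastolic_level = subject$baseline_dbp,
    notch_level = 0.40,
    dicrotic_level = 0.55
  ), class = "pulse_morph_params")
}
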