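# Configuration and the end-to-end pipeline: simulate (or read) recordings,
# condition signals, detect landmarks, compute and clean features, fit and
# cross-validate the CRM regressor, and report every evaluation metric.

#' Default pipeline configuration
#'
#' Returns the full set of tunables as a nested list. Values marked (study)
#' are the protocol constants of the processing chain this package
#' implements: 512th-order 12 Hz zero-phase FIR, 2 s trailing z-score,
#' 15--40% of PPI notch window, 20-beat/3-scaled-MAD outlier rejection,
#' 20 s / 90%-overlap averaging, 21-window centred HRDN SD, 100-estimator
#' squared-error boosting, 5 subject-wise folds, ROC thresholds 70/40/5%.
#' The remaining values (detector thresholds, the 0.02 s HRDN-SD cut, tree
#' depth, learning rate, simulator physiology) are this package's defaults.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    preprocess = list(filter_order = 512, cutoff_hz = 12, z_window_s = 2),
    fiducial = list(min_rr_s = 0.3, max_rr_s = 2.0, slope_thresh = 1.0,
                    rise_frac = 0.25, notch_range = c(0.15, 0.40),
                    min_prominence = 0.25, min_pulse_frac = 0.25),
    features = list(hrv_window = 10),
    postprocess = list(mad_window = 20, mad_k = 3, window_s = 20,
                       overlap = 0.9, min_beats = 5, std_span = 21,
                       std_threshold_s = 0.02),
    dataset = list(feature_set = "all", phase_selection = "full",
                   normalization = "none"),
    model = list(model_kind = "gb_tree", n_estimators = 100, max_depth = 3,
                 learning_rate = 0.1),
    cv = list(folds = 5),
    evaluate = list(auc_thresholds = c(70, 40, 5)),
    synth = list(fs = 500, n_subjects = 13, pmax_range = c(55, 85)),
    seed = 1
  )
}

# Merge user overrides into the defaults, erroring on any unknown key.
merge_config <- function(config = list()) {
  defaults <- default_config()
  merge <- function(def, usr, path = "") {
    for (nm in names(usr)) {
      full <- if (path == "") nm else paste0(path, "$", nm)
      if (!nm %in% names(def))
        stop_invalid("unknown configuration key: %s", full)
      if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        def[[nm]] <- merge(def[[nm]], usr[[nm]], full)
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  merge(defaults, config)
}

#' Extract the windowed feature series from one ABP recording
#'
#' Runs signal conditioning, beat segmentation, landmark detection, per-beat
#' feature computation and post-processing for a single recording, returning
#' the windowed feature series plus per-stage exclusion counters.
#'
#' @param recording An `abp_recording` (from [synthesize_session()] or
#'   [read_recording()]).
#' @param config Pipeline configuration overrides (see [default_config()]).
#' @return A list of class `extracted_session`: `features` (a
#'   `feature_series`), `fiducials`, `beat_features`, `trace`, `meta`, and
#'   `counters` (beats detected, beats without a notch, MAD- and
#'   HRDN-SD-excluded fractions).
#' @export
extract_features <- function(recording, config = list()) {
  cfg <- merge_config(config)
  pp <- cfg$preprocess
  fi <- cfg$fiducial
  sig <- preprocess_signals(recording$abp, recording$fs,
                            order = pp$filter_order, cutoff = pp$cutoff_hz,
                            z_window = pp$z_window_s)
  onsets <- segment_beats(sig, min_rr = fi$min_rr_s, max_rr = fi$max_rr_s,
                          slope_thresh = fi$slope_thresh,
                          rise_frac = fi$rise_frac)
  fid <- detect_landmarks(sig, onsets, notch_range = fi$notch_range,
                          min_prominence = fi$min_prominence,
                          min_pulse_frac = fi$min_pulse_frac)
  if (nrow(fid) == 0L)
    stop_invalid("no beats detected in session %s", recording$meta$session_id)
  po <- cfg$postprocess
  beats <- compute_beat_features(fid, sig$denoised, sig$fs,
                                 hrv_window = cfg$features$hrv_window)
  feats <- postprocess_features(
    beats, mad_window = po$mad_window, mad_k = po$mad_k,
    window = po$window_s, overlap = po$overlap, min_beats = po$min_beats,
    std_span = po$std_span, std_threshold = po$std_threshold_s
  )
  counters <- list(
    n_beats = nrow(fid),
    n_no_notch = sum(!is.na(fid$exclusion_reason) &
                       fid$exclusion_reason == "no_notch_candidate"),
    n_malformed = sum(!is.na(fid$exclusion_reason) &
                        fid$exclusion_reason == "malformed_beat"),
    excluded_fraction_mad = attr(feats, "excluded_fraction_mad"),
    excluded_fraction_std = attr(feats, "excluded_fraction_std")
  )
  structure(list(features = feats, fiducials = fid, beat_features = beats,
                 trace = recording$trace, meta = recording$meta,
                 counters = counters),
            class = "extracted_session")
}

#' Simulate and extract a full study cohort
#'
#' Plans a ramped-LBNP cohort with [study_cohort_plan()], draws the subjects
#' with [sample_cohort()], synthesizes every session and runs
#' [extract_features()] on each, discarding the raw waveforms. Subject
#' physiology overrides (e.g. `artifact_rate = 0`) can be passed through
#' `...`.
#'
#' @param n_subjects Number of subjects.
#' @param seed Master seed; subject draws and per-session synthesis seeds
#'   derive from it.
#' @param config Pipeline configuration overrides.
#' @param keep_truth Keep each session's truth table in the result.
#' @param ... Overrides forwarded to [sample_cohort()].
#' @return A list of `extracted_session` objects (with `truth` attached when
#'   `keep_truth`).
#' @export
simulate_study <- function(n_subjects = 13, seed = 1, config = list(),
                           keep_truth = FALSE, ...) {
  cfg <- merge_config(config)
  plan <- study_cohort_plan(n_subjects, seed = seed,
                            pmax_range = cfg$synth$pmax_range)
  cohort <- sample_cohort(n_subjects, seed = seed + 1L, ...)
  sessions <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    subject <- cohort[[row$subject_idx]]
    up <- if (is.na(row$up_rate)) NULL else row$up_rate
    trace <- build_protocol(row$down_rate, up, row$pmax)
    rec <- synthesize_session(trace, subject, fs = cfg$synth$fs,
                              seed = seed * 100000L + i,
                              session_id = row$session_id)
    ex <- extract_features(rec, config)
    if (keep_truth) ex$truth <- rec$truth
    sessions[[i]] <- ex
  }
  sessions
}

#' Run the full pipeline and produce an evaluation report
#'
#' Executes simulate (unless `sessions` are supplied) -> extract -> dataset
#' assembly -> subject-wise cross-validated regression -> evaluation. All
#' stage counters are aggregated in the result.
#'
#' @param config Pipeline configuration overrides (see [default_config()]).
#' @param sessions Optional pre-extracted sessions (from [simulate_study()]
#'   or [extract_features()]); simulated per config when `NULL`.
#' @return A list of class `crm_pipeline_result`: `report` (an
#'   `eval_report`), `cv`, `dataset`, `counters`, `config`.
#' @export
run_pipeline <- function(config = list(), sessions = NULL) {
  cfg <- merge_config(config)
  if (is.null(sessions))
    sessions <- simulate_study(cfg$synth$n_subjects, seed = cfg$seed,
                               config = config)
  ds <- assemble_dataset(sessions,
                         feature_set = cfg$dataset$feature_set,
                         phase_selection = cfg$dataset$phase_selection,
                         normalization = cfg$dataset$normalization)
  mc <- model_config(cfg$model$model_kind, cfg$model$n_estimators,
                     cfg$model$max_depth, cfg$model$learning_rate,
                     seed = cfg$seed)
  cv <- subjectwise_cv(ds, k = cfg$cv$folds, config = mc, seed = cfg$seed,
                       auc_thresholds = cfg$evaluate$auc_thresholds)
  counters <- do.call(rbind, lapply(sessions, function(s)
    as.data.frame(s$counters)))
  counters$session_id <- vapply(sessions, function(s) s$meta$session_id, "")
  structure(list(report = eval_report(cv), cv = cv, dataset = ds,
                 counters = counters, config = cfg),
            class = "crm_pipeline_result")
}

#' Read an ABP recording from CSV
#'
#' Expects columns `time_s` and `abp_mmhg` with uniformly spaced timestamps.
#'
#' @param path CSV file path.
#' @param fs Expected sampling rate, Hz; checked against the timestamps when
#'   given (mismatch is an error), inferred otherwise.
#' @return An `abp_recording` (without a protocol trace or truth table).
#' @export
read_recording <- function(path, fs = NULL) {
  tab <- utils::read.csv(path)
  for (col in c("time_s", "abp_mmhg"))
    if (!col %in% names(tab))
      stop_invalid("recording %s is missing the '%s' column", path, col)
  dt <- diff(tab$time_s)
  if (length(dt) < 1L || any(dt <= 0))
    stop_invalid("timestamps in %s must be strictly increasing", path)
  fs_obs <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / fs_obs)) > 0.01 / fs_obs)
    stop_invalid("timestamps in %s are not uniformly spaced", path)
  if (!is.null(fs) && abs(fs_obs - fs) > 1e-6 * fs)
    stop_invalid("sample rate mismatch in %s: header/metadata says %g Hz, timestamps imply %.6g Hz",
                 path, fs, fs_obs)
  structure(list(abp = tab$abp_mmhg, fs = if (is.null(fs)) fs_obs else fs,
                 trace = NULL, truth = NULL,
                 meta = list(subject_id = NA_character_,
                             session_id = basename(path),
                             down_rate = NA_real_, up_rate = NA_real_,
                             pmax = NA_real_)),
            class = "abp_recording")
}

#' Write an ABP recording to CSV
#'
#' @param recording An `abp_recording`.
#' @param path Output CSV path (columns `time_s`, `abp_mmhg`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  n <- length(recording$abp)
  # %.17g keeps the doubles bit-exact across the round trip
  utils::write.csv(
    data.frame(time_s = sprintf("%.17g", (seq_len(n) - 1) / recording$fs),
               abp_mmhg = sprintf("%.17g", recording$abp)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
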