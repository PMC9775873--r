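# Shared fixtures. Expensive synthetic cohorts are built once per test run
# and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A clean subject for controlled single-session experiments.
quiet_subject <- function(id = "T01", ...) {
  args <- list(subject_id = id, waveform_noise_sd = 0, jitter_sd = 0,
               hrdn_noise_sd = 0, artifact_rate = 0, drift_amplitude = 0)
  args[names(list(...))] <- list(...)
  do.call(subject_physiology, args)
}

# Noiseless short ramp session with extracted signals and truth.
noiseless_session <- function() {
  cached("noiseless_session", function() {
    tr <- build_protocol(9, 9, 60, baseline_duration = 120,
                         recovery_duration = 120)
    subj <- subject_physiology("N01", waveform_noise_sd = 0, jitter_sd = 0.01,
                               hrdn_noise_sd = 0.01, artifact_rate = 0,
                               drift_amplitude = 0)
    rec <- synthesize_session(tr, subj, seed = 11)
    sig <- preprocess_signals(rec$abp, rec$fs)
    fid <- detect_landmarks(sig)
    list(rec = rec, sig = sig, fid = fid, truth = rec$truth)
  })
}

# Small cohort in which only HRDN carries CRM signal (heart-rate and
# pulse-pressure responses zeroed): used for the planted-importance and
# leakage experiments. Short sessions keep it light.
planted_cohort <- function() {
  cached("planted_cohort", function() {
    subjects <- sample_cohort(6, seed = 21, hr_gain = 0, pp_gain = 0)
    sessions <- list()
    k <- 0
    for (i in seq_along(subjects)) {
      for (j in 1:2) {
        k <- k + 1
        tr <- build_protocol(9, 9, 50, baseline_duration = 120,
                             recovery_duration = 120)
        rec <- synthesize_session(tr, subjects[[i]], seed = 1000 + k,
                                  session_id = sprintf("P%02d_%d", i, j))
        sessions[[k]] <- extract_features(rec)
      }
    }
    sessions
  })
}

# The headline synthetic cohort: 13 subjects x 4 sessions at generator
# defaults (the stand-in for the human study).
headline_cohort <- function() {
  cached("headline_cohort", function() simulate_study(13, seed = 1))
}
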