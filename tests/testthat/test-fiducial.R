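# Beat segmentation and landmark detection.

test_that("beats at a constant rate are segmented at the right spacing", {
  fs <- 500
  for (bpm in c(60, 40)) {
    tr <- constant_crm_protocol(15, crm = 100)
    subj <- quiet_subject(baseline_heart_rate = bpm)
    rec <- synthesize_session(tr, subj, seed = 2)
    sig <- preprocess_signals(rec$abp, fs)
    onsets <- segment_beats(sig)
    ibi <- diff(onsets) / fs
    expect_equal(length(onsets), nrow(rec$truth), tolerance = 0.02)
    expect_true(all(abs(ibi - 60 / bpm) <= 1 / fs + 1e-9))  # within one sample of 2 ms
  }
})

test_that("flat or empty signals yield no beats", {
  sig <- preprocess_signals(rep(80, 5000), 500)
  expect_identical(segment_beats(sig), integer(0))
  short <- preprocess_signals(rnorm(600) + 80, 500, order = 256)
  expect_identical(segment_beats(short), integer(0))
})

test_that("beat count is invariant under affine amplitude transforms", {
  s <- noiseless_session()
  n1 <- length(segment_beats(s$sig))
  scaled <- preprocess_signals(0.013 * s$rec$abp + 500, s$rec$fs)
  n2 <- length(segment_beats(scaled))
  expect_equal(n1, n2)
})

test_that("landmarks on noiseless sessions match generator truth within 10 ms", {
  s <- noiseless_session()
  fid <- s$fid
  tt <- s$truth
  # >= 99% of beats detected
  expect_gte(nrow(fid) / nrow(tt), 0.99)
  m <- vapply(fid$t_A, function(t) which.min(abs(tt$t_onset - t)), integer(1))
  ok <- fid$notch_found
  expect_gte(mean(fid$notch_found[-nrow(fid)]), 0.99)
  pairs <- list(c("t_A", "t_onset"), c("t_B", "t_half_rise"),
                c("t_C", "t_peak"), c("t_D", "t_notch"))
  for (p in pairs) {
    err <- abs(fid[[p[1]]] - tt[[p[2]]][m])[ok]
    expect_lt(max(err, na.rm = TRUE), 0.010)
  }
  # half-rise value sits at the mid-level between onset and peak
  half <- (fid$W_A + fid$W_C) / 2
  wb <- vapply(which(ok), function(i)
    crmwave:::sample_at_time(s$sig$denoised, fid$t_B[i], s$sig$fs), numeric(1))
  expect_lt(max(abs(wb - half[ok])), 0.05)
})

test_that("accepted notches always fall in the credible PPI fraction window", {
  s <- noiseless_session()
  fid <- s$fid[s$fid$notch_found, ]
  frac <- (fid$t_D - fid$t_A) / (fid$t_F - fid$t_C)
  expect_true(all(frac >= 0.15 & frac <= 0.40))
})

test_that("notch selection applies the credible-range and prominence rules", {
  # single candidate inside the window
  one <- data.frame(time = 0.30, prominence = 1)
  expect_equal(select_dicrotic_notch(one, t_A = 0, ppi = 1)$time, 0.30)
  # a more prominent candidate outside the window loses
  two <- data.frame(time = c(0.10, 0.30), prominence = c(5, 1))
  expect_equal(select_dicrotic_notch(two, t_A = 0, ppi = 1)$time, 0.30)
  # nothing in the window: no notch
  out <- data.frame(time = c(0.05, 0.60), prominence = c(2, 3))
  expect_null(select_dicrotic_notch(out, t_A = 0, ppi = 1))
  # tie on prominence: earliest wins
  tie <- data.frame(time = c(0.35, 0.20), prominence = c(2, 2))
  expect_equal(select_dicrotic_notch(tie, t_A = 0, ppi = 1)$time, 0.20)
})

test_that("monotone-decay pulses are marked malformed", {
  fs <- 500
  # a decaying sawtooth-free signal: no upstroke anywhere after the start
  x <- c(80 + 40 * exp(-seq(0, 6, length.out = 3000)), rep(80, 2000))
  sig <- preprocess_signals(x, fs)
  fid <- detect_landmarks(sig)
  # no beat is emitted as fully resolved
  expect_equal(sum(is.na(fid$exclusion_reason)), 0)
  expect_false(any(fid$notch_found))
})

test_that("beats with a suppressed reflected wave are excluded as notchless", {
  tr <- constant_crm_protocol(40, crm = 100)
  subj <- quiet_subject(artifact_rate = 20)   # frequent artifacts
  rec <- synthesize_session(tr, subj, seed = 9)
  sig <- preprocess_signals(rec$abp, rec$fs)
  fid <- detect_landmarks(sig)
  tt <- rec$truth
  m <- vapply(fid$t_A, function(t) which.min(abs(tt$t_onset - t)), integer(1))
  art <- tt$artifact[m] == "no_notch"
  expect_gt(sum(art), 0)
  expect_true(all(fid$exclusion_reason[art] == "no_notch_candidate",
                  na.rm = TRUE))
  expect_false(any(fid$notch_found[art]))
})

test_that("the final beat of a record is marked malformed (no successive peak)", {
  s <- noiseless_session()
  expect_equal(s$fid$exclusion_reason[nrow(s$fid)], "malformed_beat")
})
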