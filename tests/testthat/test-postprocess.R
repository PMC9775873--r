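# Outlier rejection, windowed averaging, stability exclusion and
# normalization.

brute_mad_keep <- function(x, window = 20, k = 3) {
  n <- length(x)
  before <- floor((window - 1) / 2)
  after <- ceiling((window - 1) / 2)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    win <- x[max(1, i - before):min(n, i + after)]
    win <- win[!is.na(win)]
    med <- median(win)
    smad <- 1.482602218505602 * median(abs(win - med))
    keep[i] <- abs(x[i] - med) <= k * smad
  }
  keep
}

test_that("scaled MAD uses the normal-consistency constant", {
  expect_equal(scaled_mad(1:5), 1.4826, tolerance = 1e-4)
  expect_equal(mad_scale_constant(), 1.4826, tolerance = 1e-4)
})

test_that("MAD rejection keeps constants and flags a planted outlier", {
  expect_true(all(reject_outliers_mad(rep(2.5, 40))))
  set.seed(6)
  x <- 1 + rnorm(40, sd = 0.01)
  x[23] <- 10
  keep <- reject_outliers_mad(x)
  expect_false(keep[23])
  expect_true(all(keep[-23]))
})

test_that("MAD rejection matches the brute-force oracle with NAs present", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rnorm(60)
    x[sample(60, 5)] <- NA
    x[sample(which(!is.na(x)), 2)] <- 8
    expect_identical(reject_outliers_mad(x), brute_mad_keep(x))
  }
})

test_that("moving average windows hop by 2 s and match brute force", {
  set.seed(8)
  nb <- 200
  bt <- cumsum(runif(nb, 0.5, 1.0))
  feats <- data.frame(beat_time = bt)
  for (f in crmwave:::FEATURE_NAMES) feats[[f]] <- rnorm(nb)
  out <- moving_average(feats, NULL, window = 20, overlap = 0.9,
                        min_beats = 5)
  expect_equal(unique(round(diff(out$window_time), 9)), 2)
  for (t_i in sample(seq_len(nrow(out)), 10)) {
    t <- out$window_time[t_i]
    inwin <- bt > t - 20 & bt <= t
    for (f in c("PPI", "HRDN", "SI")) {
      expected <- if (sum(inwin) >= 5) mean(feats[[f]][inwin]) else NA_real_
      expect_equal(out[[f]][t_i], expected)
    }
  }
  # constant stream gives constant means
  cf <- feats
  for (f in crmwave:::FEATURE_NAMES) cf[[f]] <- 3.3
  cout <- moving_average(cf, NULL)
  expect_true(all(abs(cout$PPI - 3.3) < 1e-12, na.rm = TRUE))
})

test_that("HRDN stability exclusion flags a step discontinuity", {
  ex <- hrdn_std_exclusion(rep(0.2, 50), span = 21, threshold = 0.02)
  expect_true(all(ex$valid))
  expect_true(all(ex$moving_std < 1e-12, na.rm = TRUE))
  stepped <- c(rep(0.2, 30), rep(0.35, 30))
  ex2 <- hrdn_std_exclusion(stepped, span = 21, threshold = 0.02)
  expect_false(all(ex2$valid))
  # windows straddling the step are the invalid ones
  expect_true(all(which(!ex2$valid) %in% 20:41))
  # brute-force centred std
  brute <- vapply(seq_along(stepped), function(i) {
    win <- stepped[max(1, i - 10):min(length(stepped), i + 10)]
    sd(win)
  }, numeric(1))
  expect_equal(ex2$moving_std, brute)
  expect_error(hrdn_std_exclusion(rep(0.2, 30), span = 20), "odd")
})

test_that("baseline normalization divides by the baseline-phase mean", {
  tab <- data.frame(window_time = seq(20, 400, by = 2))
  n <- nrow(tab)
  for (f in crmwave:::FEATURE_NAMES) tab[[f]] <- 2.0
  tab$valid <- TRUE
  out <- baseline_normalize(tab, baseline_end = 300)
  for (f in crmwave:::FEATURE_NAMES)
    expect_true(all(out[[f]] == 1.0))
  # doubled series normalizes to 2
  tab2 <- tab
  tab2$HRDN <- ifelse(tab2$window_time <= 300, 1.0, 2.0)
  out2 <- baseline_normalize(tab2, baseline_end = 300)
  expect_true(all(out2$HRDN[tab2$window_time > 300] == 2.0))
  # no valid baseline windows is an error naming the feature
  tab3 <- tab
  tab3$valid <- tab3$window_time > 300
  expect_error(baseline_normalize(tab3, baseline_end = 300), "PPI")
})

test_that("postprocess output is causal with the documented latency", {
  # a window mean at time t must not change when samples after t change
  s <- noiseless_session()
  bf <- compute_beat_features(s$fid, s$sig$denoised, s$sig$fs)
  full <- postprocess_features(bf)
  cut_t <- 200
  bf_cut <- bf[bf$beat_time <= cut_t, ]
  part <- postprocess_features(bf_cut)
  shared <- part$window_time <= cut_t - 25  # clear of MAD/std edge windows
  m <- match(part$window_time[shared], full$window_time)
  expect_equal(part$HRDN[shared], full$HRDN[m], tolerance = 1e-12)
  expect_equal(part$PPI[shared], full$PPI[m], tolerance = 1e-12)
})

test_that("re-running the averaging on its own output reproduces it", {
  s <- noiseless_session()
  bf <- compute_beat_features(s$fid, s$sig$denoised, s$sig$fs)
  fs1 <- postprocess_features(bf)
  # feed the windowed values back as beats with one value per window time
  again <- data.frame(beat_time = fs1$window_time)
  for (f in crmwave:::FEATURE_NAMES) again[[f]] <- fs1[[f]]
  fs2 <- moving_average(again, NULL, window = 2, overlap = 0, min_beats = 1)
  m <- match(fs1$window_time, fs2$window_time)
  ok <- !is.na(m) & !is.na(fs1$HRDN)
  expect_equal(fs2$HRDN[m[ok]], fs1$HRDN[ok], tolerance = 1e-12)
})
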