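# Synthetic protocol, reference CRM and waveform generator.

test_that("protocol ramps have the right durations and phase structure", {
  tr <- build_protocol(down_rate = 6, up_rate = 6, pmax = 60,
                       baseline_duration = 300)
  # 60 mmHg at 6 mmHg/min: 600 s down, 600 s up
  t_apex <- tr$time_s[which.max(tr$pressure_mmhg)]
  expect_equal(t_apex - min(tr$time_s[tr$phase == "depressurization"]), 600)
  expect_equal(max(tr$time_s[tr$phase == "repressurization"]) - t_apex, 600)
  expect_equal(max(tr$pressure_mmhg), 60)
  expect_setequal(unique(tr$phase),
                  c("baseline", "depressurization", "repressurization",
                    "recovery"))
  # pressure is zero in baseline and recovery
  expect_true(all(tr$pressure_mmhg[tr$phase %in% c("baseline", "recovery")] == 0))
  # piecewise-linear and continuous: no jump larger than rate * dt
  expect_lt(max(abs(diff(tr$pressure_mmhg))), 6 / 60 + 1e-9)
})

test_that("a session can run to the full -100 mmHg terminal pressure", {
  tr <- build_protocol(down_rate = 3, up_rate = NULL, pmax = 100)
  expect_equal(max(tr$pressure_mmhg), 100)
  expect_equal(tr$pressure_mmhg[nrow(tr)], 100)
  expect_setequal(unique(tr$phase), c("baseline", "depressurization"))
})

test_that("degenerate protocol parameters are rejected", {
  expect_error(build_protocol(6, 6, pmax = 0), "pmax")
  expect_error(build_protocol(6, 6, pmax = 101), "pmax")
  expect_error(build_protocol(0, 6, pmax = 60), "down_rate")
  expect_error(build_protocol(6, -3, pmax = 60), "up_rate")
})

test_that("reference CRM follows (1 - P/Pmax) * 100", {
  expect_equal(compute_reference_crm(0, pmax = 60), 100)
  expect_equal(compute_reference_crm(60, pmax = 60), 0)
  expect_equal(compute_reference_crm(45, pmax = 60), 25)
  expect_error(compute_reference_crm(61, pmax = 60), "exceeds pmax")
})

test_that("reference CRM of generated protocols is bounded and monotone per phase", {
  tr <- build_protocol(9, 3, 72)
  crm <- compute_reference_crm(tr)
  expect_true(all(crm >= 0 & crm <= 100))
  expect_true(all(crm[tr$phase %in% c("baseline", "recovery")] == 100))
  expect_true(all(diff(crm[tr$phase == "depressurization"]) <= 1e-9))
  expect_true(all(diff(crm[tr$phase == "repressurization"]) >= -1e-9))
})

test_that("morphology map is the identity at full reserve and monotone in deficit", {
  subj <- subject_physiology("X", baseline_heart_rate = 60,
                             baseline_hrdn = 0.20)
  m100 <- crm_to_morphology(100, subj)
  expect_equal(m100$period, 1.0)
  expect_equal(m100$hrdn, 0.20)
  m50 <- crm_to_morphology(50, subj)
  m0 <- crm_to_morphology(0, subj)
  expect_true(m0$period < m50$period && m50$period < m100$period)
  expect_true(m0$hrdn < m50$hrdn && m50$hrdn < m100$hrdn)
  expect_true(m0$pulse_pressure < m100$pulse_pressure)
  expect_error(crm_to_morphology(101, subj), "crm")
  expect_error(crm_to_morphology(-1, subj), "crm")
})

test_that("noiseless stationary synthesis produces identical beats at the set rate", {
  tr <- constant_crm_protocol(10.5, crm = 100)
  subj <- quiet_subject(baseline_heart_rate = 60)
  rec <- synthesize_session(tr, subj, seed = 3)
  tt <- rec$truth
  expect_equal(nrow(tt), 10)             # 60 bpm for 10 s of complete beats
  expect_true(all(abs(diff(tt$t_onset) - 1.0) < 1e-9))
  expect_equal(tt$hrdn[-nrow(tt)], rep(subj$baseline_hrdn, nrow(tt) - 1),
               tolerance = 1e-9)
  expect_true(all(abs(tt$sbp - subj$baseline_sbp) < 1e-9))
})

test_that("identical seeds reproduce a session bit for bit", {
  tr <- build_protocol(9, 9, 50, baseline_duration = 30,
                       recovery_duration = 30)
  subj <- subject_physiology("R01")
  a <- synthesize_session(tr, subj, seed = 5)
  b <- synthesize_session(tr, subj, seed = 5)
  expect_identical(a$abp, b$abp)
  expect_identical(a$truth, b$truth)
  c <- synthesize_session(tr, subj, seed = 6)
  expect_false(identical(a$abp, c$abp))
})

test_that("truth table is internally consistent with the template formulas", {
  s <- noiseless_session()
  tt <- s$truth
  ok <- tt$artifact == "none" & !is.na(tt$t_notch)
  # notch minus half-rise is the recorded HRDN
  expect_equal(tt$t_notch[ok] - tt$t_half_rise[ok], tt$hrdn[ok],
               tolerance = 1e-9)
  expect_equal(tt$pp, tt$sbp - tt$dbp, tolerance = 1e-9)
  valid_si <- !is.na(tt$si)
  expect_equal(tt$si[valid_si] * tt$ppi[valid_si] * tt$sbp[valid_si],
               rep(60, sum(valid_si)), tolerance = 1e-9)
  # per-beat waveform extremes match the morphology levels (no noise)
  rec <- s$rec
  i <- 5
  seg <- rec$abp[round(tt$t_onset[i] * rec$fs):round(tt$t_onset[i + 1] * rec$fs)]
  expect_equal(max(seg), tt$sbp[i], tolerance = 0.05)
  expect_equal(min(seg), tt$dbp[i], tolerance = 0.05)
})

test_that("study cohort plan matches the ramped-LBNP session design", {
  plan <- study_cohort_plan(13, seed = 4)
  expect_equal(nrow(plan), 52)
  for (i in 1:13) {
    p <- plan[plan$subject_idx == i, ]
    expect_equal(nrow(p), 4)
    expect_true(is.na(p$up_rate[1]))             # depressurization-only day
    expect_equal(p$up_rate[2], p$down_rate[2])   # first ramp-up at same rate
    expect_setequal(p$up_rate[2:4], c(3, 6, 9))  # the rest cover all rates
    expect_equal(length(unique(p$down_rate)), 1L)
    expect_true(unique(p$down_rate) %in% c(3, 6, 9))
  }
})
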