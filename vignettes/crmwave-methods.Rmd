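---
title: "Estimating compensatory reserve from ABP pulse morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating compensatory reserve from ABP pulse morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmwave)
```

## The problem

Hemorrhage is hard to monitor with conventional vital signs because the body
compensates: heart rate and blood pressure hold almost steady until a patient
is near decompensation. The *compensatory reserve metric* (CRM) frames volume
status as the fraction of compensatory capacity that remains — 100% at
normovolemia, 0% at hemodynamic decompensation. In a lower-body negative
pressure (LBNP) study, sub-atmospheric chamber pressure applied to the lower
body sequesters central blood volume and reproducibly simulates hemorrhage;
repressurizing the chamber simulates resuscitation. With chamber pressure
magnitude $P(t)$ and the maximum sustained pressure $P_{max}$, the reference
CRM is defined as

$$\mathrm{CRM}(t) = \left(1 - \frac{P(t)}{P_{max}}\right) \times 100\%$$

`crmwave` implements a pipeline that estimates this quantity from the
continuous arterial blood pressure (ABP) waveform alone, using nine
interpretable pulse-morphology features — most importantly the half-rise to
dicrotic notch time (HRDN), an approximate delay between the ejected and
reflected pressure waves. HRDN shortens as vasoconstriction stiffens the
arterial tree, which is precisely the compensatory response the CRM tracks.

## Pipeline overview

1. **Pre-processing** (`preprocess_signals`): a 512th-order zero-phase FIR
   lowpass at 12 Hz denoises the 500 Hz signal; first and second
   finite differences approximate the derivatives; each series is z-scored
   within a 2-s trailing window to remove drift and amplitude scaling.
   Landmark *timing* is detected on the standardized series; feature
   *amplitudes* are read from the denoised, unstandardized signal — the
   z-scored series has no mmHg units, so the amplitude features could not be
   computed from it.
2. **Fiducial detection** (`segment_beats`, `detect_landmarks`): pulse
   onsets are the local pressure minima anchoring strong upstrokes of the
   standardized slope; for each beat the systolic peak, the half-rise
   crossing of $(W_A + W_C)/2$, and the dicrotic notch are located. Notch
   candidates are local maxima of the standardized first derivative after
   the systolic peak; among candidates within 15–40% of the peak-to-peak
   interval (measured from the pulse onset) the maximally prominent one is
   selected, and beats with no qualifying candidate are excluded rather than
   guessed.
3. **Features** (`compute_beat_features`): PPI, HRV (trailing 10-beat RMSSD
   of PPI), HRDN, SBP, DBP, PP, PA, IPA, SI per beat.
4. **Post-processing** (`postprocess_features`): per-feature outliers beyond
   3 scaled MADs (constant 1.4826) of a centred 20-beat moving median are
   removed; features are averaged over 20-s trailing windows with 90%
   overlap (2-s hop); windows where the centred 21-window moving SD of the
   HRDN averages exceeds a threshold are excluded wholesale; features can
   optionally be normalized by their baseline-phase means.
5. **Regression** (`fit_model`, `subjectwise_cv`): a gradient-boosted tree
   ensemble (100 estimators, squared-error loss, no bootstrap subsampling)
   or OLS maps the feature vector to CRM, with estimates clipped to
   [0, 100]. Cross-validation folds split *by subject*, never by row, since
   windows from one subject are strongly correlated and row-wise splits
   would leak.
6. **Evaluation** (`eval_report`): RMSE and $R^2$ per fold, rank-statistic
   ROC AUC for classifying reference CRM at the 70%, 40% and 5% thresholds,
   Bland–Altman bias and ±1.96 SD limits of agreement (plotted against the
   reference, which is a gold standard), per-ramp-speed session RMSE
   distributions, and normalized split-gain (Gini) feature importances.

## The synthetic-data generator

No public human LBNP/ABP corpus accompanies this problem, so the package
ships a generator that is itself first-class, tested code. It emulates:

- the ramped protocol: 5-min baseline, a linear depressurization at 3, 6 or
  9 mmHg/min to the subject's tolerance pressure, an optional
  repressurization at 3, 6 or 9 mmHg/min, and a 10-min recovery
  (`build_protocol`, `study_cohort_plan`). The cohort schedule mirrors the
  study design: one depressurization-only session plus three down/up
  sessions per subject, the first repressurization at the assigned rate and
  the other two covering the remaining rates.
- Finapres-like pulse morphology: each beat is a template with a systolic
  upstroke, a dicrotic notch produced by a delayed reflected wave, and a
  diastolic decay. As CRM falls, heart rate rises (default +50% at full
  deficit), pulse pressure falls (−30%), and the true HRDN shortens (−45%)
  — monotone maps with the subject baseline at CRM = 100
  (`crm_to_morphology`).
- measurement imperfections: white waveform noise (SD 1 mmHg), slow
  sinusoidal baseline drift, beat-level period jitter and HRDN noise
  (SD 10 ms each), and artifact beats at 1/min that either lose their notch
  entirely or spike in amplitude — exercising the notch-exclusion and
  MAD-rejection paths.

Every synthesized beat is recorded in a truth table (landmark times, all
nine feature values on the clean template, reference CRM), so each pipeline
stage can be validated end to end.

### Template geometry and the 12 Hz filter

A subtlety worth documenting: landmark locations must survive zero-phase
lowpass filtering. A symmetric FIR kernel preserves the location of extrema
that are locally symmetric, while flat or one-sidedly sharp corners drift
(toward the flat side) or ring. The template therefore joins segments with
matched slopes and curvatures at the landmarks: the pulse onset is a V whose
diastolic side ends in a short linear run-in (slope overmatching the
upstroke foot by a fixed factor, compensating the upstroke's acceleration
away from the junction); the systolic peak is a shallow Λ with equal slopes;
and the notch-to-dicrotic-peak interval is half the peak-to-notch fall span,
balancing curvature across the notch. With this geometry the detector
recovers all landmark times within ±10 ms of truth on noiseless sessions.

### Inter-subject variability

Baselines are drawn per subject: heart rate U(60, 72) bpm, DBP
U(65, 80) mmHg, pulse pressure U(40, 55) mmHg, HRDN ~ N(0.20 s, 8 ms)
truncated to [0.18, 0.22], HRDN gain ~ N(0.45, 0.04). The narrow HRDN spread
encodes the empirical premise of the approach: absolute HRDN carries
information about CRM *across* subjects, without per-subject baseline
normalization. Widening that spread degrades cross-subject accuracy roughly
linearly; it is the dominant error source in the synthetic experiment, ahead
of beat-level noise (which the 20-s windows average down to ~2 ms).

What the generator does **not** emulate: baroreflex dynamics and oscillatory
feedback, respiratory modulation, true Finapres noise spectra and motion
artifacts, nonlinear or hysteretic CRM–morphology coupling, and
subject-level deviations from the monotone response maps. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and
internal consistency, not clinical performance on human data.

## Numerical and design choices

- **Zero-phase filtering** is realized as a single centred pass of the
  symmetric (linear-phase) kernel with reflect padding of one filter order
  at each end — exactly zero phase with the designed magnitude response,
  and the kernel is normalized to unit DC gain.
- **Finite differences** are plain per-sample differences (forward first
  difference; central second difference; replicated edges). Landmark logic
  uses only sign patterns and peak locations, which are invariant to the
  1/fs scaling, so derivatives are kept in per-sample units.
- **Degenerate z-score windows** (SD < 1e-9, e.g. flatlines) produce 0
  rather than dividing by zero; flatlines carry no landmarks.
- **Windows are half-open** `(start, end]`: the right edge owns the sample,
  which gives unambiguous trailing-window semantics.
- **Notch anchoring**: the credible 15–40% window is measured from the
  pulse onset A, with PPI the current beat's peak-to-peak interval; the
  refined notch is the local pressure minimum immediately preceding the
  selected derivative peak, and a refined notch that falls below the 15%
  bound invalidates the beat. Equal prominences tie-break to the earliest
  candidate.
- **Candidate prominence floor** (0.25 standardized units) suppresses
  noise-born derivative wiggles from being selected in beats that truly
  lack a notch.
- **MAD rejection** drops the offending feature only, keeping the beat's
  other features; exclusion couples across features only at the HRDN-SD
  stage. The HRDN-SD threshold is not a published constant; the default
  0.02 s is this package's choice and is exposed in the configuration.
- **Windows with fewer than 5 retained beats** yield no mean (NA) rather
  than a noisy one.
- **GB hyperparameters** beyond the fixed estimator count, loss and
  no-subsampling rule: depth 3 and learning rate 0.1, common boosting
  defaults, exposed via `model_config()`. The boosting engine is xgboost
  with `lambda = 0` (no L2 shrinkage of leaf weights), single-threaded for
  determinism.
- **Fold assignment**: subjects sorted by id, shuffled by the seed, dealt
  round-robin — deterministic and balanced (13 subjects → folds of
  3/3/3/2/2).
- **AUC** is the Mann–Whitney rank statistic with ties counted 1/2;
  positives are windows with reference CRM at or above the threshold and
  the model estimate is the score.
- **Per-speed summaries** compute each session's RMSE first (separately for
  its depressurization and repressurization windows, attributed to signed
  rates), then summarize the session-level distribution per rate.
- **Reference-CRM `Pmax`** is the per-session maximum of the pressure
  trace. The alternative — carrying a subject's day-1 decompensation
  pressure into day-2 sessions — is not identifiable from the protocol
  description; per-session is the unambiguous choice and keeps CRM = 0
  attainable in every session.
- A **linear regression on HRDN** is available (`model_config("ols")`) but
  is not a headline path; boosted trees handle the mild nonlinearity of the
  HRDN–CRM map far better.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script simulate a 13-subject,
52-session cohort at 500 Hz with subject tolerance pressures drawn from
55–85 mmHg (roughly 33 hours of waveform, ~60,000 feature windows), which
this package treats as its reference experiment; controlled property tests
use shorter sessions (2-min baselines and recoveries, fast ramps) so each
focused check stays light. On the reference cohort the HRDN-only boosted
model achieves a subject-wise cross-validated RMSE of about 7.5 CRM points,
$R^2 \approx 0.94$ and AUC ≈ 0.99 at the 5% threshold — the values the
acceptance script recomputes from scratch at run time.

## Known limitations

- IPA is sensitive to the detected notch time (the integral boundary sits
  on a non-zero integrand), so a ±10 ms notch error moves IPA by several
  percent; tests bound it at 10% relative rather than the ±1% that holds
  for PA.
- DBP is read at the end-of-pulse landmark per the feature definition table
  (not the conventional pre-upstroke minimum); on filtered signals the
  V-shaped foot raises the read value by up to ~1 mmHg.
- The first ~2 s of every recording have incomplete z-score windows and the
  first/last beats of a record lack a predecessor/successor; edge beats are
  dropped or marked malformed rather than extrapolated.
- The HRDN-SD exclusion rarely fires on synthetic cohorts at its default
  threshold (the generator has no subject-specific artifact bursts of the
  kind the rule was designed for); the step-discontinuity test exercises
  the mechanism directly.
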