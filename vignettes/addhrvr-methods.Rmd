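---
title: "Methods: movement-adjusted HRV triggering and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-adjusted HRV triggering and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addhrvr)
```

This vignette documents the models implemented in `addhrvr`, the parameters
that matter, the design choices made where the design was genuinely open,
and what the synthetic-data generator does and does not emulate.

## 1. From beats to minutes

The raw signal is a beat train: R-peak timestamps (seconds since local
midnight) with the interbeat interval (IBI, ms) attached to each beat.
Minutes are half-open calendar intervals `[t, t + 60)` and a beat belongs to
the minute containing its timestamp.  Per minute we compute

* **RMSSD** (ms): `sqrt(mean(diff(ibi)^2))` — the vagally sensitive
  time-domain statistic the whole system is built on;
* **SDNN** (ms): sample standard deviation (n−1 denominator);
* **LF / HF band power** (ms²): power of the IBI tachogram over
  0.04–0.15 Hz and 0.15–0.40 Hz.

At least three intervals are required for a variability estimate; minutes
below that, or failing artifact screening, are *missing*, never zero.

**Artifact screening.**  Ambulatory devices apply proprietary validity
checks; we substitute explicit, configurable rules with the same effect
(minute → missing): a successive-interval change larger than 30 % of the
preceding interval, any interval outside 300–2000 ms, or fewer than 30
beats in the minute (`artifact_rules()`).  The defaults are conventional
ambulatory-ECG screening values; they are deliberately documented rather
than inferred, since the firmware rules are not public.

**Spectral estimator.**  No particular estimator is canonical for 1-minute
windows, so we use the field-standard chain: cubic-spline interpolation of
the tachogram onto an even 4 Hz grid, linear detrend, Hann-tapered Welch
periodogram, trapezoidal band integration with interpolated band edges (so
adjacent bands share a boundary without double counting).  A window must
span at least two cycles of the band's lower edge (50 s for LF), otherwise
the band power is missing.

## 2. Person-specific calibration

Over one 12-hour calibration day, per-minute RMSSD is regressed on movement
(MET) by ordinary least squares:

    RMSSD_m = intercept + slope * MET_m + e_m.

The model stores `intercept` (ms), `slope` (ms/MET) and a dispersion `sd`
(ms).  A later minute shows an **additional (nonmetabolic) HRV reduction**
when

    observed <= predicted - k * sd,      k = 0.5 by default,

with the boundary counting as flagged ("at least 0.5 SD lower").  Missing
minutes never flag.

Open choices, and how we resolved them:

* **Which SD?**  The dispersion could be the marginal SD of calibration-day
  RMSSD or the regression's residual SD.  The marginal SD is the default
  (matching the "SD of RMSSD" phrasing used when such calibrations are
  reported); the residual alternative is available via
  `fit_calibration(..., sd_type = "residual")`.  The two differ by the share
  of RMSSD variance that movement explains, so `k` is not transferable
  between conventions.
* **Eligibility.**  A non-negative slope contradicts the physiology the flag
  rule assumes (more movement, less vagal HRV), so such persons are flagged
  ineligible and excluded from triggering rather than silently fitted.
* **Minimum data.**  At least 120 usable minutes (of 720) are required;
  below that the person is reported uncalibratable.

## 3. The trigger engine

Flags stream through the **"13 out of 28" rule**: scanning minutes in time
order, a trigger is emitted at the first minute whose trailing 28-minute
window contains at least 13 flagged minutes, provided no trigger fired
within the preceding 60-minute **silence** period.  Numerical conventions:

* the trailing window *includes* the current minute — a real-time detector
  cannot see future minutes — and is clipped at the day start;
* the emission timestamp is the *end* of the qualifying minute, the
  earliest moment the rule can be known to hold;
* missing minutes count as not flagged, so a trigger always reflects 13
  *observed* reductions (conservative);
* silence applies to AddHRVr triggers only; random prompts are scheduled
  independently with their own minimum gap (drawn uniformly conditional on
  the gap via the standard window-shrinkage construction).

The default random-prompt rate is 15/day, chosen so that total prompts per
person over three monitoring days land near the ~45 observed in comparable
deployments.

**Virtual triggers.**  An offline pass finds minutes that satisfied the
rule but never prompted (typically suppressed by silence).  Three
exclusions keep these usable as no-intervention controls: a virtual event
must lie at least one full trailing window after the previous real trigger
(otherwise the *same* flagged-minute mass would be recounted as a new
event), at least the silence period after the previous virtual event, and
outside a ±10-minute buffer around any real prompt so its windows are
intervention-free.  The buffer width is our choice — deployed systems do
not document one — and is configurable.

## 4. Outcome windows and proximal-effect models

Each prompt contributes three windows on the ln scale (ln is applied per
minute *before* averaging — the convention when "ln RMSSD" is averaged —
and the alternative is deliberately not offered):

* **pre** (−1): minute starts in `[t − 600 s, t)`;
* **during** (0): minute starts within ±120 s of the intervention midpoint
  (the "±2 minutes" reading of a 2-minute tolerance around a 1-minute
  intervention; configurable);
* **post** (+1): minute starts in `(end, end + 600 s]`.

Only valid minutes enter HRV aggregates; the MET covariate averages over
all span minutes; a window truncated by the day edge is kept only if at
least 5 minutes remain, and a window with zero valid minutes is missing.

The proximal-effect model is a linear mixed model with a random person
intercept:

    ln_rmssd ~ met_c + smoking + trigger * time + (1 | person)

with `trigger` (AddHRVr vs random) centered within person so its
interactions carry within-person effects, MET grand-mean centered, and time
categorical with pre as reference (two contrasts: pre→during, pre→post).
Two-intervention designs use `trigger * intervention * time` with the
intervention indicator also centered within person;
`rescale_reference()` refits with dummy coding at a chosen reference level
to probe a three-way interaction through simple effects.  Estimation is
delegated to `lme4`; p-values and CIs use the large-sample normal
approximation for fixed effects (Wald), matching how such models are
conventionally reported.  Constant covariates (e.g. no smokers in a small
cohort) are dropped before fitting.

`compare_virtual()` crosses a three-level trigger factor (virtual as
reference, random, AddHRVr) with time (pre vs post); the
AddHRVr-vs-virtual × time term is the intervention effect *net of
spontaneous rebound*, since virtual triggers mark equally deep HRV
reductions that received no intervention.

## 5. What the generator emulates

`simulate_study()` draws a cohort and, per person: one calibration day,
then monitoring days generated minute by minute *in real time* — the flag,
the rolling window count, and silence are evaluated sequentially, so
intervention boosts of an emitted trigger can only affect later minutes.

Per minute:

    RMSSD_m = max(1, intercept + slope * MET_m + e_m - depth * sd_cal * [episode])
              * exp(boost_m + smoking_effect * [smoking bout])

* **Movement**: a per-minute Markov chain over activity bouts (sedentary
  1.3, walking 3.0, exercise 6.0 MET; mean dwell ~20/8/10 min), ±10 %
  jitter, floor 0.9 MET.  Stationary mean ≈ 2 MET, day-level SD ≈ 1.2.
* **Vulnerability episodes**: a Poisson number per day (rate 1.5) of
  non-overlapping episodes with shifted-exponential lengths
  (45 min minimum + exponential tail, mean 55 min), suppressing RMSSD by
  `depth = 2` calibration-SDs while active.  Depth is parameterized in SD
  units so detector sensitivity transfers across persons.
* **Interventions**: AddHRVr-triggered prompts add `during_boost = 0.08`
  ln-units to the intervention minute and its successor and
  `post_boost = 0.12` ln-units to the following 10 minutes.  Boosts are
  conditional on the trigger kind — the AddHRVr trigger *is* the low-state
  detector — so the fitted trigger×time(post) coefficient targets the
  configured boost directly.  Random-prompt interventions add nothing.
* **Self-reports**: latent pre-prompt stress = baseline + episode lift +
  noise, mapped to four 1–5 items (the first three stored reverse-coded, as
  collected); post = pre + time effect (−0.12 stress, −0.11 rumination).
  Items are continuous on the 1–5 scale by default so configured shifts are
  recovered exactly under zero noise; `discretize = TRUE` gives integer
  Likert responses.  Dispositions default to answered/ignored/dismissed/
  incomplete = 0.69/0.19/0.04/0.08.
* **Beat level** (`fidelity = "ibi"`): each minute's beat train has mean
  interval following `HR = 65 + 11 (MET − 1)` bpm and deviations (a
  respiratory-sinus-arrhythmia sinusoid plus Gaussian increments) rescaled
  so the realized minute RMSSD matches its target *exactly* (RMSSD is
  linear in the deviations) — chosen so detector tests are sharp rather
  than approximate.

`simulate_windows()` bypasses the physiological chain and draws window
outcomes directly from the mixed model the evaluation fits (person
intercept variance `tau00 = 0.13`, residual `sigma2 = 0.23`, MET effect
−0.35 ln/MET, smoking −0.03, trigger main effect −0.35, time effects).  It
is the reference generator for estimator calibration — type-I error,
variance-component and interaction recovery against exactly known values —
because the full chain's movement coupling lives on the raw ms scale (the
calibration regression is linear in ms by construction) and therefore has
no single "true" ln-scale MET coefficient.

### Why the episode geometry looks the way it does

Two artifacts can bias the trigger×time(post) estimator away from the
generated boost even though the estimator itself is sound:

1. **Regression to the mean**: the trigger selects windows whose *noise*
   is low, so pre-windows are noise-depressed and post-windows revert
   upward.  Deep episodes (2 SD) make flags track the latent state rather
   than the noise, shrinking this selection effect; per-minute noise is
   4 ms against a ~6 ms marginal SD.
2. **Spontaneous rebound**: an episode ending inside the 10-minute post
   window lifts RMSSD regardless of any intervention.  The 45-minute
   minimum episode length reflects the system's detection horizon — the
   28-minute flag window plus the 10-minute evaluation windows — so a
   detectable episode outlasts the post window; the short exponential tail
   (mean 10 min beyond the minimum) keeps episodes from outliving the
   60-minute silence and re-triggering at their end.

Under these defaults the measured bias of the trigger×time(post) estimator
is ~0.001 ln-units (Monte-Carlo SE 0.005).  In *real* deployments both
artifacts are present — which is exactly why `compare_virtual()` exists.

### What the generator does not emulate

No ECG morphology, ectopic-beat physiology, circadian or hormonal HRV
rhythms, true respiratory waveforms (only a band-limited RSA sinusoid for
spectral tests), no missing-data patterns beyond the artifact rules, no
feedback from self-reports to physiology, and no day-to-day drift in the
calibration parameters.  Passing tests therefore demonstrate that the
*algorithms* behave as specified under the assumed data-generating model,
not that the model captures real ambulatory physiology.

## 6. MRT sample size

For a constant standardized proximal effect `d`, randomization probability
`p`, expected availability `τ`, and `T = days × occasions` decision points,
the Wald test of the proximal effect has noncentrality
`λ = N T τ p (1 − p) d²`; with the small-sample correction the statistic is
referred to an `F(1, N − 2)` distribution, and `mrt_sample_size()` returns
the smallest integer `N` whose power reaches the target.

The number of decision points per day is a required design input that
published study descriptions often omit.  The package default is
**10 occasions/day**: scanning plausible values 3–25, this is the unique
count under which the method maps the reference design (4 days, p = 0.40,
τ = 0.75, power 0.80, α = .05) to the reference sizes N = 30 at d = 0.2 and
N = 51 at d = 0.15 — recorded as a calibration note in every
`run_pipeline()` summary.

## 7. Problem sizes and numerical tolerances in the test-suite

The suite checks engine/oracle equivalence on 1000 random 720-minute days
(exact equality), calibration recovery over 100 simulated persons (exact
without noise; mean absolute slope error < 0.3 ms/MET at 8 ms minute
noise), end-to-end effect recovery over 20 replicates of 50 persons ×
3 days (95 % CI coverage of the generated 0.12 boost), and type-I error of
the interaction test over 200 window-level replicates of 30 persons ×
25 prompts (rejection count within the exact binomial 99 % band around 5 %).
These sizes were chosen so each property is sharply testable while the
whole suite stays comfortably runnable on a laptop.

## 8. Known limitations

* The calibration is static; deployed systems may want dynamic
  recalibration as fitness or medication changes (out of scope here).
* The during-window estimate is attenuated by construction: the measured
  during window (midpoint ±2 min) includes one pre-prompt minute, while a
  causal intervention effect can only start at the prompt.  Under the
  generator defaults the expected during coefficient is
  `(2 * during_boost + post_boost) / 4`, and tests compare against that
  derived value rather than the raw `during_boost`.
* Percent summaries (`summarize_prompts()`) round half-up to two decimals;
  published compliance tables are not always internally consistent at that
  precision, so comparisons should allow one unit in the last digit.
* Wald inference for mixed models is anticonservative in very small
  cohorts; the type-I calibration holds at the tested sizes (≥ 20 persons).
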