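# addhrvr

Movement-adjusted heart-rate-variability triggers for just-in-time adaptive
interventions (JITAIs), with microrandomized-trial (MRT) evaluation tools and
a synthetic ambulatory-data generator that makes the whole chain testable end
to end.

## The problem

Transient reductions in vagally mediated heart rate variability (HRV) that
are *not* explained by bodily movement — additional HRV reductions
("AddHRVr") — are a candidate physiological marker of momentary
psychophysiological vulnerability.  A wearable that detects them in real
time can push a one-minute intervention (slow-paced breathing, mindful
breathing, external attention focus) exactly when autonomic regulation is
compromised.  This package implements that detection-and-evaluation chain
for researchers designing or analyzing such studies:

1. **HRV features** — interbeat-interval (IBI) streams are cut into calendar
   minutes; each minute yields RMSSD (root mean square of successive
   differences), SDNN, and LF/HF spectral band power, with configurable
   artifact screening.
2. **Calibration** — for each person, one 12-hour day of per-minute RMSSD is
   regressed on movement (metabolic equivalents, MET) by ordinary least
   squares:  `RMSSD = intercept + slope * MET + error`.  A later minute is
   *flagged* when its observed RMSSD is at least `k = 0.5` SD below the
   movement-predicted value (persons with non-negative slopes are excluded).
3. **Trigger engine** — the "13 out of 28" rule: a prompt fires at the first
   minute whose trailing 28-minute window contains at least 13 flagged
   minutes, with a 60-minute silence mode between triggers.  Random prompts
   are scheduled alongside, and an offline scan recovers *virtual* triggers
   (qualifying windows that never fired) as no-intervention controls.
4. **Evaluation** — per prompt, ln-scale HRV outcomes are aggregated over
   the 10 minutes before (time code −1), the ±2 minutes around the
   intervention (0), and the 10 minutes after (+1).  Multilevel models with
   a random person intercept and within-person-centered trigger (and
   intervention) indicators estimate the proximal effect as the
   trigger-by-time interaction; `compare_virtual()` separates the
   intervention effect from spontaneous HRV rebound.
5. **Design** — MRT sample size for a constant standardized proximal effect
   (Wald test with small-sample F correction), prompt-compliance summaries,
   and a paced-breathing helper (4 s in / 6 s out → 0.1 Hz resonance
   breathing).
6. **Synthetic data** — person-days with movement-coupled RMSSD, episodic
   nonmetabolic suppression, intervention-contingent boosts, and pre→post
   declines in stress/rumination ratings, at beat level (`fidelity = "ibi"`)
   or minute level (fast default).

## Worked example

Simulate a 10-person, 3-day cohort (after its calibration day), build the
outcome windows, and estimate the proximal effect of AddHRVr-triggered
versus random prompts:

```r
library(addhrvr)
sim     <- simulate_study(n_persons = 10, n_days = 3, seed = 7)
windows <- build_windows(sim$minutes, sim$prompts)
fit_proximal_model(windows)
#> <proximal_model> ln_rmssd ~ met_c + smoking + trigger * time + (1 | person_id)
#>   1637 observations, 10 persons
#>                term estimate    se       z        p
#>         (Intercept)    3.831 0.061  62.800  0.0e+00
#>               met_c   -0.070 0.002 -28.990 8.9e-185
#>         smokingTRUE    0.063 0.038   1.671  9.5e-02
#>             trigger   -0.095 0.012  -7.636  2.2e-14
#>          timeduring    0.016 0.007   2.315  2.1e-02
#>            timepost    0.030 0.007   4.492  7.0e-06
#>  trigger:timeduring    0.059 0.018   3.364  7.7e-04
#>    trigger:timepost    0.119 0.018   6.738  1.6e-11
#>   sigma2 = 0.012, tau00 = 0.037, ICC = 0.750
#>   key term trigger:timepost: b = 0.119, p = 1.6e-11
```

Reading the output: `trigger` is the AddHRVr-vs-random indicator centered
within person, so `trigger:timepost = 0.119` says that from the 10 minutes
before a prompt to the 10 minutes after it, ln RMSSD rises about 0.12
ln-units *more* after AddHRVr-triggered interventions than after random
ones — here recovering the generator's configured post-intervention boost of
0.12.  `trigger = -0.095` is the expected main effect: AddHRVr prompts fire
when HRV is suppressed.  `met_c` is the movement covariate; `sigma2`/`tau00`
are the within/between-person variance components.

Prompt compliance and a design-stage sample size:

```r
summarize_prompts(sim$prompts)
#>   disposition count   pct
#> 1    answered   377 68.30
#> 2   dismissed    23  4.17
#> 3     ignored   103 18.66
#> 4  incomplete    49  8.88

mrt_sample_size(mrt_design(days = 4, p_rand = 0.40, availability = 0.75,
                           effect = 0.2, power = 0.80))
#> [1] 30
```

`run_pipeline()` chains simulate → calibrate → detect → evaluate → design
and writes CSV artifacts plus a JSON run summary; see
`vignettes/addhrvr-methods.Rmd` for the modelling details and design
choices.

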