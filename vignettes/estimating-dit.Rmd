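---
title: "Estimating diet-induced thermogenesis from chamber calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diet-induced thermogenesis from chamber calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ditchamber)
```

## The measurement problem

Diet-induced thermogenesis (DIT) is the rise in energy expenditure (EE)
above the fasting state caused by digesting, absorbing and storing food —
typically around 10% of energy intake for a mixed diet. In a whole-room
indirect calorimeter, minute-level EE is the sum of three components that
cannot be separated by the gas analysis alone:

$$\mathrm{EE}(t) = \mathrm{BMR} + \mathrm{PAEE}(t) + \mathrm{DIT}(t) + \varepsilon(t),$$

where BMR is the basal metabolic rate and PAEE the physical-activity-related
expenditure. DIT is a small residual (tens of kcal over hours, against a
background of 1300–2000 kcal/day), so the estimator design and the activity
index used to model PAEE dominate the error budget. `ditchamber` implements
two estimators, each driven by either a triaxial-accelerometer vector
magnitude or an infrared percent-movement index:

* **Fasting-calibration (time-course) method** (`M1a` accelerometer, `M1b`
  infrared). While the subject is fasted, EE contains no DIT, so a short
  protocol of low-intensity activities (seated rest, desk work, a jigsaw,
  folding laundry; 20 min each) identifies the subject's own affine map
  from activity intensity to EE. The fitted line predicts the non-DIT
  expenditure $\mathrm{EE}_e(t) = \hat\beta_0 + \hat\beta_1\,\mathrm{PA}(t)$
  at every postprandial minute, and
  $\mathrm{DIT}(t) = \mathrm{EE}(t) - \mathrm{EE}_e(t)$. Summing over the
  evaluation windows gives the total; uniquely, this method also yields the
  minute-resolution time course.
* **Postprandial intercept (Schutz-type) method** (`M2a`, `M2b`). EE and
  activity are averaged over consecutive 30-min bins of postprandial waking
  time; the zero-activity intercept of the bin-level regression estimates
  the resting metabolic rate RMR = BMR + DIT rate, and
  $\mathrm{DIT} = (\widehat{\mathrm{RMR}} - \mathrm{BMR}/1440) \times
  \text{evaluation minutes}$. It needs an external BMR and yields no time
  course; its intercept is known to be sensitive to when intense activity
  happens relative to meals, which `ditchamber`'s tests reproduce on
  simulated data.

## The signal chain

Raw 32 Hz triaxial acceleration is high-pass filtered per axis to remove
the gravitational component, collapsed to a per-sample Euclidean norm
("synthetic acceleration", in mG), and averaged over 60-s epochs to the
minute grid. Only the cutoff frequency (0.7 Hz) is physiologically
prescribed; the realization is a design choice:

* **4th-order Butterworth, applied forward–backward** (`signal::filtfilt`).
  Zero-phase filtering keeps the filtered signal aligned with the bout
  schedule; a causal filter would smear activity onsets by its group delay.
  The order trades passband flatness against transient length; 4th order is
  the accelerometry default. Tests verify the realized frequency response
  against the transfer function evaluated analytically.
* The infrared index is the percentage of seconds per minute in which at
  least one passive-infrared sensor detected movement; sensors are OR-ed
  per second before counting, and a minute with missing seconds is an
  error — DIT is a small residual, so silent imputation is never allowed.
* Steady-state bout means use the window \[start + 2 min, end − 1 min),
  excluding the metabolic on-transient and the final transition minute.
  The boundary is half-open by the package-wide convention (a minute value
  covers \[m, m + 1)), so a 20-min bout contributes 17 minute samples.

Energy expenditure comes from gas exchange by the abbreviated Weir
equation, $3.941\,\dot VO_2 + 1.106\,\dot VCO_2$ kcal (rates in L/min),
with no urinary-nitrogen term since chamber protocols rarely collect urine;
the coefficients are arguments for other conventions. The sleeping
metabolic rate is the minimum mean EE over any 180 consecutive minutes of
sleep (1-min slide), scaled to kcal/day. BMR is deliberately an *input*:
either measured, or predicted from SMR with user-supplied coefficients
(`predict_bmr()`); the package ships no prediction coefficients because
such equations are population-specific, and inventing one would silently
bias every intercept-method result.

## Estimator conventions

* **Negative DIT is retained**, minute-wise and in totals, for both
  methods. Truncation at zero would bias the estimate upward and hide the
  intercept method's characteristic failure mode (fitted intercept below
  the basal rate).
* **Bins are anchored at each evaluation window's start**, not at clock
  half-hours, and a partial bin at a window's end is dropped rather than
  prorated — a bin mean over fewer minutes would have inflated variance.
* **Rate/period conversion**: the intercept and BMR are compared as
  kcal/min and the difference is scaled by the total evaluation-window
  minutes; this is the only dimensionally consistent choice.
* The fasting calibration is fit to **bout-level means** (typically 4
  points), matching the steady-state design; minute-level fitting would
  weight long bouts more and mix in transients.
* `estimate_ee()` returns the raw affine prediction without flooring;
  the intercept is fit at the data's origin, so negative predictions do
  not arise in practice, and clipping would bias the residual.

## The simulator

`simulate_session()` generates seeded chamber sessions under the additive
model with a known decomposition, so every estimator can be checked against
ground truth:

* **Protocol defaults** mirror a reproducibility-style stay: entry at
  t = 0 (18:50), dinner at minute 10, 7 h sleep, four 20-min calibration
  bouts at 2/6/10/20 mG in the fasted morning, breakfast and lunch, three
  5-h postprandial windows (900 min). A validity-style variant
  (`sim_config_validity()`) has one evening meal and a single 6-h fasted
  evaluation block in which true DIT is zero. Intake defaults to 2008 kcal
  across three meals, basal rate to 0.9 kcal/min (1296 kcal/day), activity
  cost to 0.02 kcal/min per mG, EE noise to 0.03 kcal/min.
* **Thermogenic response**: a single-peak gamma-type curve
  $d(t) = A\,(t/\tau)\,e^{1-t/\tau}$ per meal, $A$ normalized so the curve
  integrates to `dit_fraction` × intake (default 0.10). $\tau$ (default
  60 min) is the time-to-peak, in the usual postprandial range. Each 5-h
  window captures $1 - 6e^{-5} \approx 96\%$ of its meal's response; the
  remainder is tail mass, partly caught by later windows.
* **Activity** is episodic — geometric episode lengths (mean 10 min) with
  an episode-level exponential intensity (mean 8 mG awake, mostly < 30 mG,
  near zero asleep). Spontaneous chamber activity is autocorrelated in
  reality, and episode structure also gives the 30-min bin regression real
  between-bin variance; i.i.d. per-minute activity would make the
  bin-level regressor almost constant and induce an errors-in-variables
  bias in the intercept estimate.
* **Infrared model**: per-second Bernoulli detection with probability
  min(1, accel/`ir_sat`), `ir_sat` = 60 mG, so percent-movement stays
  roughly proportional to intensity over the free-living range and
  saturates only during sustained vigorous movement.
* **Noise** is additive Gaussian on minute EE, floored at zero, with no
  autocorrelation — the simplest model that exercises estimator variance.

What the simulator does **not** emulate: circadian drift of BMR, substrate
dynamics, water-induced thermogenesis, posture effects on the accelerometer,
sensor dropout, or non-steady-state activity within bouts. Passing the
recovery tests therefore shows the estimators are correct under the additive
model, not that real-chamber error will be as small; on real data both
methods additionally face calibration drift and the fasting residual that
motivates the validity design.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 20 simulated subjects for
recovery and fasted-centring checks, 15 paired subjects for the test-retest
harness, and 1000 replicates for the Bland–Altman coverage property — sizes
at which the stochastic checks are stable across seeds while the whole
suite runs in seconds. OLS fits use `stats::lm` and are tested against the
closed-form covariance/variance expressions to 1e-10; the SMR scan is a
cumulative-sum sliding window tested against exhaustive enumeration. The
variance-homogeneity F places the larger variance in the numerator and uses
a two-sided p (doubled upper tail), Bonferroni-adjusted for the 6 pairwise
comparisons among 4 methods. Degenerate inputs are flagged, not patched:
zero-variance columns refuse the F-test, identical paired days report an
undefined correlation with a note, and a zero-variance one-sample t reports
p = 1 or 0 by the documented convention.

## Reproducibility statistics

`paired_day_stats()` reports the day-1 − day-2 convention throughout: mean
and SD of differences, paired t, Pearson r, Bland–Altman bias ± 2 SD (the
coefficient of repeatability), and the within-subject CV
$$\mathrm{CV\%} = 100 \cdot \frac{\mathrm{SD}(d)/\sqrt{2}}{\bar x},$$
with $d$ the paired differences and $\bar x$ the grand mean — the standard
two-period crossover form; the $\sqrt 2$ converts a difference SD into a
single-measurement within-subject SD. Published CV figures computed from
unrounded raw data generally cannot be reproduced exactly from rounded
aggregate tables, so the package's tests validate the CV on synthetic data
with known within-subject variance instead.

## Worked example

```{r example}
cfg <- sim_config(seed = 42)
sim <- simulate_session(cfg)
sim$truth$window_dit_kcal          # injected ground truth over the windows

res <- run_pipeline(sim$session)
res$table[, c("method", "total_kcal", "percent_of_intake", "r")]
```

## Known limitations

The fasting calibration assumes one EE–activity line covers all
postprandial movement; locomotor activity has a different energy cost per
mG than household activity, so sessions with much walking violate it. The
intercept method inherits any BMR error one-for-one in rate. Neither
method distinguishes DIT from other slow EE components (e.g. thermogenesis
after drinking water), which end up in the residual. Bout windows shorter
than 4 minutes have no steady-state interior and are rejected.
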