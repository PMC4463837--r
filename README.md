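# ditchamber

Diet-induced thermogenesis (DIT) — the rise in energy expenditure above the
fasting state caused by digesting and storing food — is a small residual
(~10% of intake) buried in whole-room indirect-calorimetry recordings.
`ditchamber` is an R toolkit for metabolic-phenotyping labs that estimates
DIT from chamber sessions by two approaches, with the full sensor chain,
resting-rate definitions, statistics battery and a ground-truth simulator.

Minute-level chamber energy expenditure is modeled additively:

    EE(t) = BMR + PAEE(t) + DIT(t) + noise

with two estimators, each usable with a triaxial-accelerometer vector
magnitude (`a`) or an infrared percent-movement index (`b`):

* **Fasting-calibration method** (`M1a`/`M1b`): an individual regression of
  steady-state EE on activity intensity across four fasted calibration
  bouts predicts the non-DIT expenditure `EEe(t) = b0 + b1 * PA(t)`;
  postprandially, `DIT(t) = EE(t) − EEe(t)`, summed over the evaluation
  windows and available as a minute-resolution time course.
* **Postprandial intercept method** (`M2a`/`M2b`, Schutz-type): EE is
  regressed on activity over 30-min postprandial waking bins; the
  zero-activity intercept estimates RMR = BMR + DIT rate, and
  `DIT = (RMR − BMR/1440) × evaluation minutes`.

Around the estimators the package provides: Butterworth high-pass filtering
and vector-magnitude aggregation of raw 32 Hz acceleration; infrared
per-second OR-then-count minute percentages; Weir-equation EE from VO₂/VCO₂;
sleeping metabolic rate (minimum 3-h sleep window); a validity and
test-retest statistics battery (one-sample and paired t, two-sided
variance-homogeneity F with Bonferroni, Pearson r, Bland–Altman limits,
within-subject CV); session file I/O; and a seeded session simulator with a
known BMR/PAEE/DIT decomposition.

## Worked example

Simulate a 24-h session (three meals totalling 2008 kcal, 10% of intake
injected as thermogenesis) and estimate DIT by all four methods:

```r
library(ditchamber)

cfg <- sim_config(seed = 42)
sim <- simulate_session(cfg)
sim$truth$window_dit_kcal
#> [1] 195.3567

res <- run_pipeline(sim$session)
res$table[, c("method", "total_kcal", "percent_of_intake", "r")]
#>   method total_kcal percent_of_intake         r
#> 1    M1a   195.1447          9.718359 0.9993591
#> 2    M1b   198.3782          9.879392 0.9998099
#> 3    M2a   189.8137          9.452875 0.6674009
#> 4    M2b   194.4322          9.682878 0.6591411
```

The true windowed DIT is 195.4 kcal (9.7% of intake; each 5-h window
captures ~96% of its meal's response curve). The fasting-calibration
estimate `M1a` lands within 0.2 kcal here; the intercept methods are close
on this session, but their weaker bin-level correlations (r ≈ 0.66 vs
≈ 0.999 for the four-point fasting calibrations) reflect the looser
EE–activity coupling at 30-min resolution that makes them sensitive to
activity timing. The `r` column logs each fitted regression so implausible
or negative estimates can be audited.

The reference 11-subject validity table (6-h fasted block, where the
theoretical DIT is zero) ships with the package:

```r
tab <- validity_dit_reference()
column_summary(tab$M1a)
#> $mean
#> [1] 22.45455
#>
#> $sd
#> [1] 13.4259
one_sample_t(tab$M1a)$ci95
#> [1] 13.43490 31.47419
count_negative(tab$M2b)
#> [1] 6
```

A thin CLI covers the same operations from a shell
(`inst/scripts/dit.R simulate|calibrate|run|stats`).

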