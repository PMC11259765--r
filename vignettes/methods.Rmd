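---
title: "Methods: heat-flux CBT estimation and biphasic shift detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-flux CBT estimation and biphasic shift detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovushift)
library(dplyr)
```

This vignette records the modelling assumptions, parameter choices and
numerical conventions behind `ovushift`, in enough detail that every
behaviour of the package can be predicted from this document alone.

## 1. The heat-flux model

### Physical picture

A temperature sensor worn on the chest measures skin temperature
$T_s$ (°C). Heat flows from the body core (temperature $\mathrm{CBT}$)
through tissue to the skin, and from the skin through clothing and a
boundary air layer to the environment at ambient temperature $T_a$. At
steady state the two conductive fluxes balance, giving

$$
\mathrm{CBT} = T_s + K\,(T_s - T_a),
$$

where $K$ (dimensionless, $K \ge 0$) is the ratio of the core-to-skin
thermal resistance to the skin-to-air resistance. `estimate_cbt()` is a
direct transcription of this equation.

### Assumptions

1. **Steady state.** The model ignores thermal inertia; it is valid for
   slowly varying signals, which is why the pipeline operates on
   sleep-time data after a warm-up discard.
2. **Constant $K$ within a night.** $K$ depends on sensor placement,
   adhesion and clothing; it is treated as fixed per night (or per
   subject/device once calibrated).
3. **Outward heat flow.** The model presumes $T_s > T_a$. Minutes with
   $T_a > T_s$ indicate reversed flux (detached sensor, external heat
   source) and are excluded rather than extrapolated.

### Calibrating K

During deep sleep CBT is nearly constant, so rearranging the model,

$$
T_s = \frac{K\,T_a + \mathrm{CBT}}{1 + K}
      = \alpha\,T_a + \beta,
\qquad \alpha = \frac{K}{1+K},\ \beta = \frac{\mathrm{CBT}}{1+K},
$$

and a linear regression of $T_s$ on $T_a$ over a night identifies
$K = \alpha / (1 - \alpha)$. `fit_thermal_coefficient()` implements
this with `stats::lm()` and guards the inversion:

- $\alpha < 0$ (slope pointing the wrong way, usually noise around a
  flat ambient trace) is clamped to $K = 0$ with a warning;
- $\alpha \ge 1$ has no physical $K$ and is an error
  (`ovushift_error_model`);
- a constant ambient trace leaves $\alpha$ unidentified and is an error
  (`ovushift_error_degenerate`);
- fewer than 10 pairs is an error (`ovushift_error_input`).

In simulation, the mean relative error of the recovered $K$ from one
night of 240 minutes with 0.05 °C sensor noise is a few percent (see
`scripts/acceptance.R`, `k_recovery_rel_error_pct`).

## 2. Nightly reduction

`preprocess_night()` and `summarize_night()` reduce a minute-level night
to one representative temperature. The defaults live in
`preprocess_config()`:

| parameter            | default | unit   | rationale |
|----------------------|---------|--------|-----------|
| `window_discard_min` | 60      | min    | sensor warm-up and settling-in transient after getting into bed |
| `window_length_min`  | 240     | min    | analysis window following the discard; long enough to average over posture changes, short enough to precede the pre-waking CBT rise |
| `max_step`           | 0.3     | °C/min | physiological CBT cannot change faster; larger jumps are sensor artifacts |
| `max_ambient_step`   | 2       | °C/min | ambient air cannot change faster under normal conditions |
| `min_valid_fraction` | 0.5     | —      | a representative mean over less than half the nominal window is not trusted |

Minute status is assigned in order: `out_of_window` (before the discard
ends or after the window closes), `invalid_range` (skin outside
15–45 °C or ambient outside −10–45 °C), `excluded_ambient`
($T_a > T_s$), `excluded_artifact`, else `valid`. An artifact run opens
when the estimated CBT jumps by more than `max_step` or ambient by more
than `max_ambient_step` from the previous minute, and closes only when
the signal returns to within `max_step` of the last pre-artifact valid
value — this holds the exclusion through a plateaued artifact (e.g. a
lifted sensor reading room temperature) rather than re-admitting it one
minute after the jump.

Two deliberate conventions:

- **Quorum against the nominal window.** `min_valid_fraction` is judged
  against `window_length_min`, not against however many minutes were
  recorded. A recording that ends 120 minutes into the window can still
  pass (120/240 = 0.5), but the bar does not silently drop for short
  nights; shorter recordings set `quality_flag = "too_short"` via the
  `truncated` attribute only when no analysis window can be formed at
  all.
- The representative temperature is the unweighted mean of valid-minute
  CBT estimates, which makes it invariant to the order of exclusions.

## 3. The three-over-six rule

`detect_shifts()` evaluates every candidate onset day $d \ge 7$ of a
daily temperature series:

- **Reference window:** the 6 calendar days $d-6, \dots, d-1$, of which
  at least 4 must be recorded. Let $M$ be their maximum and $\mu$ their
  mean.
- **Base rule:** days $d, d+1, d+2$ are all recorded and each
  $\ge M + 0.2$ °C.
- **Fourth-measurement exception:** $d$ and $d+1$ clear $M + 0.2$, the
  third value satisfies $M < v_3 < M + 0.2$, and the next *recorded* day
  after $d+2$ exceeds $M$ (by any margin).
- **Disregard exception:** among $d, d+1, d+2$, exactly one recorded
  value is $\le \mu$; it is disregarded, the other two must clear
  $M + 0.2$, and the next recorded day after $d+2$ must be
  $\ge \mu + 0.2$, completing the triple.

The three variants are tested in that order and are mutually exclusive:
the first that fires names the detection's `rule_variant`.

### Numerical conventions

- **Rounding.** Clinical basal thermometry reads to 0.01 °C, and the
  rule's strict/weak inequalities are meant at that resolution. All
  temperatures are rounded to 0.01 °C before comparison, and every
  comparison carries a $10^{-9}$ tolerance so that values equal after
  rounding never flip an inequality through floating-point
  representation error. A consequence, verified by test: detections are
  invariant under whole-series translation by any multiple of 0.01 °C.
- **Missing days** break a run of rising measurements (a candidate whose
  three base days include an unrecorded day fails the base rule, though
  the disregard exception may still apply to a recorded dip). The
  "next recorded day" used by both exceptions skips missing days.
- **Onset day = candidate day.** The reported `onset_day` is $d$, the
  first day of the (possibly repaired) rising run. Under the disregard
  exception the disregarded value may itself be day $d$; the detection
  then anchors one day *before* the first elevated value. This is a
  direct consequence of letting any one of the three values be
  disregarded, and the test suite pins it explicitly.
- **Fever masking.** `exclude_days` removes externally annotated
  disturbance days (fever, alcohol, disrupted sleep) from the series
  before evaluation, as the clinical rule prescribes.

### Cycle classification

`classify_cycle()` accepts a detection as evidence of ovulation only
when its onset falls in the last 14 days of the cycle
($d \ge \mathrm{length} - 13$), since the luteal phase is
physiologically capped near 14 days; earlier rises are treated as
noise. When several detections fall in the window, the *earliest* is
reported (`accept = "earliest"`, the default) — the first sustained rise
is the biologically meaningful one. Series shorter than 10 days are not
evaluable and classify as `not_evaluable`.

### Verification strategy

The detector is verified against `oracle_three_over_six()` (in
`tests/testthat/helper-oracle.R`), an independent, deliberately literal
loop-and-if transcription of the rule text, on 12,000 random series
drawn from a coarse temperature grid with missing days (2,000 in the
unit suite, 10,000 in the acceptance suite). Hand-traced examples pin
each rule variant, the 4-of-6 reference quorum, run-breaking by missing
days, the last-14-days filter and fever masking.

## 4. Cycle assembly and inclusion

`assemble_cycles()` splits each subject's daily table at menstruation
onsets; a cycle runs from one onset to the day before the next, so the
span after the final onset is dropped as incomplete (cohort generators
therefore emit a terminal onset row to close the last cycle). LH
labelling is trichotomous: any positive test → `ovulatory`, only
negatives → `anovulatory`, no tests → `unlabelled`.

`apply_inclusion_filters()` mirrors study-style exclusions, applied in
order: `too_short` (length < 15 days — too short to host a 6-day
reference, a 3-day rise and a 14-day acceptance tail), `missing_lh`, and
`missing_temps` (any temperature source missing on > 30 % of days; the
cycle is dropped for *all* sources so the paired method comparison stays
on a common cycle set). The filter is idempotent.

## 5. Diagnostic statistics

- `compute_metrics()` returns the five standard 2×2 ratios at full
  precision (percent for sensitivity/specificity/PPV/NPV, fraction for
  F1), with `NA` for zero denominators rather than errors.
- `mcnemar_test()` compares two methods on the same cycles through their
  discordant pairs $b, c$: exact two-sided binomial when $b + c < 25$,
  otherwise the continuity-corrected statistic
  $(|b - c| - 1)^2 / (b + c)$ on 1 df. The chi-square branch is
  cross-checked against `stats::mcnemar.test()` in the test suite.
- `proportion_test()` wraps `prop.test(correct = FALSE)` (equivalently
  the uncorrected chi-square) for comparing biphasic-call rates.
- `rmcorr()` implements the repeated-measures correlation as the ANCOVA
  `lm(y ~ subject + x)`:
  $r_{rm} = \mathrm{sign}(\hat\beta_x)\sqrt{SS_x / (SS_x + SS_{err})}$
  with $df = n - k - 1$ ($k$ subjects), and a Fisher-$z$ confidence
  interval with $se = 1/\sqrt{df - 1}$. It equals the Pearson
  correlation of within-subject-centred values (tested to $10^{-10}$)
  and is invariant to per-subject location shifts; the CI's empirical
  coverage is checked over 100 simulated datasets.

## 6. The synthetic-data module

### What the generator emulates

- **Nights** (`generate_night()`): a constant true CBT; a warm-up
  transient of amplitude −1.5 °C decaying over roughly the first quarter
  of a 45–75 min warm-up period; ambient air cooling at −0.5 °C/h with a
  slow random-walk wander (sd 0.5 °C over the night); Gaussian sensor
  noise (default sd 0.05 °C); optional detachment artifacts (a 1–3 °C
  skin-temperature drop lasting 5–15 min). Skin temperature is derived
  from CBT and ambient through the *same* heat-flux relation the
  estimator inverts, so exact recovery under no noise is a meaningful
  round-trip test rather than a tautology about means.
- **Cycles** (`generate_cycle()`): a follicular baseline (default
  36.48 °C), a luteal shift drawn from $N(0.41, 0.20^2)$ truncated at
  0.05 °C, an ovulation day at cycle length − 14 ± 2 days, LH tests
  daily from day 8 with the positive on the day before ovulation, i.i.d.
  daily noise (default sd 0.10 °C) and missing days (default
  probability 0.10). The defaults for the baseline, shift distribution,
  cohort size (26 subjects, 74 cycles, 60 ovulatory) and
  between-subject sd (0.22 °C) reproduce the population conditions of
  the validation study the pipeline is designed for; they are
  *descriptions of the study population*, not tuned values.
- **Cohorts** (`generate_cohort()`): per-subject baselines
  $N(36.48, 0.22^2)$, consecutive cycles with a closing menses-onset
  row, and two parallel temperature methods — the estimated CBT (noise
  sd 0.10) and a noisier oral BBT (noise sd 0.15) expressing only 80 %
  of the shift (`bbt_shift_factor = 0.8`), reflecting oral measurement's
  attenuated and noisier view of the core rhythm.

### The shift ramp

The post-ovulatory rise is a logistic ramp
`plogis(8 * (day - ovulation_day - 0.5) / shift_ramp_days)` (default
ramp 2 days; a `"linear"` shape is available). Centring the ramp half a
day *after* ovulation means the ovulation day itself carries essentially
none of the shift and the first post-ovulatory day carries ~88 % of it.
This matches the physiology (progesterone rises after, not at,
ovulation) and keeps shift days out of the detector's reference window;
centring at the midpoint instead would place a half-shifted day in the
reference and suppress detection even in noiseless data.

### Why synthetic sensitivity is lower than field reports

With the default i.i.d. daily noise of 0.10 °C, end-to-end sensitivity
for a 0.41 °C shift is roughly 30–35 %, well below the ~85 % reported
for comparable hardware in clinical cohorts. This is expected, not a
defect: the three-over-six rule conditions on the *maximum* of six
reference days, and six independent draws of 0.10 °C noise inflate that
maximum by ~0.13 °C on average, while each of three consecutive rise
days must independently clear it by a further 0.2 °C. Real
basal-temperature series are strongly autocorrelated night-to-night
(stable sleep architecture, slow hormonal drift), which the i.i.d.
generator deliberately does not model. The package therefore treats
*monotonicity* — sensitivity strictly increasing in shift size (0 %,
~1 %, ~30 % at shifts of 0.10, 0.20, 0.41 °C) and exact detection in the
noiseless limit — as the validated property, and makes no claim that the
generator's absolute operating point matches field data. No generator
parameter or detector threshold was adjusted to move these numbers.

### Determinism

Every generator takes a `seed`; when supplied, the global RNG state is
restored afterwards (`withr::local_seed()`), so generators are pure
functions of their arguments and replay identically. The acceptance
script derives all of its seeds from its single `--seed` argument.

## 7. Problem sizes and runtimes

On one CPU core: the full test suite (≈4,400 assertions, including
12,000 oracle-comparison series, a 74-cycle end-to-end cohort, 600
grid cycles and 100 CI-coverage replicates) runs in ~75 s;
`scripts/acceptance.R` in ~11 s. Memory stays well under 1 GiB.

## 8. Limitations

- The heat-flux model is steady-state and single-compartment; it cannot
  correct for rapid posture-driven perfusion changes within a minute.
- $K$ calibration needs ambient variation within the night; a perfectly
  climate-controlled room leaves $K$ unidentified (the package refuses
  rather than guesses).
- The synthetic module models neither night-to-night autocorrelation nor
  cycle-length variability beyond ovulation-day jitter; absolute
  diagnostic metrics on synthetic cohorts should not be quoted as
  expected field performance.
- The disregard exception's anchoring (onset possibly one day before the
  first elevated value) follows from the rule text; users comparing
  onset days against other implementations should check which convention
  those use.
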