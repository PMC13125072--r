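---
title: "Methods: simulation, reasoning and evaluation in vitalwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, reasoning and evaluation in vitalwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalwatch)
library(dplyr)
```

vitalwatch studies a context-aware patient-monitoring architecture end to
end: a synthetic cohort of virtual patients streaming vital signs, sensor
agents that derive High/Low/Normal statuses from threshold rules and
broadcast Tell messages, a probabilistic-logic layer for exact
call-the-doctor reasoning, a tick-based multi-agent escalation simulation,
and a benchmark of five classifiers implemented from their defining
equations. This vignette records the models, the tunable parameters, and
the design decisions behind each layer, in the spirit of a lab notebook a
maintainer can audit.

## The synthetic cohort

No patient data ships with the package; everything downstream is exercised
on cohorts drawn by `generate_cohort()`. The default configuration creates
1,000 virtual patients with 120 sequential records each — one record per
monitoring tick — at an exact 60/40 split of `Normal` versus `SARS-risk`
labels ("SARS" in the generic sense of a severe acute respiratory distress
pattern, not a specific pathogen). Class counts are produced by rounding,
not by Bernoulli sampling, so the cohort composition is deterministic and
testable.

Channel values follow a two-factor latent structure chosen to mimic the
statistical texture of real monitoring data:

* a **severity factor** `s` (standard normal; shifted by
  `severity_shift = 1.6` for the risk class) that raises heart rate, ECG
  index, body temperature, systolic pressure and blood sugar and depresses
  SpO2 — the common-cause signature of physiological deterioration;
* a **comorbidity indicator** (prevalence `comorbidity_rate = 0.38`,
  independent of the class label) representing baseline sympathetic
  activation — e.g. chronic hypertension with tachycardia — that adds fixed
  offsets to the cardiovascular channels (heart rate +16 bpm, ECG index
  +13, systolic +25 mmHg, diastolic +16 mmHg, blood sugar +28 mg/dL) in
  both classes alike. Diastolic pressure carries almost no severity
  loading, which makes it an informative marker *of the comorbidity
  itself*.

Patient baselines add an independent between-patient effect per channel;
records add within-patient noise; and every value is clipped to its
class's physiological range. The `Normal`-class ranges sit inside the
nominal dataset ranges (heart rate 60–100 bpm, blood pressure 60–175
mmHg, body temperature 98–105 °F, ECG index 80–120), while risk-class
ranges extend far enough that the threshold rules can fire. SpO2 is
generated on a clinically plausible 70–100% scale.

Two aspects of this design deserve emphasis. First, only the marginal
ranges above are fixed; the class-conditional distributions are this
package's own design. The latent-factor structure and its constants were
calibrated once so that ridge logistic regression lands in the target
operating region (accuracy ≈ 0.744, ROC-AUC ≈ 0.820, MCC ≈ 0.530) on
repeated splits; the constants live
in `cohort_config()`/`default_channels()`, not in code. Second, the
comorbid subgroup is what separates the jointly fitted models from the
marginal ones: a naive-Bayes model sees elevated cardiovascular channels
and reads them as risk, while a joint linear model learns to discount them
using the diastolic marker. That is the realistic mechanism behind the
benchmark's headline ordering, and it also means the cohort emulates
*cross-channel correlation structure*, not merely shifted means. What the
generator does not emulate: temporal autocorrelation beyond a constant
per-patient baseline (records are exchangeable within patient), sensor
drift/failures, treatment feedback, or circadian rhythm — so passing tests
say nothing about those aspects of real telemetry.

Missingness is injected completely at random per cell
(`missing_rate = 0.03` by default); identifiers, ticks and labels are
never masked.

## Preprocessing

`preprocess_cohort()` applies, per patient per channel: forward-fill of
gaps up to `ffill_limit = 3` ticks (real-time-consistent imputation for
short sensor dropouts), channel-mean imputation for whatever remains
(isolated or leading gaps), a trailing moving average of
`smoothing_window = 5` ticks, and min–max scaling into [0, 1]. The moving
average is trailing (causal) rather than centered because a deployed
monitor cannot see the future; partial head windows average what exists.
A channel that is constant on the fitting portion maps to 0 by convention.
Imputation means and scaling bounds can be fitted on a designated subset
of patients (`bounds_patients`) to keep train/test separation strict; when
the benchmark is run on a cohort preprocessed as a whole, the min–max
transform is a fixed monotone per-channel map, which leaves classifier
rankings and threshold-based decisions unchanged — the leakage-sensitive
quantities (class-conditional fits, Youden thresholds) are always
estimated on training patients only.

## The sensor-agent rule layer

`threshold_profile("reference")` encodes the package's canonical
sensor-agent rule table (rules R1–R28): fever at ≥ 39 °C and hypothermia at ≤ 37 °C, heart rate high at
≥ 100 bpm and low at ≤ 60, blood sugar high at ≥ 150 mg/dL and low at
≤ 70, ECG abnormal at ≥ 1.2 and low at ≤ 0.6 on the ratio scale, room
temperature high at ≥ 35 °C and low at ≤ 15 °C, compound blood pressure
high at 145/100 and low at 100/60 mmHg, and blood oxygen saturation
flagged **High** at ≥ 90 (rule R4). That last rule is clinically
backwards (desaturation, not high saturation, is the emergency), so a
second profile, `"clinical"`, flags SpO2 ≤ 90 as Low instead; the
reference profile is the default and both ship as YAML files under
`inst/extdata/profiles/`. Three further conventions the rule table leaves
open: boundary values belong to the extreme rules (a value equal to a
cutoff is High/Low, strictly-between is Normal, so the three statuses
partition the line); compound blood pressure is High when *either*
component exceeds its cutoff, Low when either falls below, with High
taking precedence if both fire; ECG data arrives on two scales in
practice (0.6–1.2 ratio vs. 80–120 index), so the profile carries an
`ecg_divisor` (100 maps the index scale onto the ratio
cutoffs). Tell messages are emitted exactly for the non-Normal statuses
whose rules carry Tell clauses; the fire sensor relays its level
unconditionally.

## Probabilistic logic

The reasoning layer is a minimal probabilistic-logic engine: independent
probabilistic facts (`0.9::fever.`) plus negation-free definite clauses
(`call :- fever, low_spo2.`), acyclic by validation. A query's marginal is
the total weight of possible worlds in which the atom is derivable —
`enumerate_worlds()` is the brute-force oracle (capped at 20 facts), and
`query_marginal()` restricts to the query's dependency cone before
summing, which keeps desk-scale programs exact and fast without knowledge
compilation. Multiple clauses for one head combine as logical OR over
worlds, so independent single-fact bodies give the familiar noisy-or
`1 − Π(1 − pᵢ)`.

The shipped example program `inst/extdata/sars_call.pl` encodes the
worked call-the-doctor scenario with its evidence strengths (white-cell
abnormality 0.5, tachypnea 0.6, fever 0.9, desaturation 1.0); its call
marginal is 0.72. The tests assert that the marginal is a probability and
monotone in every evidence strength — the properties that matter for
alerting — rather than any single endpoint value.

## The multi-agent simulation

`sim_setup()`/`sim_step()` implement the tick loop: patients and doctors
wander (unit steps, reflecting boundaries, cosmetic 33×33 grid), the seven
sensor agents (blood oxygen, environmental, body temperature, heart rate,
ECG, blood pressure, room temperature) read each patient's current record
through the rule layer, and each patient's risk probability is updated as

> p = clip( logistic(intercept + abnormal_weight · n_abnormal) + drift )

where `n_abnormal` counts that patient's non-Normal statuses this tick,
`intercept = −3` and `abnormal_weight = 1.2` place an all-normal patient
near 0.05 and a five-alarm patient near 0.95, and the Gaussian drift
(`drift_sd = 0.02`) models unexplained fluctuation before clipping to
[0, 1]. The update rule is this package's own construction, and it is the piece that ties the rule layer to the escalation machinery.
Escalation cutoffs (critical ≥ 0.6, extremely critical ≥ 0.8,
life-threatening ≥ 0.95; the first aligned with the high-risk alert
boundary) map to doctor notification (nearest doctor by Euclidean
distance, ties to the lowest agent id, alert fallback when no doctor
exists), alert generation, and ambulance dispatch; each above-cutoff
patient produces exactly one event per tick at its highest severity.
Randomness is split into named streams (setup, movement, drift) derived
from one master seed, so the event log is a pure function of
(seed, config, ticks) and movement draws can never perturb drift
sequences. The population-level statistic is the arithmetic mean of
patient probabilities, guarded to `NA` for an empty population. Treatments
are carried as opaque attributes with no effect model, since no mechanics
are specified for them.

## Classifiers from their equations

All five classifiers are implemented in this package from their defining
update equations; established libraries appear only as independent oracles
in the test suite.

* **Gaussian naive Bayes** — class priors and per-class per-feature
  normal densities under conditional independence, posterior by Bayes'
  rule; plain densities (no kernel estimation), variance floor `1e-9`.
* **Multinomial naive Bayes** — the token-count model adapted to vitals
  by 10 equal-width bins per feature with Laplace `alpha = 1`; unseen bins
  survive through the smoothing, constant features contribute nothing.
* **Decision table** — IF(conditions)-THEN(action) lookup over binned
  features; the schema is chosen by greedy forward selection maximizing
  3-fold cross-validated accuracy (deterministic row-order folds), with a
  global-majority fallback for unseen keys. A best-first subset search
  with leave-one-out, as rule-learning workbenches use, would be costlier
  without changing the semantics under test; greedy forward selection is a
  documented deviation.
* **Ridge logistic regression** — the sigmoid model fitted by damped
  Newton/IRLS with an unpenalized intercept, `ridge = 1e-8` (the
  conventional workbench default), `max_iter = 100`; non-convergence
  returns a flagged fit rather than an error.
* **SMO support vector machine** — the simplified sequential-minimal-
  optimization loop: error cache `Eᵢ = f(xᵢ) − yᵢ`, curvature
  `η = K(xᵢ,xᵢ) + K(xⱼ,xⱼ) − 2K(xᵢ,xⱼ)`, box-clipped pair updates under
  `0 ≤ α ≤ C` and `Σ αᵢyᵢ = 0`, threshold recomputation, termination
  after `max_passes = 10` clean passes. The partner choice is the
  deterministic max-|Eᵢ−Eⱼ| heuristic with fall-through, so fits are
  reproducible without randomness. Defaults `C = 1`, `tol = 1e-3`, linear
  kernel (an RBF kernel is available). Because the loop's cost grows
  quadratically with the training size, fits are capped at
  `max_train = 2000` rows by deterministic stratified thinning — ample for
  a stable linear boundary on this problem. SMO decision values are
  min–max mapped to [0, 1] for the alerting layer; that score is monotone
  but deliberately not a calibrated probability.

`SARS-risk` is the positive class throughout, fixing the TP/FP
orientation of every metric. Identifier-like columns (`patient_id`,
`tick`) are never used as features.

## Evaluation protocol

`run_benchmark()` repeats a stratified 70/30 train–test split ten times.
The split unit is the **patient**: all 120 records of a patient fall on
one side, because record-level splitting would leak within-patient
correlation into the test set. Each
classifier is fitted on training records; record-level positive-class
probabilities are averaged into one score per patient (an alternative
`max` aggregation is available); the operating threshold is selected by
Youden's index (max TPR − FPR, ties to the lowest threshold) on the
*training* patients; and test-side metrics are computed from the
confusion table (TP-rate, FP-rate, precision, recall, F1, accuracy, MCC
with the zero-denominator conventions) plus trapezoidal ROC-AUC and
step-interpolated PR-AUC. Results are reported as mean ± sample SD
(n−1). Logistic regression and Gaussian naive Bayes are compared by
McNemar's test on their matched per-patient test predictions in every
repeat — exact binomial below 25 discordant pairs, continuity-corrected
chi-square otherwise. Train/test patient sets are disjoint by
construction and asserted in tests.

Classifier probabilities are mapped to the three clinical alert levels —
low < 0.3, moderate 0.3–0.6 (boundaries inclusive), high > 0.6 — by
`alert_level()`, with per-agent configurable boundaries.

## Problem sizes and numerical conventions

The unit-test suite runs on small cohorts (tens of patients, ~10–30
records) so every module's contracts are checked in seconds; the
end-to-end benchmark tests use the full default cohort (1,000 × 120, ten
repeated splits), a few minutes of CPU, which is the same experiment
`scripts/acceptance.R` re-runs from scratch. Other conventions:
probability rows are validated to sum to one within 1e-9; world
enumeration is exact (tolerance 1e-12 against the oracle); min–max
degenerate ranges map to 0; Youden ties resolve to the lowest threshold
(favouring sensitivity); equidistant doctors resolve to the lowest agent
id; and every random draw in the package flows through named streams
derived from a single master seed.

## Known limitations

The cohort is a calibrated emulation, not a reproduction of any real
dataset: the benchmark numbers are calibration targets rather than blind
replications, and external validation against clinical databases is out
of scope. The rule language is a fixed threshold schema, not a
general logic; the probabilistic-logic engine excludes negation and
probabilistic clauses; the simulation's treatment handling is
intentionally inert; and the SMO implementation is the simplified
textbook variant, adequate for desk-scale benchmarks but not tuned for
large-margin production training.
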