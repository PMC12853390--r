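---
title: "Sigma-stratified dynamic QC: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigma-stratified dynamic QC: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmaqc)
```

# The problem

Routine hematology analytes (Hb, WBC, RBC, HCT, PLT) differ widely in
analytical stability, allowable error, and clinical risk, yet most
laboratories control all of them with the same QC frequency and the same
rules. **sigmaqc** implements a differentiated, patient-data-aware
alternative built from four cooperating pieces:

1. **Sigma-metric assessment** grades each analyte's analytical performance
   and assigns it a QC plan (frequency + Westgard rule set) matched to risk.
2. An **adaptive moving-average (MA) monitor** watches the stream of
   accepted patient results continuously, between control-material runs.
3. An **LSTM deviation forecaster** reads the recent patient series and
   warns *before* a developing systematic shift becomes large.
4. A **Westgard multirule engine** provides the confirmatory verdict on
   control materials, and an orchestrator ties the three tiers together
   into alerting / out-of-control events with lead-time accounting.

# Sigma metrics and the matrix correction

For an analyte with total allowable error $TEa$, bias
$\mathrm{Bias} = |(\bar{x}_{lab} - x_{ref})/x_{ref}| \times 100$, and
imprecision $CV = SD/\bar{x} \times 100$ (sample SD, $n-1$), the sigma
metric is

$$\sigma = \frac{TEa - \mathrm{Bias}}{CV},$$

all three terms in percent. Grading: $\sigma \ge 6$ world-class ("high"),
$3 \le \sigma < 6$ acceptable ("moderate"), $\sigma < 3$ high-risk
("low"); boundaries are inclusive upward ($\sigma = 6$ is high). A
negative sigma (bias above TEa) is reported with a warning rather than an
error — it is an actionable QC finding.

Control materials are not patient plasma. When a patient-result CV is
available, the matrix correction factor

$$F = \frac{CV_{patient}}{CV_{IQC}}, \qquad
  \sigma_{adj} = \frac{\sigma}{F}$$

deflates sigma for the extra matrix/biological variability. Two numeric
modes are provided. The default *reported* mode divides by $F$ rounded to
2 decimals (half-up) and reports 2 decimals — the convention under which
published corrected tables reproduce exactly (e.g. $CV$ pair (1.5, 1.6)
gives $F = 1.07$ and $4.65/1.07 = 4.35$); the *exact* mode keeps full
precision. Rounding is half-away-from-zero throughout reporting
(`round_half_up()`), matching laboratory practice rather than R's
round-half-even.

`stratify_plan()` maps the grade to the plan: high runs QC once daily
under a single 1-2s rule; moderate runs per batch under a 1-2s + R-4s
multirule; low runs every 4 h under a dual rejection rule with MA
monitoring enabled. When $\sigma_{adj}$ exists it overrides raw sigma for
tiering — the corrected value is the clinically relevant one.

Choices made where the design was open:

* The low tier's "dual rule" is pinned to {1-3s, 2-2s}: a Levey-Jennings
  rejection pair with good error detection and low false rejection,
  complementing the MA tier that covers slow drift. Any of the six shipped
  rules can be configured instead.
* A sole 1-2s rule (the high tier) is treated as a rejection criterion,
  since it is then the only failure rule; inside a cascade it is a warning.

# The adaptive MA monitor

After preprocessing (flagged samples dropped; gross outliers beyond
`outlier_sd` = 3 target-SDs from the target excluded, measured against the
*fixed* analyte target so a genuine shift cannot mask itself), the monitor
maintains a sliding mean over the last $W$ accepted values, re-evaluated
at every sample:

* $W$ starts at 100 (warm-up; no status is emitted until the buffer first
  holds 100 values), then adapts at each step: 50 when the real-time CV
  (over the current buffer) exceeds the historical CV (trailing 1000
  accepted samples), 150 otherwise. Shrinking keeps the most recent 50
  values; growth lets the buffer refill to 150.
* Status comes from dynamic limits $\bar{x}_T \pm k \cdot SD_{limit}$ with
  $k_{alert} = 1.5$ and $k_{ooc} = 2.5$.
* Escalation: three consecutive alert evaluations, or a single
  out-of-control breach, suspend testing for investigation. "Three
  consecutive runs" is implemented as three consecutive evaluated samples;
  the patient stream carries no batch structure.

**What does "SD" mean in the limits?** This is the one genuinely
underdetermined constant, and both readings are implemented
(`ma$sd_mode`):

* `"ma_statistic"` (default): $SD_{limit} = s_{base}/\sqrt{W}$, the
  sampling SD of the MA statistic itself, with $s_{base}$ the SD of the
  first `calibration_n` = 500 accepted values (the analyte target SD is
  used until calibration completes). Limits on an averaged statistic must
  scale with its own variability, otherwise $\pm 1.5\,SD$ around a
  100-sample mean would never fire. We estimate the MA's marginal SD from
  the baseline *values* rather than from the SD of the overlapping MA
  series: the latter estimates the same quantity with an effective sample
  size of only `calibration_n`/W and is badly biased downward, tightening
  the limits and flooding the monitor with spurious out-of-control
  states. Note the operating characteristics this reading implies: since
  the standardized MA is approximately standard normal in control, the
  marginal exceedance rates per evaluation are about 13% beyond the
  alert limit and 1% beyond the out-of-control limit. The false-alarm
  regression test pins a calibrated ceiling of 200 alerts per 1000
  evaluated samples.
* `"population"`: $SD_{limit}$ is the raw target SD. Alerts are then rare,
  decisive breaches; with default preprocessing a sustained shift can
  never push the accepted MA past $2.5\,SD$ (the $3\,SD$ exclusion band
  caps the accepted mean below it), so this mode pairs naturally with a
  wider gross-outlier band (see the lead-time study below).

The historical CV is the CV over the trailing 1000 accepted samples
(falling back to whatever history exists after warm-up); real-time and
historical CV use the same cumulative-sum machinery, so every window
statistic is exact, not approximated.

# The LSTM deviation forecaster

The forecaster is a single-layer LSTM: 100 consecutive accepted values in
(standardized by the analyte target mean and SD), 64 tanh hidden units,
and a linear head predicting one scalar — the mean deviation of the next
10 samples from the target mean, in analyte units. "Mean deviation trend
of the next 10 samples" is deliberately operationalized as this scalar:
it is the quantity the red-alert rule needs, and a scalar target keeps
the loss (MAE) and the early-warning threshold well defined.

Training uses Adam (learning rate 0.005, minibatch 128, global-norm
gradient clipping at 5), an 8:2 train/validation split, optional k-fold
cross-validation *inside* the training portion (model-selection
diagnostics; the untouched 20% yields the reported MAE), and early
stopping (patience 10 by default). No deep-learning framework is
involved: forward and backward passes are written in C++ (Armadillo) and
every source of randomness — weight initialization, the split, fold
assignment, minibatch order — is drawn from R's RNG under the config
seed, so a seed fully determines the fit.

The red alert fires when the predicted deviation strictly exceeds 50% of
TEa (`warn_fraction_of_tea` = 0.5); a prediction of exactly half TEa does
not alert. TEa may be stored as percent-of-target or in absolute units
(PLT conventionally uses an absolute limit); it is converted to analyte
units at the comparison.

Defaults the architecture leaves open: `max_epochs` 200 with early
stopping, single recurrent layer, linear output head.

# The orchestrator

`run_monitoring()` runs whichever tiers the QC plan enables, in time
order (patient samples before control samples at equal timestamps):
forecaster (re-forecast every 10 accepted samples by default), MA
monitor, and the Westgard engine over the control stream (runs are
grouped by identical timestamps). Patient-tier events are emitted at
rising edges — entry into red alert, alert, or out-of-control — not at
every affected sample. An alert followed within the episode horizon
(24 h) by a Westgard rejection becomes a *dual* record: one row counted
under both the alerting and the out-of-control tally, carrying
`t_confirmed` and the confirming rule. Unconfirmed alerts stay alerting.
Lead times are summarized per episode (a new episode starts when an
upstream event is separated from the previous one by more than the
horizon), and episodes without a downstream confirmation are excluded
from the averages but counted.

# The synthetic stream generator

The generator emulates a *stationary* analyte stream with injectable
faults — the minimal structure the monitoring framework assumes:

* Baseline draws are normal for Hb/RBC/HCT and log-normal (matched to the
  target mean and CV) for the count-type analytes WBC/PLT; both families
  are available for every analyte.
* Default PLT scenario: target 250 x 10^9/L, baseline CV 2.8%, 20
  samples/hour (so a 100-sample window spans 5 h and lead times read
  naturally in hours), 1% per-flag rate, 0.5% gross outliers at 3.5-6 SD.
* Faults: step shifts (in target-SD multiples), linear drifts (analyte
  units per sample), and CV inflation, each active over a stated onset
  and duration; ground-truth labels mark affected samples.

What it does **not** model: patient-mix drift (ward/outpatient case mix,
diurnal patterns), autocorrelated biology, multicenter effects, or
instrument-specific artifacts. Passing tests on these streams show that
the monitors detect what they claim to detect under clean stationarity;
they do not establish real-world false-alarm rates, which depend on
population structure the generator deliberately omits.

# The canonical lead-time study

The question "how far ahead of the MA monitor does the forecaster warn?"
is answered on a pinned scenario pair (`canonical_drift_scenario()`):

* **Training stream**: 5000 supervised windows from a PLT stream with
  eight linear-drift episodes of both signs, slopes 0.03-0.08 SD/sample,
  durations 40-80 samples (peaks 2.4-3.2 SD) — ramps of both directions
  across the deviation range where the red-alert threshold (0.5 TEa =
  0.71 SD for the default PLT spec) lives. The study model trains with
  up to 100 epochs, patience 20, no inner CV (one well-converged model is
  needed, not a model-selection estimate).
* **Test streams**: 1000 in-control samples (warm-up + limit calibration
  + history), then one 150-sample drift at 0.05 SD/sample. Twenty seeded
  replicates.
* **Monitor configuration** (`canonical_drift_config()`): population-SD
  limits and a 6 SD gross-outlier band. The comparison is only meaningful
  when MA out-of-control events are fault-driven: under MA-statistic
  scaling the OOC threshold (about 0.2 SD) sits far below the red-alert
  threshold (0.71 SD) and carries a percent-level per-sample false rate,
  so a first-event comparison measures the monitor's noise floor rather
  than the forecaster's anticipation — analytically, even a perfect
  forecaster cannot precede a detector whose threshold is 3.5 times more
  sensitive than its own. Under population scaling with the default 3 SD
  exclusion band the breach can never happen at all. The pinned pair is
  the configuration under which the
  three-tier cascade is well ordered; the monitoring constants themselves
  ($k = 1.5/2.5$, the 50%-TEa rule, windows 50/100/150) are untouched.
* The forecaster is evaluated at every accepted sample in the study (the
  same cadence as the MA), so timing differences reflect the detectors,
  not polling granularity.

The acceptance suite runs this protocol and asserts red-alert precedence
in at least 80% of the replicates with positive mean lead; the README
shows the lead times one such run prints.

# Numerical choices and degenerate inputs

* Rolling means/CVs use cumulative sums — exact to double precision; the
  MA equals a brute-force window mean to 1e-12 by regression test.
* CV requires at least 2 values and a nonzero mean; kappa errors on
  degenerate marginals ($p_e = 1$); AUC requires both classes and handles
  ties by midranks.
* Reporting rounds half-away-from-zero; internal computation keeps full
  precision except where the *reported* correction mode intentionally
  divides by the rounded factor.
* Streams must be non-decreasing in time; a regression is a hard error at
  read time, never silently sorted, because every lead-time statistic
  depends on order.

# Problem sizes

Test and example problem sizes are desk scale by design: streams of
1200-10000 samples, 5000 training windows, 12-20 seeded replicates per
property. They are large enough for the sampling-error bounds asserted in
the tests and small enough to iterate comfortably.

# Known limitations

* The forecaster saturates (tanh) on deviations far outside its training
  range; it is a near-threshold early-warning instrument, not a magnitude
  estimator for gross faults. Models should be retrained per analyte and
  per site.
* The MA-statistic reading of the control limits alarms frequently by
  construction; laboratories wanting rare, decisive alarms should use the
  population reading (and a gross-outlier exclusion wide enough for it to
  fire).
* Sigma assessment treats the reference value as exact; uncertainty in
  the peer-group median is not propagated.
* The event model records actions as labels (recalibration, suspension);
  it does not simulate the effect of interventions on the stream.
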