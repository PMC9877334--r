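---
title: "Methods: multimodal CGM and activity analytics for remote review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal CGM and activity analytics for remote review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucowear)
```

## The problem

Remote patient monitoring for newly diagnosed youth with type 1 diabetes
reviews a whole clinic population asynchronously, typically on a
two-week cadence. Two device streams carry the signal: a CGM sampling
interstitial glucose nominally every 5 minutes (up to 288 readings per
day), and a wrist-worn activity tracker reporting heart rate, per-minute
step counts, METs and recorded exercise sessions at irregular intervals.
`glucowear` turns these two raw exports into (i) a synchronized display
frame, (ii) per-period metric rows, (iii) flags for clinician attention
and (iv) a prioritized review table. This vignette records the model
behind each step, the tunable parameters, and the choices made where the
design was genuinely open.

## Input model and cleaning

CGM data arrives as CSV (`timestamp,glucose_mg_dl`), activity data as a
JSON object with four streams. Vendor exports contain re-sent and partial
records, so every stream passes through one cleaning function with three
rules:

- **Incomplete** records — missing timestamp, missing value, or value
  outside the stream's physiological bounds (glucose 20–600 mg/dL, heart
  rate 25–250 bpm, steps and METs ≥ 0) — are dropped. The bounds-based
  definition of "incomplete" is our own: it makes the invariant testable
  while catching the sentinel values vendors use for failed readings.
- **Duplicates** — a second record at an already-seen timestamp — are
  dropped. When values differ at a shared timestamp the *last-read*
  record wins, on the rationale that vendor re-sends supersede earlier
  transmissions. This is the one place cleaning is order-sensitive: for
  inputs without conflicting same-timestamp records (the normal case),
  cleaning is fully permutation-invariant, and the test suite checks
  exactly that.
- Every dropped record is counted:
  `n_in = n_out + duplicates_removed + incomplete_removed` always holds.

All timestamps carry an ISO-8601 UTC offset and are converted once to a
single fixed "standard time" offset (configurable, default +00:00, no
daylight-saving shifts). Day, minute and epoch arithmetic downstream is
then plain clock arithmetic. Serialization is canonical — fixed key
order, glucose and bpm to one decimal, METs to two — so parse → write is
bit-for-bit idempotent.

Run configuration is a JSON (or YAML) file merged over the defaults with
unknown keys rejected; both formats have mature, schema-free parsers in
the R ecosystem, which is why they were chosen as the configuration
dialects.

## Display synchronization

The overlay places glucose, heart rate and steps on a fixed grid
(default 1 minute, the finest cadence of any stream). Glucose and heart
rate are drawn as lines with piecewise-linear interpolation; steps as a
step plot, never interpolated.

The missing-data rule: a stream silent for **more than 15 minutes** is
not bridged. We read "more than" strictly — a gap of exactly 15:00
stays within one segment; 15:00.001 breaks it — and apply the rule per
channel independently, so an hour of tracker non-wear leaves the CGM
line intact while heart rate and steps show nothing. Segments never
extrapolate: grid points outside a segment's first/last sample are
masked out, and a single-sample segment is shown only in its own minute.

Interpolation exists for visualization only. Every metric and flag in
the package consumes raw samples; no interpolated value ever enters a
computation.

## CGM metrics

All percentages weight samples equally, with no duration weighting —
CGM sampling is nominally uniform at 5 minutes, and the simplification
is recorded here as a limitation for traces with irregular cadence.
Review periods are half-open `[start, end)` (default 14 days), so
adjacent periods partition a timeline without double counting.

- **Wear percent** = 100 × observed / expected samples, expected =
  period minutes / sampling interval (default 5 min), capped at 100.
- **Mean glucose** = arithmetic mean of raw values; absent (never zero)
  for an empty period.
- **Bands.** TIR is [70, 180] inclusive at both ends; hypoglycemia bands
  are strict (< 70, < 54); hyperglycemia bands strict (> 180, > 250).
  The printed clinical targets ("70–180", "<70", ">180") do not fix the
  boundary convention; this choice is the one that makes
  {TBR<70, TIR, TAR>180} an exact partition, so their percentages sum to
  100 — an invariant the tests enforce to 1e-9 on random traces.
- **TIR change** is an arithmetic difference in percentage points, not a
  relative change: that is how TIR deltas are read clinically, and it
  keeps antisymmetry exact.

## Activity metrics

- **Tracker wear** is inferred from heart rate: a minute is worn iff at
  least one valid heart-rate sample falls in it. The tracker reports
  heart rate continuously while worn, so heart-rate presence is the
  cleanest wear proxy; the minute granularity makes the estimate
  oracle-testable by a brute-force minute scan.
- **Epochs** tile each day as half-open 15-minute intervals anchored at
  local midnight (half-open prevents double counting; the anchor makes
  epochs reproducible across runs). Epoch steps are the sum of member
  minutes; epoch mean MET the mean of member MET minutes, absent minutes
  excluded; epochs with no data are omitted.
- **Intensity** is classified from epoch mean MET with cutpoints 1.5 and
  3.0: sedentary below 1.5, active in [1.5, 3.0), highly active at or
  above 3.0. The three category names are standard wearable vocabulary;
  the cutpoints are not printed with them, so we adopt the conventional
  1.5-MET sedentary ceiling and 3.0-MET moderate-intensity floor. Both
  are configurable.
- **MVPA** is counted in whole highly-active epochs (epoch granularity,
  not per-minute), because intensity is defined at the epoch level. The
  daily guideline is ≥ 60 MVPA minutes (configurable); a day with no
  data in any stream is all-absent with `guideline_met = FALSE`, and
  such days count against `pct_days_guideline_met` but are excluded from
  the step/MVPA means so absence is never conflated with inactivity.
- **Activity change** is relative (percent of the previous period's mean
  daily MVPA), absent when there is no previous period or the previous
  mean was zero. Unlike TIR — an already-bounded percentage — activity
  volume has no natural scale, so a relative change is the readable
  choice.

## Flags

**Exercise flags** evaluate raw glucose samples inside each recorded
session window `[start, end]`, inclusive at both ends, with no
post-exercise extension (nocturnal hypoglycemia risk is out of scope).

- `rapid_drop`: the maximum decline from any earlier in-bout sample to
  any later one — the running-maximum excursion — reaches 50 mg/dL.
  This is the strictest reading of "a drop during exercise" (start-to-end
  would miss a fall that partially recovers) and is verified against an
  O(n²) all-pairs oracle in the tests. Two in-bout samples are required;
  with fewer the drop is not evaluable and no drop flag is emitted.
- `in_bout_hypoglycemia`: any in-bout sample strictly below 70 mg/dL;
  evaluable from a single sample. The flag's evidence is the in-bout
  nadir.

At most one flag of each kind is emitted per bout. Lowering the drop
threshold or raising the hypoglycemia threshold can only add flags
(monotonicity, tested by sweep).

**Population flags** compare the period summaries against configurable
thresholds: CGM wear < 70%, tracker wear < 50%, guideline-met days
< 50%, TIR change ≤ −5 pp, activity change ≤ −25%. The example flag
families are named in the clinical workflow but no thresholds are
printed with them; these defaults are config values chosen at plausible
clinical screening levels, not calibrated quantities. An absent metric
never flags.

## Prioritization

The production care model's ranking algorithm is published separately
and is deliberately not reproduced. The default policy here is an
explicit, configurable stand-in: lexicographic and safety-first —
TBR<54 descending, TBR<70 descending, TIR change ascending (absent
treated as 0, i.e. neutral), TIR ascending, patient id as the final
tie-break. The id tie-break makes the order total, hence
permutation-invariant, which the tests verify by shuffling. Ranks are
1..N with 1 reviewed first.

## The synthetic patient simulator

The simulator defines the study conditions for every test; its defaults
are fixed once and are not tuned against outcomes.

- **Glucose** is a stationary mean-reverting AR(1) on the 5-minute grid:
  mean 150 mg/dL, SD 40 mg/dL, coefficient 0.95 per step, clipped to
  [40, 400]. Newly diagnosed youth in remote-monitoring programs
  typically run means in the 140–160 mg/dL range with TIR near 60–75%;
  this parameterization lands there while the 0.95 coefficient gives the
  hour-scale autocorrelation real traces show. AR(1) is the simplest
  process with controllable mean/variance/autocorrelation; it does not
  model meals or insulin dynamics.
- **Bouts**: during a configured session the stochastic path is replaced
  by a deterministic linear decline at `drop_rate` mg/dL per 10 minutes
  from the glucose value at bout entry, resuming the AR process from the
  bout-end value. Deterministic declines mean configured drops are
  recovered *exactly* by the flag detector — the end-to-end recovery the
  acceptance suite relies on. The default schedule is one 60-minute
  after-school bout every other day, alternating walking
  (3.5 METs, 105 steps/min, 6 mg/dL per 10 min) and running (8 METs,
  160 steps/min, 10 mg/dL per 10 min) — magnitudes in the range reported
  for aerobic exercise in type 1 diabetes, with the running decline
  (60 mg/dL total) deliberately above the 50 mg/dL flag threshold and
  the walking decline (36 mg/dL) below it.
- **Heart rate** is one sample per minute: resting normal around 70 bpm
  (SD 4), elevated to 80 + 12 × METs during bouts. **Steps** outside
  bouts are Poisson (mean 4/min, ≈ 5 800 background steps/day);
  **METs** outside bouts are uniform on [1.0, 1.4], safely below the
  sedentary cutpoint so ground-truth MVPA equals bout-driven MVPA.
- **Gaps**: configured CGM-dropout and tracker-nonwear windows are cut
  from the emitted streams (tracker nonwear removes heart rate, steps
  and METs together) and recorded in the ground truth, so wear-time
  estimation and gap segmentation can be checked against the injected
  truth.
- **Determinism**: one master seed, split per channel by fixed offsets;
  identical configs produce byte-identical files.

The ground truth (per-bout drop and nadir, per-day steps and MVPA, gap
positions) is computed by independent plain loops over the emitted
minute vectors, not by the metric pipeline, so simulator-versus-pipeline
comparisons are genuine dual-route checks.

What the simulator does **not** emulate: meal and insulin excursions,
sensor noise and compression artifacts, irregular CGM cadence, heart-rate
driven exercise detection, non-step activities, timezone travel. Passing
tests therefore demonstrate the correctness of the computations under
controlled conditions, not clinical performance on real traces.

## Numerical and degenerate-input choices

- Periods and epochs are half-open; bout windows are closed (a sample at
  the session boundary is part of the exercise).
- Empty periods yield absent metrics (`NA`), never zeros; wear percent of
  an empty trace is 0 (wear is a coverage fraction, not a summary of
  values).
- The band partition holds exactly in rational arithmetic; the test
  tolerance of 1e-9 absorbs floating-point summation only.
- Interpolation uses the standard piecewise-linear routine with ordered
  ties; values never leave the bracketing samples' range.
- Review-table serialization rounds metrics to one decimal; the
  round-trip guarantee is stated at that precision.

## Problem sizes

The test suite simulates 1–14-day patients (288–4 032 CGM samples,
up to 20 160 minute records), runs 100-trace and 100-bout random
property sweeps, and completes in about 90 seconds on one CPU; the
acceptance sweeps are a few hundred small constructed traces and run in
seconds. These sizes were chosen to exercise every code path at
full-period scale while keeping the suite fast to iterate on.

## Known limitations

- Sample-count (not time) weighting of CGM percentages under irregular
  sampling.
- Wear estimation is blind to a worn-but-silent tracker (no heart-rate
  backfill handling).
- MVPA at epoch granularity under-counts activity that straddles epoch
  boundaries at sub-epoch duration.
- The ranking policy is a documented stand-in, not the published
  production algorithm.
- Cleaning's last-read-wins rule is order-dependent in the presence of
  conflicting same-timestamp records, which is unavoidable under a
  "latest supersedes" semantics without record sequence numbers.
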