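---
title: "The ctgdiag diagnostic engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ctgdiag diagnostic engine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgdiag)
```

## What the engine does

A cardiotocogram (CTG) pairs the fetal heart rate (FHR, beats per
minute) with the uterine contraction intensity (UC, relative units),
conventionally plotted at two points per second. Obstetricians read a
CTG by relating heart-rate excursions to contraction cycles: a
deceleration that reaches its nadir before the contraction completes is
*early*, one whose nadir trails the contraction end is *late*, and
abrupt V- or U-shaped drops are *variable* (type B when followed by a
brief "shoulder" acceleration above baseline). Sustained rates above
160 bpm or below 110 bpm for at least three minutes are *tachycardia*
and *bradycardia*.

`ctgdiag` mechanises that reading. The pipeline is

1. **clean** — invalidate physically implausible samples and sensor
   holds, bridge short gaps, split at long ones;
2. **smooth** — centered moving average on both channels;
3. **baselines** — the FHR baseline *B* and the UC resting tone, per
   10-minute window;
4. **key points** — contraction cycles (UCs, UCp, UCe), deceleration
   episodes (HRs, HRp, HRe), shoulders (HSp, HSe), sustained runs;
5. **rules** — six threshold rule sets, per-patient configurable via an
   XML profile;
6. **report** — a classed object with one alert per (episode, label),
   serialisable to JSON.

All detection operates on the smoothed channels; the raw trace is kept
by the caller. Times are seconds from trace start, sample *i* (1-based)
at *(i−1)/rate*; all threshold comparisons are inclusive, so boundary
geometries are label-positive.

## The rule sets

With `.t` a key-point time (s) and `.v` its value (bpm), `B` the local
baseline and defaults in parentheses:

| Label | Rules |
|---|---|
| Tachycardia | all samples ≥ 160 bpm for ≥ 180 s |
| Bradycardia | all samples ≤ 110 bpm for ≥ 180 s |
| Early deceleration | HRp.t < UCe.t; HRp.t − HRs.t ≥ 30 s; HRs.t ≥ UCs.t + 5 s; B − HRp.v ≥ 15 bpm |
| Late deceleration | HRp.t ≥ UCe.t; HRp.t − HRs.t ≥ 30 s; B − HRp.v ≥ 15 bpm |
| Variable, type A | HRp.t − HRs.t ≤ 30 s; HRs.t ≥ UCs.t + 5 s; B − HRp.v ≥ 15 bpm |
| Variable, type B | HRs.t ≥ UCs.t + 5 s; B − HRp.v ≥ 15 bpm; HSp.v − B ≥ 10 bpm; HSe.t − HRe.t ≥ 10 s |

The same symbol can enter one rule as a time and another as a value;
`ctgdiag` resolves this by making every key point an explicit `(t, v)`
pair and stating per rule which field is compared (the table above).

**Multi-label policy.** Every satisfied rule set is reported and
multi-label episodes are flagged `ambiguous`; no precedence is imposed.
This is not cosmetic: the type-B rule set contains no fall-time
constraint, so a V-shaped deceleration (fall ≤ 30 s) that satisfies
type B *necessarily* satisfies type A as well, and a type-B geometry
with a slower fall necessarily satisfies early or late (depending on
where its nadir sits relative to the contraction end). A single-label
type-B episode is impossible under the rule table as printed. The
synthetic recovery metric therefore counts a label *entailed* by the
injected geometry (type A alongside a V-shaped type B) as correct
rather than spurious.

## Preprocessing choices

* **Valid FHR range 50–240 bpm** (`fhr_valid_range`): outside readings
  are transducer artefacts, invalidated and treated like missing data.
* **Sensor holds**: a run of more than `dup_run_max = 10` samples (5 s
  at 2 Hz) repeating one exact value is a held reading *only if* it
  joins its neighbourhood through a jump of more than
  `hold_jump_bpm = 10` bpm (or borders missing data). A genuine flat
  rate joins continuously and is preserved; a frozen transducer jumps
  when the signal resumes. Without the jump condition every exactly
  constant stretch — including noiseless synthetic baselines — would be
  destroyed.
* **Gap bridging** (`max_gap_s = 15`): missing/invalid runs up to 15 s
  are linearly interpolated; longer runs stay missing and split the
  trace into independent analysis segments. Sustained runs never merge
  across segments, and cycles are detected per segment.
* **Smoothing** (`smooth_window_s = 5`): a centered moving average over
  `round(window · rate)` samples (forced odd), excluding missing
  samples from each window and leaving missing positions missing. A
  moving average was chosen over spline fitting because it is
  deterministic, order-free and exactly checkable against a brute-force
  oracle; 5 s suppresses beat-to-beat noise without flattening the
  shortest variable decelerations (≈ 16 s total width) beyond
  recognition.
* **FHR baseline** (`baseline_window_s = 600`): per 10-minute window,
  the median of smoothed samples between the window's 10th and 90th
  percentiles, rounded to 1 bpm. The trim discards deceleration nadirs
  and acceleration peaks, mimicking a clinician reading the level
  *between* excursions; the estimate is invariant (by test) to a single
  deceleration of depth ≥ 15 bpm occupying ≤ 10 % of the window.
  Windows shorter than 60 s, or without valid samples, reuse the
  nearest computed window.
* **UC resting tone**: the 10th percentile of the smoothed UC channel
  per window — the level the channel rests at between contractions.

## Key-point extraction

* **Contraction cycles**: a peak is a sample strictly higher than both
  neighbours (plateaus collapse to their earliest sample — the rule
  says nothing about ties, so the earliest sample is taken) rising at
  least `min_prominence = 10` units above tone; UCs/UCe are the nearest
  crossings of `tone + tol` (`tol = 2`). Overlapping candidates that
  share a crossing are split at the valley minimum between peaks.
* **Deceleration search**: forward from UCs, within a horizon ending
  `horizon_s = 60` s after UCe. The deepest excursion below the local
  baseline is the candidate; excursions shallower than
  `min_excursion_bpm = 2` are dismissed as jitter.
* **Nadir (HRp)**: the centre of the contiguous plateau of samples
  within `nadir_band_bpm = 2` of the minimum. On a noisy flat-bottomed
  deceleration the raw arg-min wanders several seconds; the plateau
  centre is steady and exact at zero noise.
* **Onset (HRs)**: the descending limb is modelled as a raised cosine,
  under which `acos(1 − 2·relative depth)` is linear in time. The limb
  samples between 15 % and 85 % of the measured depth (`onset_frac`)
  are fitted by least squares and the onset read off the baseline
  intercept. This replaces a naive backward walk from the nadir, which
  is ill-posed on a smoothed gentle onset (it lands about half a
  smoothing window early at zero noise) and unstable under noise
  (stopping at wiggles mid-limb). The fit is unbiased, uses the whole
  limb, and degrades gracefully: with fewer than three usable limb
  samples the 15 %-depth crossing itself is used.
* **Recovery (HRe)**: first return to within `return_tol = 5` bpm of
  the baseline after the nadir; an episode that never returns before
  the trace ends is not reported.
* **Shoulder**: the highest local maximum above baseline within
  `shoulder_search_s = 60` s after HRe, with HSe the first return to
  within `return_tol` of baseline after it.
* **Sustained runs**: sample-wise comparison against the thresholds
  (not window means — "the condition must last" is read literally),
  with run duration counted as `n/rate`.

None of `min_prominence`, `tol`, `return_tol`, the horizons, or the
onset/nadir localisation constants is clinical; they are engineering
constants pinned by the test suite and exposed in `ctg_config()`.

## The synthetic generator

`generate_ctg()` renders: contractions as raised-cosine bells over a
resting tone (default 5 units); decelerations as inverted raised
cosines of the stated depth whose fall lasts `fall_s` with a mirrored
recovery, anchored to the *analytic* cycle start/end (the bell's
crossings of `tone + tol`, which is what cycle detection localises);
shoulders as positive raised cosines appended at the recovery point;
sustained events as plateaus with 10-s raised-cosine ramps; then
additive Gaussian FHR noise and independent per-sample dropout on both
channels. Identical seeds give bit-identical output, and generation
does not disturb the caller's RNG stream.

Raised cosines were chosen because the qualitative shapes in the
clinical literature (bell-shaped contractions, U/V decelerations) carry
no dimensions; a raised cosine is smooth, fully parameterised by
depth/duration, and every ground-truth key point is known analytically.
V-shapes are realised by short fall times.

**Study conditions.** The recovery suite draws, per event class,
parameters uniform in ranges chosen once as clinically plausible and
rule-satisfying with honest margins (they are *not* tuned to the
detector): contraction bells 95–120 s long, 40–70 units high;
deceleration depths 20–45 bpm (variable: 20–40); early/late fall times
38–55 s, variable 8–20 s; onset lags 10–18 s; late nadirs 10–25 s after
the contraction end; shoulders 13–18 bpm for 15–20 s; tachycardia
165–180 bpm and bradycardia 85–100 bpm for 200–280 s. Deceleration
traces are 300 s with one contraction; sustained traces are 720 s with
two event-free decoy contractions placed clear of the plateau. The
noisy condition is 5-bpm Gaussian noise with 1 % dropout.

**What the generator does not emulate** — and hence what passing tests
do not certify on real data: beat-to-beat FHR variability and its
spectra, maternal heart-rate crosstalk, transducer displacement drift,
non-cosine deceleration morphologies, overlapping simultaneous events,
and real contraction irregularity. The suite demonstrates that the
engine implements its stated reading of the rules faithfully and
robustly at realistic noise, not that it attains any clinical
sensitivity.

## Numerical and degenerate-input behaviour

Ties in cycle peaks resolve to the earliest plateau sample; equal-depth
excursions resolve to the first minimum found. Traces with fewer than
two valid FHR samples, empty series, and windows with no valid samples
raise structured errors (the CLI maps them to exit code 2, I/O failures
to 3). Criteria files must be well-formed XML; absent thresholds fall
back to defaults with one warning each, non-positive thresholds are
errors naming the element. Report serialisation uses full-precision
JSON so reports round-trip exactly and repeated runs on identical
inputs are byte-identical.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use: 120 single-event traces
per recovery condition (20 per class; 300-s or 720-s traces at 2 Hz),
1,000 random 10-minute step traces for the sustained-run oracle, a
72-case truth-table grid for the rule engine, and 200 random traces for
the unit-level run-length comparison. These sizes give stable
percentages while keeping a full run under a minute on one core.

## Known limitations

* One deceleration per contraction cycle: the first qualifying fall is
  taken, so double dips within one cycle are reported once.
* Variable decelerations are only linked through contraction cycles, as
  the rule table requires, although clinically they may occur without
  one.
* The baseline estimator assumes excursions occupy well under half of
  each window; prolonged decelerations bias it.
* The type-B entailment described above means downstream consumers
  should treat the label set, not a single label, as the diagnosis.
* No variability indices, sinusoidal-pattern detection or acceleration
  scoring; severity grading and composite CTG scores are out of scope.
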