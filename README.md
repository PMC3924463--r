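# ctgdiag

Rule-based diagnostic engine for cardiotocography (CTG) traces: paired
fetal heart rate (FHR, bpm) and uterine contraction intensity (UC,
relative units) recordings, conventionally sampled at two points per
second.

The package is for engineers and researchers building or evaluating
automated fetal-monitoring pipelines. It cleans and smooths both
channels, estimates the FHR baseline *B* and the UC resting tone,
extracts the clinical key points of each contraction cycle and
deceleration episode, and classifies six abnormality patterns against
obstetrician-customisable thresholds loaded from a per-patient XML
profile. A seeded synthetic generator with analytic ground truth makes
the whole engine testable without clinical recordings.

## The model

Key points, each an explicit `(t, v)` pair: contraction start, peak and
end (UCs, UCp, UCe); deceleration fall start, nadir and recovery (HRs,
HRp, HRe); the optional post-deceleration "shoulder" acceleration (HSp,
HSe); and the baseline *B* (trimmed median per 10-minute window). The
rule sets, all comparisons inclusive:

* **Tachycardia** — FHR ≥ 160 bpm sustained ≥ 180 s.
* **Bradycardia** — FHR ≤ 110 bpm sustained ≥ 180 s.
* **Early deceleration** — HRp.t < UCe.t, HRp.t − HRs.t ≥ 30 s,
  HRs.t ≥ UCs.t + 5 s, B − HRp.v ≥ 15 bpm.
* **Late deceleration** — HRp.t ≥ UCe.t, HRp.t − HRs.t ≥ 30 s,
  B − HRp.v ≥ 15 bpm.
* **Variable deceleration, type A** — HRp.t − HRs.t ≤ 30 s,
  HRs.t ≥ UCs.t + 5 s, B − HRp.v ≥ 15 bpm.
* **Variable deceleration, type B** — HRs.t ≥ UCs.t + 5 s,
  B − HRp.v ≥ 15 bpm, HSp.v − B ≥ 10 bpm, HSe.t − HRe.t ≥ 10 s.

Every satisfied rule set is reported; multi-label episodes are flagged
ambiguous (see the methods vignette for why a V-shaped type-B episode
always also satisfies type A).

## Worked example

```r
library(ctgdiag)

spec <- synth_spec(
  duration_s = 300,
  uc = uc_bells(onset_s = 60, duration_s = 100, amplitude = 60),
  events = list(ev_early_decel(1, depth_bpm = 45, fall_s = 45, lag_s = 10)),
  noise_sd_bpm = 2, dropout_prob = 0.005, seed = 42
)
sim <- generate_ctg(spec)          # trace + analytic ground truth
dx  <- ctg_diagnose(sim$trace, ctg_criteria(patient = "demo"))
dx
#> CTG diagnosis for 'synthetic' (patient 'demo')
#>   1 deceleration episode(s), 0 sustained-rate episode(s), 1 alert(s)
#>   alert: EarlyDeceleration      at   121.0 s  [decel-1]
summary(dx)
#> CTG diagnosis for 'synthetic'
#>   baseline windows: 140 bpm; UC tone: 5 units
#>   decel-1: HRs 75.7 s, HRp 121.0 s (95.4 bpm), HRe 157.0 s, B 140 -> EarlyDeceleration
```

The injected deceleration starts 10 s after the contraction onset,
falls 45 bpm over 45 s and reaches its nadir before the contraction
ends; the engine recovers HRs at 75.7 s against an analytic onset of
75.8 s, measures a 45.3-s fall and a 44.6-bpm depth against baseline
140, and the rule sets label it an early deceleration — late fails
because the nadir precedes the contraction end, type A because the fall
exceeds 30 s, type B because there is no shoulder. `write_ctg_report()`
serialises the result (JSON schema in `inst/extdata/`), and
`emit_alerts()` hands each (episode, label) alert to a consumer exactly
once, in time order.

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ctg.R", package = "ctgdiag"))')" \
  diagnose --trace tr.csv --criteria crit.xml --out report.json
```

with subcommands `diagnose`, `simulate` and `validate-criteria`, and
exit codes 0 (ok), 1 (usage), 2 (degenerate input), 3 (I/O).

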