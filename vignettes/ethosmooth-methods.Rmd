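---
title: "Methods: smoothing and evaluating nocturnal behavior timelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothing and evaluating nocturnal behavior timelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethosmooth)
```

## The model

A recording night (by default 14 h at 1 fps) is divided into consecutive
7-second intervals, each carrying exactly one ethogram state: `standing`,
`lhu` (lying, head up), `lhd` (lying, head rested — the postural indicator
of REM sleep, since postural atonia forces the head down) or `absent`.
The label order `standing < lhu < lhd < absent` is fixed and used for
serialization and tie-breaking. A *phase* is a maximal run of one state;
per-night **phase counts** and **total durations** per state are the
quantities behavioral studies report, typically as mean ± SEM across nights.

The prediction pipeline this package post-processes works in three stages:
a per-frame object detector (localizes the animal, or declares the frame
empty), two interval-level classifiers (a single-frame stream whose outputs
are averaged over the interval, and a multiframe stream fed a 2×2 mosaic of
four cut-outs), and the temporal logic implemented here: stream fusion,
rolling average, absence injection, argmax decision, and transition-rule
smoothing.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `interval_s` | 7 | seconds | annotation granularity of the source data; 7 frames at 1 fps |
| `conf_threshold` | 0.97 | fraction | detector boxes below 97% confidence are discarded; at most one box per frame |
| `cutout_px` / `tile_px` | 300 / 150 | pixels | stream-1 input side; mosaic tile side (2×150 = 300 keeps both streams' input sizes equal) |
| `encoding_frame_offsets` | 0, 2, 4, 6 | frame offsets | which 4 of the 7 frames feed the mosaic (see "Open design points") |
| `window` | 3 | intervals | centered rolling-average width; must be odd |
| `max_passes` | 50 | passes | rule-engine fixpoint cap; `1` gives the single literal detect-and-replace sweep |
| rule minima | 3–50 | intervals | see `default_rules()`; 3 intervals = 21 s, 50 intervals = 350 s |

## The rule engine, precisely

A rule *(prev-set, current, next-set, m)* targets interior phases only: a
phase with no previous or next neighbor (night boundary) is never replaced,
because the pattern requires both flanks. The replacement target is always
the *previous* phase's label, even when the next-set matched a different
label.

One **pass** scans the phase segmentation left to right; at each interior
phase the rules are tried in list order, and on a match the phase is
relabeled, the segmentation re-merged immediately, and the scan resumes at
the phase following the merged block. Since a replacement can merge two
long phases across a removed short one and thereby expose a new short phase,
passes repeat until one changes nothing. Every replacement reduces the
number of phases by at least one, so termination is structural; the
`max_passes` cap merely bounds worst cases, and a warning is raised if
patterns remain when it is hit. Rule order within a pass follows the
configured list (the printed table order for the defaults); order is part of
the configuration because species-specific rule sets are expected to be
adapted.

The engine is validated against an independent naive reference that mutates
the raw label array with explicit index walking (no run-length encoding) —
the two agree on 10⁵ random sequences of length ≤ 12, and the output is
always a fixpoint.

## Fusion, rolling average and absence

`fuse_streams()` is the component-wise arithmetic mean of two normalized
vectors — means of probability vectors stay normalized. `rolling_average()`
uses a centered window, truncated (not padded) at the boundaries: the first
element with window 3 averages elements 1–2 only. Truncation was chosen over
padding because padding with copies of the boundary value biases toward the
night's first/last prediction, and the upstream description does not
prescribe either. `inject_absence()` converts the detector's evidence into
probability mass: with detected fraction *f* over the interval's 7 frames,
P(absent) = 1 − *f* and the behavior components are scaled by *f*.
`decide()` is the argmax with ties broken by the fixed label order.

When streams are 3-state behavior vectors with gaps (intervals where nothing
was detected), fusion falls back to whichever stream is defined, the rolling
window averages only the defined rows it covers, and absence injection then
fills the gaps — an interval with no detections always decides `absent`
regardless of its neighbors' behavior probabilities. When streams already
carry 4-state vectors (as the synthetic noise model produces), injection is
skipped.

## The synthetic world

`simulate_night()` draws alternating phases: the label sequence is a Markov
chain without self-transitions; phase lengths are gamma-distributed
(shape 2 by default — right-skewed bout lengths, as resting bouts are) with
per-state means, rounded to ≥ 1 interval and truncated so the night is
exactly full (7,200 intervals at the defaults). Transition weights default
to the target phase frequencies replicated per row; for that choice the
embedded chain's stationary distribution *equals* those frequencies, so
expected phase counts scale directly with the configured values. Defaults
are calibrated to a typical common-eland night: ≈ 8 standing phases
(≈ 195 min), ≈ 17 lhu phases (≈ 590 min), ≈ 9 lhd phases (≈ 50 min), a
couple of brief absences.

`corrupt_predictions()` emulates the classifier ensemble with (i)
independent per-interval confusion flips (default symmetric, 5%), (ii)
contiguous *bursts* (start probability 0.01 per interval, geometric length
with mean 3) overwriting a run with one wrong label — stretches of occlusion
or truncation, and (iii) probability vectors drawn from a Dirichlet
concentrated on the possibly-corrupted label (concentration 20). The two
streams are conditionally independent corruptions of the same truth; real
stream errors are correlated, which would make fusion *less* effective, so
independence is the conservative setting for testing that fusion helps.

What a green simulation test does **not** establish: real nights have
enclosure- and individual-specific error structure (systematic confusions in
particular corners, lighting drift, label ambiguity near transitions), and
real stream errors are correlated. The simulator exposes knobs rather than
claiming realism; quantitative agreement with any particular animal's
published figures is not claimed anywhere in the test suite.

`render_frames()` draws toy night-vision frames (textured background, one
bright articulated silhouette whose shape depends on the state, tight
ground-truth boxes) purely to exercise the detection/cut-out/mosaic
geometry; no one should train a network on them.

## Numerical choices

* Probability rows must sum to 1 within 1e−9; fusion/rolling preserve this
  to ~1e−12 even over 7,200-interval nights.
* Boxes are 0-based half-open pixel rectangles; COCO `[x, y, w, h]` is
  converted on read. IoU of boxes touching only at an edge is 0.
* The AP@t denominator counts predicted boxes only; a prediction on a
  truth-less frame scores IoU 0, and frames absent in both inputs (correct
  rejections) are excluded from the ratio but counted separately.
* `cutout()` clips the box to the frame, then resizes; aspect ratio is not
  preserved (the network input is a fixed square, and no padding scheme is
  prescribed). Resampling is bilinear, the common default.
* Augmentation order is crop → flip → blur → brightness/contrast → rotation;
  brightness/contrast jitter is ±20% and blur σ ∈ [0, 1.5] (no ranges are
  prescribed upstream; both are configurable), crop 0–16 px and rotation
  ±25° are fixed by the recipe. All draws come from a seeded private RNG
  stream that leaves the caller's `.Random.seed` untouched.
* Images travel as plain-text PGM (P2) by default so all fixtures remain
  text; PNG is optional via the `png` package.

## Open design points and how they were decided

* **Which 4 of 7 frames** feed the mosaic, and the tile order, are not
  specified by the upstream description: offsets {0, 2, 4, 6} (even spacing,
  endpoints included — maximal temporal coverage) and row-major order were
  chosen and recorded in the configuration, so inputs stay compatible with
  whatever a trained model expects.
* **Stream-1 accumulation** is the unweighted mean over detected frames;
  only "accumulate" is prescribed.
* **Incomplete trailing intervals** are dropped (fixed-length contract);
  whether the source pipelines keep them is unknowable from the description.
* **Rolling-average details** (window length, weights) are not published;
  a centered, truncated, unweighted window of 3 is the default and
  configurable.
* **Binary task and absent**: `binary_accuracy()` keeps absent as a third
  outcome by default (this preserves the guarantee binary ≥ multiclass
  accuracy, since collapsing lhu/lhd can only convert errors into
  agreements); `drop_absent = TRUE` scores the pure standing-vs-lying
  decision instead.
* **Undefined metrics** (a class never predicted, or never true) are
  reported as `NA` with a `defined = FALSE` flag rather than zeroed, so
  macro-averages cannot be silently biased.
* **Accuracy with/without absent**: both modes exist
  (`accuracy(include_absent = )`); reported multiclass tables conventionally
  cover the three behavior classes.

## Known limitations

* The rule engine's guarantee is about *patterns*: a short phase whose
  neighbors do not match any rule's sets legitimately survives; and rule 6
  (absent, minimum 50 intervals ≈ 6 min) deliberately erases real absences
  shorter than that — visible in the worked example in the README.
* Phase counts after smoothing are still biased upward under heavy noise:
  bursts longer than a rule's minimum are kept by design.
* Only one individual per enclosure is supported (`filter_detections()`
  keeps one box); multi-animal tracking is out of scope.
* No learned temporal model: smoothing is purely rule-based, which is the
  point — rules are auditable and species-adjustable — but means the engine
  cannot exploit, e.g., time-of-night priors.
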