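---
title: "Hierarchical smoking detection from wrist accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical smoking detection from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffdetect)
```

## The problem

A cigarette is smoked as a sequence of stereotyped hand-to-mouth
gestures. On the wrist of the smoking hand, each puff appears in a
triaxial accelerometer as a slow (~1 Hz and below) rotation of the
gravity vector through the sensor frame: the watch face starts up
(z ≈ +9.81 m/s²), the wrist turns toward the mouth (y takes up much of
gravity), holds for the inhale, and returns. `puffdetect` detects
smoking *sessions* — whole cigarettes — in such recordings, and
evaluates the detections against participant self-report logs, which
are themselves imperfect.

Detection is hierarchical. A neural network makes a local, per-window
judgment — "does this 5 seconds look like a puff gesture?" — and a
rule-based layer above it imposes the temporal grammar of smoking:
puffs have a minimum duration, rests between puffs have bounds, and a
session needs several puffs within a bounded span. The division of
labour matters: isolated puff-like gestures (a yawn, scratching the
nose, one sip of a drink) can fool any window classifier, but they
cannot satisfy the session grammar.

## Preprocessing

Traces are nominally uniform at `fs` (20 Hz by default). Gaps in the
timestamps are *reported*, never interpolated — in field data, dropped
transmission spans are grounds for exclusion, and resampling would
manufacture signal where there is none.

Each axis is smoothed with a 4th-order Butterworth low-pass applied
forward and backward (zero phase, so gesture timing is not shifted).
The cutoff defaults to 5 Hz: puff gestures live well below 1 Hz, while
walking and hand jitter contribute mostly above; 5 Hz removes the
jitter without rounding off gesture edges. The filter family, order and
cutoff are package choices — the qualitative goal (suppress
high-frequency motion noise before windowing) admits many
implementations, and all three are configurable. Zero-phase filtering
is wrapped with odd-reflection end padding long enough for the filter
transient to settle, so constants (gravity) pass exactly and edges show
no startup artefact.

Windows are cut with a rolling window of 5 s advanced by a configurable
stride (default 1 sample), each flattened axis-major into
`3 × window_samples` features — 300 at the defaults, matching the
network's input layer. The axis-major layout is a package convention;
only the total feature count is structurally meaningful.

## The gesture network

The classifier is a 300–10–1 feed-forward network with logistic sigmoid
activations on both layers, so the output is directly a probability.
Training minimises L2-regularised cross-entropy (penalty `1e-4`) by
full-batch L-BFGS from a small seeded uniform initialisation
(`±sqrt(6/(fan_in + fan_out))`). Everything random — the stratified
20% holdout split and the initial weights — derives from the `seed`
argument, so a fit is exactly reproducible. Features are standardised
per axis (pooled mean and sd of the x, y and z blocks, estimated on the
training split and stored in the model): raw magnitudes differ strongly
with gravity orientation, and per-axis pooling preserves the within-axis
shape that distinguishes gestures.

Held-out accuracy is computed per window at a 0.5 decision point, the
natural accuracy metric for a balanced corpus. Stream classification
instead uses a deliberately conservative threshold of 0.85: scores are
computed for every stride-1 window, each decision is attributed to the
window's **centre** sample, and edge samples inherit the nearest valid
window's decision. Centre attribution is the least biased choice — a
window's evidence is symmetric about its middle — and the residual
blurring (a detected puff widens by up to ~2 s per side) is harmless
because gesture edges are brief relative to the gesture and the rule
layer works on durations much longer than the blur.

## The rule layer

Five parameters define the session model (`session_params()` defaults):

| parameter | default | meaning |
|---|---|---|
| `min_puff_s` | 0.75 s | a puff must last longer than this |
| `min_gap_s` | 2.5 s | runs separated by less are one split puff |
| `max_gap_s` | 240 s | a longer rest separates sessions |
| `min_puffs` | 3 | fewer puffs is not a session |
| `max_session_s` | 480 s | longer chains are split (chain-smoking) |

`stream_to_puffs()` merges **before** filtering by duration: a rest
below `min_gap_s` means the classifier split one puff, so the fragments
are reunited before their combined length is judged. The merge is a
single left-to-right pass — extending a puff rightward never changes
its gap to the next candidate, so one pass is already stable, and the
operation is idempotent.

`puffs_to_sessions()` first splits chains at rests exceeding
`max_gap_s`, then walks each chain greedily, starting a new session at
the first puff whose end would push the span past `max_session_s` —
a deterministic single-pass reading of "an over-long sequence counts as
two sessions". The minimum-puff-count filter is applied last, so a
short orphan group created by a duration split is discarded: the
duration rule has precedence. Session spans are measured from the first
puff's start to the last puff's end (no trailing rest). Boundary
conventions: merging uses a strict `<` on the rest, chain splitting a
strict `>`, the duration filter a strict `>` on `min_puff_s`, and a
group is closed only when the span strictly exceeds `max_session_s`.
Emitted sessions therefore satisfy closed-interval invariants (rests in
`[min_gap_s, max_gap_s]`, span `≤ max_session_s`). Whether merging
should chain across three near-adjacent runs in one pass is not
prescribed by the model; the left-to-right accumulation used here does
chain, which is the reading consistent with "one incorrectly split
puff", and the brute-force reference in the test suite encodes the same
choice independently.

## Evaluation

Self-report entries missing one bound get an 8-minute window imputed on
the reported side (`impute_bounds()`), the same 8 minutes as the
session cap. Matching is greedy, earliest-first and one-to-one: walking
reports in time order, each consumes the earliest unconsumed detection
that overlaps it by any positive amount. No overlap tolerance is
imposed because the reference intervals are already inflated by the
reporting process itself. One-to-one matching means two detections
inside one report yield one true positive and one false positive —
the reference cannot corroborate more sessions than it contains.

Two false-positive denominators are provided. The contiguous count,
`nonsmoking_windows()`, is `floor(total minutes / window) − reported`
(777 for a 120-hour study with 123 reports; 80 for a 12-hour day with
10 cigarettes). The rolling count, `rolling_window_count()`, is the
number of window placements in a sampled record; the default
`"exclusive"` convention counts `N − W` (854,400 eight-minute windows
in 12 hours at 20 Hz), with `N − W + 1` available as `"inclusive"` —
the two differ by one placement and the exclusive form matches the
standard worked example.

Progressive exclusion accounting (`tpr_exclusion_table()`,
`fpr_exclusion_table()`) recomputes rates as inspection-established
discrepancy categories are removed: false-negative categories
(`no_smoking`, `improper_use`, `abnormal_gesture`,
`true_false_negative`) shrink the reported-session denominator;
`clearly_smoking` removes false positives *and* their windows from the
FPR denominator (777 → 771 when 6 are excluded). Assigning sessions to
categories is the analyst's judgment; the package provides only the
arithmetic.

Rounding follows the conventions in which such tables are printed:
whole-percent TPR values are truncated (100/121 prints as 82, 88/123
as 71), while one-decimal FPR values are rounded half-up (16/771 →
2.1%). Raw fractions are always retained alongside.

## The synthetic generator

`sim_config()` fixes the study conditions: 20 Hz sampling; a puff as a
1.0 s raise, 1.5 s hold, 1.0 s lower (smooth-step interpolated gravity
rotation of ~70°, magnitude exactly 9.81 m/s² before noise) with 10%
multiplicative timing jitter; 5–13 puffs per session; rests drawn from
20–90 s; Gaussian sensor noise of 0.3 m/s² per axis; self-report bounds
inflated by Uniform[0, 180] s at each end, reflecting that logged
sessions run minutes longer than observed ones. Log error modes default
to field-calibrated rates: ~22% of entries missing one bound, ~5%
unreported, ~2% phantom.

Two design points deserve a note:

* **Session-duration cap.** Rests drawn independently from 20–90 s can
  produce a 13-puff session far exceeding the 8-minute session model,
  which would make the generator's own ground truth violate the rules
  it is meant to exercise. When a draw would exceed 460 s, the rests
  are rescaled proportionally to fit; the worst-case rescaled rest
  (~7.6 s) remains far above the 2.5 s merge bound, so every generated
  session satisfies the full session model with margin for the
  classifier's edge widening. The 460 s cap (vs 480) is exactly that
  margin.
* **Confounders as caricatures.** Eating is frequent short raises with
  rests mostly below 2.5 s; drinking is sparse raises with a longer
  hold and the wrist rotating the other way (x-dominant tilt); walking
  is ~2 Hz oscillation plus high-frequency jitter; typing is
  low-amplitude jitter face-up; tying shoes is a single slow bend.
  These are parameterised conventions constrained by qualitative
  morphology, not biomechanical fits — no quantitative amplitudes for
  these gestures are published. Their obligations are only that (a) a
  small MLP can separate puffs from them and (b) their timing
  structure exercises the rule layer (eating merges into long
  non-sessions, a drink or a bend is an isolated gesture that the
  minimum-puff-count rule discards).

The training corpus generator applies the same low-pass filter as the
detector, labels each window by its centre sample against the
ground-truth puff intervals, and balances positives against negatives
drawn ~40% from within-session rests and ~60% from confounders —
event-sparse confounders (a bend, a drink) are generated as many short
segments so their events are well represented among negatives.

What the simulation does **not** emulate: inter-person variability in
gesture amplitude and speed, watch-orientation violations (wrong wrist,
supinated wear), postural context (smoking while lying down), sensor
drift and dropped-sample gaps, and chain-smoking beyond what the
8-minute split handles. A classifier achieving near-perfect held-out
accuracy here shows the pipeline is correct and the architecture
adequate for the task's geometry — not that field accuracy would be
this high. Field performance on real recordings is reported to be
materially lower, which is consistent with these idealisations.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 10,000-window balanced
corpus (stratified 20% holdout) for the classifier property, 1,000
random streams of up to 2,000 samples for rule-layer/brute-force
equivalence, 500 simulated sessions for exact parameter recovery, and
ten simulated one-hour recordings with one or two sessions each plus
confounders and default log errors for the end-to-end property (TPR
against ground truth ≥ 0.9, false sessions ≤ 0.25/h). These sizes give
stable statistics while a full run stays comfortably interactive.
L-BFGS runs up to 400 iterations with `factr = 1e7`; scores are clamped
to `[1e-12, 1 − 1e-12]` inside the loss; stream scoring is chunked
(20,000 windows at a time) so arbitrarily long recordings never
materialise the full window matrix.

## Known limitations

* The rule parameters are population-level; abnormally quick smokers
  (puffs near 0.75 s) can fall below the duration rule. Per-person
  calibration of `min_puff_s` is the natural extension.
* Orientation correction is out of scope: the detector assumes the
  watch is worn on the smoking hand, face up. Improper wear must be
  excluded (or corrected upstream) before detection.
* The evaluation's matching is interval-overlap only; it does not
  compare puff counts between detection and report, although both are
  carried through for inspection.
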