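---
title: "Methods: hierarchical fall detection with a multiphase fall model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical fall detection with a multiphase fall model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `phasefall`, its
assumptions, the conventions and numerical choices the implementation had
to fix, and what the synthetic generator does and does not demonstrate.

## The detection model

A recording is a tri-axial acceleration series in g at a fixed sampling
rate (default 128 Hz; the algorithm operates on sample indices, so
timestamps are optional on disk and regenerated as `i / sample_rate`).
Detection proceeds in four steps.

**Windowing.** The per-sample Euclidean norm
$\lVert a\rVert=\sqrt{a_x^2+a_y^2+a_z^2}$ attains its maximum at the
*critical point* — for a fall, the impact. One classification frame of
513 samples is cut per record: 192 samples (1.5 s) before the critical
point, the critical point, and 320 samples (2.5 s) after it. This
asymmetry reflects the physics: the informative pre-impact interval
(free fall) is short, while the post-impact interval must be long enough
to observe whether the subject comes to rest. One frame per record is an
assumption — the package classifies episodes, not a continuous stream.

**Threshold triage.** Frame extrema $v=\max\lVert a\rVert$ and
$w=\max\lVert(a_y,a_z)\rVert$ feed a four-threshold rule. The fall
thresholds are the maxima of $v$ and $w$ over training ADL frames; the
ADL thresholds are the minima over training fall frames. Strictly above
both fall thresholds ⇒ Fall; strictly below both ADL thresholds ⇒ ADL;
otherwise the frame is *unidentified*. By construction no training frame
can be triaged into the wrong class; the rule's whole purpose is to
resolve cheaply what can be resolved and defer the ambiguous band.

**Multiphase segmentation and phase classification.** An unidentified
frame is partitioned into free fall / impact / rest. The impact window is
21 samples centred on the critical point for severe impacts (peak > 6 g)
and 31 samples (10 + critical + 20) for mild ones — mild impacts settle
more slowly, so the window extends further right. Free fall is the 32
samples immediately before the impact; rest is everything after it. Each
phase yields 54 time-domain statistics which a one-vs-one linear SVM
labels as FreeFall, Impact or Rest.

**Temporal-order rule.** The frame is a fall iff the three predicted
labels are exactly (FreeFall, Impact, Rest) — 1 admissible sequence of
the $3^3 = 27$ possible. This rule, not the SVM alone, carries the
rejection of ambiguous ADLs: a fast lie-down may produce an impact-like
window, but its pre-impact window does not look like free fall *and* its
post-impact window rarely looks like motionless rest in exactly the
right order.

## Parameters and conventions

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sample_rate` | 128 | Hz | fast enough that a sub-second impact is well resolved |
| window | 192 + 1 + 320 | samples | 1.5 s look-back / 2.5 s look-ahead at 128 Hz |
| `severe_peak_g` | 6 | g | severity boundary for the impact-window length |
| impact window | 21 / 31 | samples | severe / mild impact duration |
| free-fall window | 32 | samples | 0.25 s pre-impact interval |
| `cost` | 1.0 | — | SVM margin penalty; no basis for another value, config-exposed |
| `sd_denom`, `var_denom` | n−1 | — | sample estimators; switchable to n |
| `skew_form` | g1 | — | standardized third central moment; `G1` bias-adjusted variant |
| `kurt_form` | pearson | — | standardized fourth central moment (normal ≈ 3); `excess` subtracts 3 |
| `vert_pair` | (a_x, a_y) | — | coronal-plane axis pair, see below |
| `pad_policy` | replicate | — | boundary handling for short records |

Decisions the implementation had to make where the procedure is
underdetermined:

* **Peak exactly 6 g** is assigned to the severe branch: a peak at a
  ±6 g sensor's range limit indicates saturation, i.e. a severe impact.
* **Threshold boundaries are strict**: a frame sitting exactly on a
  threshold is deferred to the knowledge stage rather than classified —
  the conservative direction. When the classes separate cleanly the
  unidentified band may be empty and a frame in the gap satisfies the
  Fall branch first; the branches are evaluated in Fall, ADL order.
* **Critical-point ties** break to the earliest index (deterministic and
  order-stable).
* **Coronal plane.** Only the horizontal plane is fixed by the norm
  definition as $(a_y,a_z)$; with $a_x$ vertical, either remaining pair
  can be read as coronal. The default is $(a_x,a_y)$, configurable via
  `vert_pair`, and the choice is bundled with the fitted model so
  features are always computed under the fit-time convention.
* **Degenerate statistics.** Correlation, skewness and kurtosis of a
  (numerically) constant signal are defined as 0 — rest phases can be
  nearly constant, and the classifier needs finite features. Variance
  guards use a 1e-300 floor on the second central moment; the CSV
  round-trip is exact to better than 1e-12 g (`%.17g` formatting).
* **Feature standardization.** Features are z-scored with a scaler fit
  on the training phase features (constant features pass through with
  scale 1). A linear margin machine on features whose natural scales
  differ by orders of magnitude (variance vs kurtosis) is dominated by
  the large-scale features without it. The scaler is a stored model
  component, not hidden inside the SVM.
* **Phase-classifier training uses fall frames only** (three classes,
  one 54-vector per phase per fall). ADL rejection is delegated entirely
  to the temporal-order rule; no ADL phase labels exist to train on.
* **One-vs-one voting ties** are resolved by libsvm's internal rule
  (first class encountered), equivalent to a lowest-class-index
  tie-break; ties are measure-zero with continuous features.
* **Undefined metrics** (zero denominator) are reported `NA` and
  excluded from cross-validation means rather than coerced to 0, which
  would silently bias small folds.
* **Cross-validation is stratified** (class proportions preserved per
  fold) and re-draws a partition that would leave a training split
  single-class; each record is tested exactly once per round.

## What the simulator emulates — and what it does not

The generator produces the signal *statistics* of each archetype, not
body kinematics:

* **Falls**: pre-fall activity (2 s, so the look-back window needs no
  padding), a free-fall interval whose norm decays below 0.5 g with
  duration drawn from 0.12–0.8 s (the range reported for instrumented
  falls), a half-sine impact pulse with peak drawn from 3–8 g —
  deliberately straddling both the 6 g severity boundary and the learned
  threshold band, so the knowledge stage is genuinely exercised — a
  damped settling oscillation, and rest at 1 g in a lying orientation.
* **ADLs**: ~2 Hz gait for walking/stairs; single moderate transients
  for sit/stand; a lying transition with a 1.5–3 g bump for the fast
  lie-down (the deliberately fall-like, hardest ADL); rhythmic jumping
  as repeated takeoff-push / flight-dip / landing-spike cycles with a
  fatigue taper, so the loudest landing occurs mid-bout and movement
  continues through its look-ahead window — a jumper does not freeze
  motionless after landing, and it is precisely the non-rest rest window
  that lets the temporal-order rule reject jumping.
* Gaussian sensor noise (default SD 0.05 g) throughout; bit-exact
  reproducibility under a fixed seed without disturbing the caller's RNG
  stream.

Passing tests on this data shows the pipeline is implemented correctly
and that the hierarchy resolves the engineered ambiguity; it does not
show clinical performance. Real signals contain soft-tissue artefacts,
sensor drift, orientation changes during ordinary movement, and fall
types with no clean free-fall signature — none of which are modelled.

## Problem sizes and numerical tolerances

The test suite checks the 54 features against an independent
direct-formula oracle on 1000 random segments at 1e-9 absolute
tolerance; structural constants (513/192/320/21/31/32, feature length
54) exactly; and end-to-end recovery at ≥ 95% sensitivity and
specificity on 220 generated records (110 falls, 110 ADLs) under 5-fold
cross-validation — sizes chosen to exercise every archetype several
times per fold while keeping the full suite in tens of seconds. The
acceptance script uses the same 220-record design with 5 folds × 5
rounds. Across generator seeds, cross-validated sensitivity typically
falls in 99–100% and specificity in 96–100%.

## Known limitations

* Episode classifier, not a continuous monitor: one frame per record,
  no sliding-window detection.
* Only the three core phases are modelled; pre-fall and recovery phases
  (and with them alarm-severity grading) are out of scope.
* Thresholds are extremal statistics and thus sensitive to single
  outlier training frames; they are fit per training split, never
  personalised per subject.
* The linear kernel and `cost = 1` are sensible defaults for z-scored
  time-domain features, not the result of a hyperparameter search.
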