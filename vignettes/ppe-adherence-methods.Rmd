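---
title: "Methods: pose-landmark PPE adherence monitoring and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-landmark PPE adherence monitoring and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppemonitor)
```

`ppemonitor` implements a camera-based monitor of personal protective
equipment (PPE) adherence — mask, gloves, gown — together with the
statistical protocol used to evaluate such a monitor. This vignette is the
package's own account of the method: the model, its assumptions, the
parameters that matter, the synthetic test surface, and the numerical and
design choices made where the design was genuinely open.

## The pipeline model

Each frame passes through three stages.

**Pose to regions.** A pose provider returns 17 COCO-style anatomical
keypoints with per-point confidences. Three geometric rules convert
landmarks to square, axis-aligned regions of interest:

* *Face*: centred on the nose; the measurement scale is the mean Euclidean
  distance from each ear to the nose; the half-side is `face_coeff = 1.2`
  times that scale.
* *Palm*: the measurement scale is the elbow-to-wrist distance; the centre
  is extrapolated `palm_offset_coeff = 0.5` scales beyond the wrist along
  the forearm direction; the full side is `palm_side_coeff = 1.6` scales.
* *Torso*: centred on the centroid of both shoulders and both hips; the
  half-side is `torso_coeff = 0.83` times the distance from the centroid to
  the furthest of the four landmarks.

The coefficients are empirical constants of the original system. The
published rules do not state whether the face and torso factors are
half-sides or full sides; we adopt *half-side* for face and torso (a 1.2×
ear–nose *full* side would not contain a face) and *full-side* for the palm
(where the factor is described as the crop's dimensions and 1.6 forearm
lengths plausibly spans a hand). Both readings are reproducible: the
convention is a per-region field of `geometry_config()`.

All three rules are equivariant under translation, uniform scaling and
left/right mirroring of the landmarks — the property suite checks this on a
thousand random skeletons — and all degenerate geometry (coincident
landmarks, zero scales) yields a *region-not-visible* signal rather than an
error, because a live frame loop must never crash on a bad pose.

**Visibility.** A region is assessed only when its defining landmarks pass
a confidence threshold (default 0.3; the original protocol cleaned its data
manually, so the threshold is our choice and is configurable) and, for
palms, the wrist lies inside the frame. The nose-confidence requirement
doubles as a back-of-head proxy. Crop windows that extend past the frame
edge are zero-padded rather than clamped, keeping the region geometrically
centred for the classifier; the fraction of the window inside the frame is
reported. Resampling to the 224×224 network input uses nearest-neighbour
indexing, so an in-bounds window resampled at its own size reproduces the
source pixels exactly — a property the tests rely on.

**Classification.** Each crop is mapped to a feature vector of length
`F = 712` and classified by a head of the form
dropout(0.2) → dense(712) → ReLU → dense(1) → sigmoid. The published
architecture sentence does not spell out the scalar output layer; a single
probability requires one, so the 712 → 1 map before the sigmoid is our
documented interpretation. Training follows the stated protocol: 10 epochs
of Adam (standard hyperparameters: learning rate 1e-3, β₁ = 0.9,
β₂ = 0.999) on binary cross-entropy, a seeded 20 % validation split, and
inverted input dropout active only in training. Mini-batch size 32 (not
stated in the protocol; recorded in run metadata). The decision threshold
is 0.5 and configurable. Training is bit-reproducible given the seed.

The feature extractor is pluggable. The default is a deterministic seeded
Gaussian random projection of the block-mean-pooled (14×14×3),
per-image-standardised crop. It preserves the head's training contract
(fixed-length deterministic features) at desk scale; an adapter slot
(`custom_feature_extractor()`) accepts any image-to-vector function, and
the head adapts to its output dimension. The printed feature width 712
does not match common published backbone widths, so `F` is treated as a
configurable default rather than a constraint.

**Aggregation.** The gloves item is adherent only if *every visible palm*
is predicted gloved; a single visible palm decides alone. This matches the
treatment of mixed gloving (one gloved, one bare hand) as a failure mode:
it must not read as adherent. Frame correctness has two definitions: *no
misclassified regions* (every visible region correct) and the relaxed *no
misclassified mask or gown* (face and torso only), which isolates the
impact of the weakest model, the glove classifier. Both are computed over
visible regions only. At frame level the strict definition can never beat
the least-performing region model; the tests assert this bound on every
run.

Event-level verdicts (majority vote per item over 1:5-sampled frames, ties
non-adherent) are an aggregation layer we add on top of the frame-level
statistics, which are the primary output; the published evaluation is
frame-level. Frame sampling keeps indices 0, 5, 10, … — the published
protocol states only the 1:5 ratio, the phase is our choice.

## Evaluation statistics

All statistics operate on 2×2 tables with ground truth on rows and
prediction on columns (`a` = TP, `b` = FN, `c` = FP, `d` = TN):

* accuracy `(a+d)/n`;
* Cohen's kappa `(p_o − p_e)/(1 − p_e)` with marginal-product chance
  agreement; degenerate marginals (`p_e = 1`) return `NA` with a warning;
* McNemar `(b−c)²/(b+c)` **without** continuity correction;
* Pearson chi-square `n(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` **without** Yates
  correction, for correctness-by-confounder tables;
* p-values as the upper tail of the chi-square distribution with 1 df
  (`stats::pchisq`; the acceptance suite verifies it against a numeric
  integration oracle to 1e-6);
* the Wald margin `z√(p(1−p)/n)` and planning sample size
  `⌈z²p(1−p)/h²⌉` (Wilson intervals available behind a flag).

The uncorrected variants are deliberate: they are the exact forms that
reproduce the published statistics from the published counts (e.g. the
McNemar value 24.67 = 74²/222 for the training mask model); corrected
variants sit behind `correct`/`yates` flags. p-values are reported to
three decimals with `"<0.001"` below that.

One fixture deserves a note: in the published confounder table, the height
column's totals (7068) disagree with every other column's (7124), and the
printed height chi-square (46.51) does not recompute from the printed
height counts (we obtain 46.40). The package reports the recomputed value
and the acceptance suite asserts the mismatch as a documented discrepancy
instead of silently correcting either number. Similarly, the operative
total sample size is taken as 7124 (consistent across the overall table
and the margin calculation) rather than the 7142 that appears once
elsewhere.

## The synthetic test surface

`scene_spec()`/`render_scene()` draw a schematic upright person —
skin-coloured head and arms, clothing panel, trousers — on a hospital-like
or regular background, with PPE rendered as colour patches: a light-blue
rectangle over the lower face anchored on the nose, purple discs at the
palm-rule centres, a yellow panel over the torso. Within-class hue jitter
(default ±0.04 per channel) and additive Gaussian pixel noise (default
sd 0.02) make classification learnable but not trivial. Rendering is
bit-exact under a fixed seed.

The palette is constructed so that each PPE hue is separated from every
other rendered colour by more than the colour-rule oracle's radius (0.12
in RGB) plus twice the maximum jitter; `oracle_color_rule()` is therefore
exact on generated crops at default amplitudes, which guarantees the
training acceptance property is attainable and gives the pipeline tests an
error-free reference predictor. The single deliberate exception is the
`white_coat` clothing mode, whose hue sits *inside* the gown ball to
reproduce the known failure mode of white coats being read as gowns; a
regression test asserts the confusion.

What the generator emulates: staged events of one person entering a scene
in a fixed PPE permutation (continuous lateral walk-in trajectories),
balanced labelled crop datasets with confounder tags (clothing, scenery, a
figure-scale class), hidden joints (zero-confidence ground truth), and
out-of-field wrists. What it does not emulate: real anatomy, texture,
lighting, occlusion, motion blur, or multiple people. Passing tests
therefore demonstrate that the *mechanics* — geometry, training loop,
visibility logic, aggregation, statistics — are correct; they say nothing
about classification accuracy on real people, and the published field
accuracies (85.58 % overall in training, 70.52 % live) are not reproducible
from synthetic data. The acceptance suite instead asserts the substituted
properties: ≥95 % held-out accuracy per region model on 200 generated
crops per class per region, ≥95 % end-to-end frame accuracy over eight
events covering all eight PPE permutations, and the min-region bound.

## Problem sizes and numerical choices

The shipped study sizes are desk-scale by design: 256×256 frames with a
~200 px figure, 200 crops per class per region for the acceptance
training run (400 crops per model, 80 validation), 50-frame events sampled
1:5. The pooled-projection extractor keeps feature extraction exact and
fast at these sizes.

Other numerical choices: probabilities are clamped to `[1e-12, 1 − 1e-12]`
inside the cross-entropy; feature standardisation adds 1e-8 to the
denominator so an all-zero crop maps to the zero vector; Glorot-uniform
seeded initialisation; single-person scenes are assumed throughout (the
published system does not state a multi-person rule); all randomness
derives from one run seed via a deterministic string-hash
(`derive_seed()`), so any two runs with the same configuration and seed
produce byte-identical outputs.

## Known limitations

* The synthetic surface verifies mechanics, not visual realism; no claim
  about real-world accuracy follows from green tests.
* The default feature extractor is linear; it separates colour-coded PPE
  but would not separate realistic textures. Plug in a real backbone
  through the adapter for field use.
* Only axis-aligned crops are produced; strongly rotated poses would
  benefit from rotation-aligned regions, which are out of scope.
* The event-level verdict rule (majority, ties non-adherent) is an
  extension beyond the frame-level published protocol and is flagged as
  such.
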