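---
title: "Methods: dilated contextual attention and two-stage mitosis detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilated contextual attention and two-stage mitosis detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mitotic count — the number of dividing cells in a fixed-area region of a
stained tumor section — is a core grading parameter in surgical pathology.
Automating it from whole-slide images (WSIs) is hard for two reasons:
mitotic figures are sparse (a handful per mm^2 against thousands of resting
nuclei), and they are easily confused with apoptotic or densely packed
nuclei. Practical systems therefore use a two-stage cascade: a detector
proposes candidate figures tile by tile, and a classifier re-scores each
candidate from a re-centered crop. This package implements that cascade as a
reusable toolkit: the dilated contextual attention operator, the two
confidence-fusion rules, the tiling/relocation inference scaffold, the
high-power-field (HPF) counting protocol and its error metrics, and a seeded
synthetic-data generator so every part is testable without WSI data.

## Dilated contextual attention (DiCoA)

The operator runs on a feature map `x` of shape `C x H x W`. Three 1x1
convolutions produce queries, keys and values; queries and keys may be
projected to a different channel count (256 in the full-scale detection
configuration), while the value projection keeps `C` channels so the
residual update below is well-typed. Each pixel attends to its
`delta`-dilated `k x k` neighborhood (defaults `k = 3`, `delta = 1`, so
`D = k^2 = 9` neighbors):

* scores: `DPS[n,i,j] = softmax_n( <Q[,i,j], K[,rho_n(i,j)]> )`, a per-pixel
  distribution over the D neighbors;
* update: `y[c,i,j] = norm( sum_n DPS[n,i,j] * V[c,rho_n(i,j)] ) + x[c,i,j]`.

Within a detection backbone the operator sits at the deepest bottom-up
feature level (after the 1x1 lateral convolution of C5, feeding the P5
top-down path), and its two outputs are consumed separately: `y` flows on
through the feature pyramid, while `DPS` is summarised into a per-box scalar
`Pdicoa`.

Numerical and interface choices that the operator's definition leaves open,
and how this package resolves them:

* **Border rule.** `D = k^2` is kept constant everywhere by shifting the
  whole dilated window inward near borders (the rule neighborhood-attention
  implementations use). If an axis is shorter than the dilated window span,
  positions are clamped per coordinate instead. Neighbor order is row-major
  over the `(row, col)` offset grid, so score layouts are bit-reproducible.
* **Softmax scaling.** The raw dot product is used as the logit; an optional
  `scale_qk` switch applies `1/sqrt(d)` for numerical robustness at large
  channel counts. The default follows the unscaled formulation.
* **`norm`.** The feature update's normalisation is per-position channel
  standardisation by default (zero mean, unit variance over channels, eps
  `1e-6`), with `l2` and `identity` modes available. All three map the zero
  vector to zero, which gives an exact residual identity (`V = 0` implies
  `y = x`) that the tests exploit.
* **`Pdicoa`.** How the score field becomes a per-box scalar is not pinned
  down by the operator's definition, so the package uses a deterministic,
  bounded rule: project the box to the feature map by the stride (rounded
  outward, at least 1x1), average the per-pixel maximum neighbor score over
  that footprint, and rescale so a uniform field (`1/D`, no attention
  contrast) maps to 0 and a one-hot field to 1. With `k = 1` the field is
  uniform by construction and the score is defined as 0.

## Detection stage

Slides are processed as overlapping 512-px tiles (default overlap 64 px,
edge-aligned final rows/columns so no tile leaves the slide). The detector
backend is pluggable: anything that maps a tile to boxes
`{x, y, w, h, Pobj}` (plus optionally `Pdicoa`) satisfies the contract.
Detections whose center lies within the relocation margin (default 32 px) of
their source tile border were produced with truncated context; each is
re-evaluated on a fresh tile centered on the box, the nearest re-detection
within the matching radius replaces `Pobj`, and unmatched border boxes are
dropped. The margin and overlap defaults are chosen so a ~50-px mitotic
figure cannot straddle a blind spot. Confidences are then fused,

    Pdet = (1 - alpha) * Pobj + alpha * Pdicoa,    alpha = 0.5 by default,

and greedy NMS (IoU 0.3, deterministic `(y, x)` tie-break) runs on the fused
score. Fusing before NMS is a deliberate ordering choice: suppression should
rank candidates by the same confidence the downstream stages consume. Boxes
without an attention score keep `Pdet = Pobj`.

## Classification stage

Each surviving box is re-cropped so its center coincides with the center
pixel of a 3x128x128 crop; at slide edges the window shifts inward (never
pads) and the shift is recorded. Two backbone feature extractors run on the
crop; their channel-concatenated feature maps are compressed by 2-d global
average pooling to a `C1 + C2` vector and a single linear layer with a
sigmoid produces `Pcls` (a binary mitosis-vs-not confidence; no hidden
layers or dropout). The final confidence is

    P = omega * Pdet + (1 - omega) * Pcls,    omega = 0.5 by default.

`omega` is exposed as a required configuration knob with the symmetric
default; results should always be reported together with the `omega` used.

## Reference backends

The package ships classical, CPU-trainable reference implementations of both
backend contracts so the full cascade can be exercised deterministically in
minutes: the detector segments dark blobs (Gaussian smoothing, Otsu
threshold with a contrast guard, connected components), summarises each blob
with moment features (area, eccentricity, major axis, darkness, aspect), and
scores it with a binomial GLM trained on labelled synthetic tiles; a DiCoA
pass over a 4-channel, stride-8 hand-crafted tile feature map (16 projection
channels at this desk scale) supplies `DPS` and `Pdicoa`. The classifier's
two stems are a center-focused segmentation stem (shape features of the blob
nearest the crop center) and a global context stem; both emit 1x1 spatial
maps, so the concat + GAP + linear-head contract is exercised end to end.
These backends exist to exercise the pipeline and the synthetic benchmark;
they make no claim about performance on real histology, and real
deep-learning backbones can be plugged in behind the same contracts.

## Evaluation protocol

* **Matching.** Predictions at or above the confidence threshold are matched
  to annotated centers greedily by ascending center distance; a pair is
  valid within a 25-px radius (about one mitotic figure diameter at the
  package's nominal 0.25 um/px scale). The matcher is deliberately simple
  and fully deterministic; radius matching was chosen over IoU because point
  annotations are the norm for mitosis datasets.
* **Metrics.** Recall, precision, F1, accuracy and specificity from the
  TP/FP/FN/TN counts; zero-denominator cases return 0 with an explicit flag
  rather than NaN.
* **HPF selection.** The mitotic-count region is one 7110x5333-px rectangle
  (the 10-HPF, 2.37-mm^2 counting region at 0.25 um/px). `select_hpf`
  searches integer origins using a coarse stride grid (default 256 px)
  augmented with edge-aligned and detection-aligned candidate origins. The
  detection-aligned candidates are the classic max-covering-rectangle event
  points; with them the search provably attains the true maximum over all
  integer origins (and the smallest tie-break origin), at negligible cost. A
  pure stride grid cannot guarantee that: on scaled-down slides the feasible
  origin range is smaller than the stride, leaving only corner candidates,
  and the tests compare against an exhaustive stride-1 oracle.
  Window membership is half-open on both axes with 0-based origins.
* **Counting.** The window is always selected from the predictions. GA
  (fully automated) reports the predicted count in that window; GB
  (human-machine interactive) reports the annotation count in the same
  window. The per-slide reference count is the annotation count in the HPF
  selected from the annotations themselves — the region a pathologist would
  count — so GB error reflects window mislocalisation only.
* **Threshold sweep.** MAPE (`mean(|pred - true|/true) * 100`) and MAE over
  slides, reported at the MAPE-minimising threshold (ties go to the lower
  threshold; the sweep optimises one threshold per dataset, not per slide).
  A zero reference count raises an explicit error naming the slide rather
  than silently skipping it, which would bias the sweep.

## Synthetic data

The generator renders eosin-textured tiles with dense round "nuclei"
distractors and sparse elongated, boundary-perturbed "mitotic figures",
Poisson-distributed at configurable per-mm^2 densities under the fixed
0.25 um/px scale convention, with an optional hotspot disc whose mitotic
density is multiplied. Defaults model a proliferative tumor region: 10
mitoses/mm^2, 4000 nuclei/mm^2, nucleus radii 6-10 px, mitotic major axes
20-36 px with 2.2-3.5 elongation. Everything is a pure function of
(config, seed), and annotations are exact by construction.

What the generator deliberately does **not** emulate: stain variability,
scanner artifacts, tissue architecture, touching/overlapping figure clumps,
and the real morphological diversity of mitotic phases. Passing tests on
synthetic data therefore demonstrate the correctness of the pipeline
machinery and the learnability of a minimal morphology contrast — not
performance on real WSIs.

The evaluation fixture generator places ground truths with pairwise
separation above twice the matching radius, drops each with the configured
miss probability, jitters survivors, and adds far-away Poisson false
positives; by construction the expected TP/FP/FN are exact whenever the
jitter stays below the radius, which turns the whole matching/metrics chain
into a checkable recovery experiment.

## Problem sizes used in the shipped tests

The test-suite and the acceptance script run entirely on synthetic data at
desk scale, chosen so the full suite completes comfortably on one CPU:
attention oracles on maps up to 16x16 with up to 16 channels; tiling and NMS
properties on slides of a few hundred pixels; HPF-selection oracles on
600x800 slides with the proportionally scaled (0.1x) window, flagged
non-standard; the end-to-end hotspot experiment on 900x1100 slides with a
planted hotspot placed inside the region that every candidate HPF window
covers, which makes the interactive-count recovery assertion robust to
which tied window the deterministic tie-break selects. Densities in tests
are set well above the clinical defaults so that small slides still contain
enough objects to train and evaluate the reference backends; the defaults
themselves stay at the realistic values documented above.

## Known limitations

* The reference backends are intentionally shallow; their scores saturate on
  easy synthetic contrast and should not be read as calibrated
  probabilities.
* `Pdicoa` from randomly initialised projections has a small dynamic range;
  with `alpha = 0.5` the fused `Pdet` is then dominated by `Pobj` shifted
  toward 0.5, which is why end-to-end operating thresholds near 0.5 act on
  the final fused `P` rather than on `Pdet` alone.
* Region reads decode the full image before cropping; the lazy-read
  interface is stable but the implementation targets desk-scale slides, not
  pyramid WSI formats.
* The relocation rule (re-detect on a re-centered tile, accept the nearest
  match within the evaluation radius, drop unmatched border boxes) is a
  reconstruction of border re-evaluation as commonly practised; other
  reasonable acceptance rules exist.
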