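# mitodica

Mitotic figure detection for histopathology, built around **dilated
contextual attention (DiCoA)** and a two-stage detection/classification
cascade, with the full high-power-field (HPF) mitotic-counting protocol.

## Who this is for

Counting mitotic figures in a fixed-area region of a stained tumor section
is a standard grading parameter. `mitodica` is aimed at people building or
evaluating automated mitosis detectors: it provides the attention operator,
the confidence-fusion rules, the whole-slide tiling/relocation inference
scaffold, the evaluation protocol (center-distance matching, F1-family
metrics, HPF selection, GA/GB counting, MAPE/MAE threshold sweeps), and a
seeded synthetic histology generator so every component is testable on one
CPU with no image downloads.

## The core operator

For a feature map `x ∈ R^{C×H×W}`, 1×1 convolutions produce queries, keys
and values. Each pixel attends to its δ-dilated k×k neighborhood ρ
(defaults k = 3, δ = 1, hence D = k² = 9 neighbors):

    DPS[n,i,j] = softmax_n( ⟨Q[·,i,j], K[·,ρ_n(i,j)]⟩ )
    y[c,i,j]   = norm( Σ_n DPS[n,i,j] · V[c,ρ_n(i,j)] ) + x[c,i,j]

`y` flows on through the detector's feature pyramid (the operator sits after
the 1×1 convolution of the deepest bottom-up level, feeding the top-down
path); `DPS` is summarised into a per-box attention confidence `Pdicoa`.
Stage confidences are fused twice:

    Pdet = (1 − α)·Pobj + α·Pdicoa          (detection stage, α = 0.5)
    P    = ω·Pdet + (1 − ω)·Pcls            (classification stage, ω = 0.5)

The classifier re-crops each box so its center sits at the center of a
3×128×128 window, concatenates two backbone feature maps along channels,
global-average-pools, and applies a linear + sigmoid head. The mitotic count
is read from the 7110×5333-px HPF rectangle (the standard 10-HPF, 2.37-mm²
region at 0.25 µm/px) with the highest predicted count, either fully
automated (GA: predicted count) or interactively (GB: annotation count in
the predicted window).

## Worked example

```r
library(mitodica)

cfg <- synth_config(slide_dim = c(1200, 1200), mitotic_density = 60,
                    distractor_density = 3000, seed = 7)
slide <- generate_slide(cfg)            # 12 annotated mitoses

detector   <- train_reference_detector(cfg, seed = 1)
classifier <- train_reference_classifier(cfg, seed = 2)

boxes <- run_detection(slide$image, detector, validate_config()$detect)
boxes <- run_classification(boxes, slide$image, classifier)

m   <- match_detections(boxes, slide$annotations, radius = 25, threshold = 0.5)
met <- detection_metrics(m)
```

Printed results from this exact script:

```
TP 11  FP 0  FN 1
recall 0.917  precision 1.000  F1 0.957

        x       y  w  h p_obj p_dicoa p_det p_cls     p
1  36.958 202.694 15 36     1   0.009 0.504     1 0.752
2 245.194  76.888 31 39     1   0.007 0.503     1 0.752
3 300.149  84.421 25 24     1   0.006 0.503     1 0.751
```

Reading the columns: `p_obj` is the detector's blob confidence, `p_dicoa`
the attention-derived score (small dynamic range under randomly initialised
projections), `p_det` their α-blend, `p_cls` the crop classifier's
confidence, and `p` the final fused confidence that matching thresholds act
on. Eleven of the twelve planted mitoses are recovered with no false
positives at threshold 0.5.

A thin command-line wrapper ships in `inst/cli/mitodica.R` with subcommands
`simulate`, `detect`, `classify`, `evaluate`, `attention-check` and
`pipeline`.

## What it is not

No GPU training, no pretrained backbone weights, no pyramid WSI formats, no
claim of benchmark accuracy on real datasets: the shipped detector and
classifier are classical reference backends that exercise the pipeline on
synthetic data. Real backbones plug in behind the documented
`DetectorBackend` / `ClassifierBackend` contracts. See the methods vignette
(`vignettes/mitosis-detection-methods.Rmd`) for the model, the design
decisions, and known limitations.
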