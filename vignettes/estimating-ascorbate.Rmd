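---
title: "Estimating ascorbic acid in camu-camu from images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ascorbic acid in camu-camu from images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camuvision)
```

## The estimation problem

Camu-camu (*Myrciaria dubia*) is priced by its vitamin C (ascorbic acid,
AA) content, which is normally measured by DCPIP titration in a
laboratory. `camuvision` implements an image-based surrogate: from an
overhead photograph of fruits on a neutral background at a known camera
distance, it estimates the pulp mass of each fruit from its projected
silhouette and ripeness stage, then scales certified stage-specific
laboratory concentrations by the estimated mass. The package deliberately
separates the *estimation* chain (calibration, pulp model, proportional
concentration estimator, reporting, evaluation) from the *perception*
front-end: a simple color-based reference detector is included so the
chain runs end to end, and detections from any trained object detector
can be injected through COCO-style JSON instead.

## The estimation chain

**Scale calibration.** A fruit silhouette of $A_{px}$ pixels becomes a
physical area $A = A_{px} / s^2$ cm² with $s$ = 143.79 px/cm, the scale
of the calibrated acquisition geometry (30 cm lens-to-tray distance,
3024 px square frames). The scale is a configuration field, never a
hard-coded constant, because it is only valid at that distance: area
errors scale with the square of any distance deviation, which is the
dominant field-use failure mode. When only a bounding box is available,
the projected area uses the ellipse inscribed in the box,
$\pi w h / 4$ — camu-camu is near-spherical, and a raw box overcounts a
round silhouette by $4/\pi$. Pixel masks, when present, are counted
directly and take precedence.

**Pulp model.** The default pulp estimator is the quadratic calibration
obtained from manual depulping of 100-g samples across area classes and
stages:

$$P = 0.084\,A^2 - 0.252\,A + 6.292 + 0.63\,M \quad [\mathrm{g}]$$

with maturity factor $M$: Pinton Green 0, Ripe Pinton 1, Ripe 2. The
source material states $M \in \{0,1,2\}$ without naming the mapping; we
assign it in ripeness order over the commercial stages and expose it as a
configuration field so users can override it. Two numerical caveats are
handled explicitly: the polynomial's vertex lies at $A = 1.5$ cm², so the
model is only monotone above that area (verified by a property test); and
the intercept of 6.292 g at zero area is biologically odd, so while the
model evaluates as printed for all $A \ge 0$, negative areas are
rejected rather than extrapolated. The volumetric alternative
$P = A \times 0.8\ \mathrm{cm} \times 1\ \mathrm{g/cm^3}$ (mean pulp
thickness times density) is retained as a selectable estimator
(`pulp_model = "thickness"`); which of the two produced the published
system values is not stated in the source, so the quadratic calibration —
described there as the cornerstone of the pipeline — is the default.

**Area classes.** The depulping table bins areas as "less than 5",
"between 5 and 8" and "more than 8" cm² without fixing the boundaries'
side. We resolve them half-open — $[0,5)$, $[5,8)$, $[8,\infty)$ — so the
classes partition $[0,\infty)$; 5.0 falls in the middle class and 8.0 in
the top one. The table's "Pinton Ripe" label is normalized to
"Ripe Pinton" (the same stage under two names).

**Concentration estimator.** For certified stage concentration $R_1$
(mg/100 g), reference mass $b_1 = 100$ g and estimated mass $b_2$,

$$R_2 = R_1 \cdot b_2 / b_1 .$$

The aggregation of $b_2$ over an image is not spelled out in the source;
we interpret $b_2$ per stage as the summed estimated pulp mass of that
stage's fruits, consistent with the 100-g-per-stage laboratory protocol
(≈10 fruits per sample). $R_2$ is reported in mg/100 g alongside — never
conflated with — the per-fruit total ascorbate in mg, computed as the
laboratory concentration per gram times the fruit's pulp mass. Green
fruit is excluded from every total: it is not commercialized (it is
reserved for ripening), has no maturity factor, and the published error
analysis excludes it too. Exclusion is a flag on the record, so Green
fruit still appears in counts.

## The reference detector

The reference detector exists so the pipeline is testable without trained
weights; it is not a reimplementation of any deep model. Foreground =
pixels whose HSV saturation exceeds a threshold (default 0.15; the
neutral background sits near 0.03), connected components above a minimum
area (default the pixel equivalent of 0.1 cm²) become detections with a
tight box and mask, and confidence is identically 1. Staging assigns the
masked mean color to the nearest of four prototype colors, measured by
Euclidean distance in the feature space
$(s\cos 2\pi h,\ s\sin 2\pi h,\ v)$ — a hue/saturation embedding chosen
over raw RGB for illumination robustness, with hue treated circularly.
Exact ties break toward the lower ripeness ordinal, making staging
deterministic. The four stages are defined visually in the source, not
numerically, so the palette is a declared fixture (green, yellow-green,
orange-red, dark red prototypes) and fully configurable. Touching fruits
are not split — overlap handling belongs to the external detector — and
the synthetic generator keeps fruits disjoint by default.

## The synthetic-scene generator

`scene_spec()` / `generate_scene()` emulate the acquisition setup: ~15
rotated ellipses (near-spherical fruit, diameters 2.0–3.2 cm) in
stage-prototype colors on a neutral background, stage mix weighted 0.4
toward Ripe and 0.2 elsewhere (mirroring the stage balance of typical
harvest trays), at a default 1024-px canvas standing in for the 3024-px
frames. The pixel scale shrinks by the same 1024/3024 factor so
*physical* areas are preserved; tests therefore run at realistic areas in
seconds. Placement rejection-samples non-overlapping bounding circles
and raises a capacity error when the requested count cannot fit. One
global RNG seeded from `spec$seed` drives every draw, so scenes are
byte-reproducible; optional Gaussian noise, specular highlights and blur
are off by default.

Ground truth records each ellipse's parameters, its analytic area
$\pi a b$, and the expected downstream quantities recomputed from the
calibration, so end-to-end tests compare the pipeline against closed-form
expectations. On noiseless scenes the only discrepancy is rasterization:
pixel-center membership makes mask areas differ from $\pi a b$ by well
under 2% at these fruit sizes (~0.7–1.5 cm² of px at 48.7 px/cm).
What passing these tests does *not* show: robustness to real-world
lighting, glare, occlusion, touching fruit, background clutter, or
camera-distance error — the generator renders flat-shaded ellipses, not
photographs, and the color prototypes match the palette by construction.

## Evaluation

`mape()` implements
$\mathrm{MAPE} = \tfrac{100}{n}\sum |y_i - \hat y_i| / y_i$ (laboratory
values $y_i > 0$; division by zero is rejected). `stagewise_mape()`
computes it per stage and averages *unweighted* across commercial stages
— that convention reproduces the published mean, $(11.95 + 3.80 + 5.56)/3
\approx 7.1\%$, from the certified comparison pairs shipped as a fixture
(one printed pair per stage; whether replicate pairs stood behind the
published figures is unstated, and the single pairs reproduce them
exactly at printed precision under round-half-up). Green pairs are
dropped with a warning unless explicitly included.

`detection_pr()` scores detections at a single IoU threshold with
one-to-one matching of maximum cardinality: the matching is seeded
greedily in confidence order (each prediction preferring its highest-IoU
admissible box) and augmented to optimality, so the reported TP equals an
exhaustive optimal assignment — pure confidence-greedy matching is
occasionally suboptimal, and we prefer the well-defined optimum, with
confidence/IoU acting only as tie-breaks. mAP@50–95 is deliberately
omitted: the reference detector produces no score sweep, so a
single-threshold precision/recall/F1 plus the 4×4 stage confusion matrix
(`stage_confusion()`, macro-averaged metrics) is the honest metric set.

## Numerical and design choices

* Bounding boxes are COCO-convention: top-left pixel origin, zero-based,
  half-open $(x, y, w, h)$.
* Reports serialize numbers at full precision; rounding happens only in
  formatted human-readable tables (printed MAPE comparisons round half
  away from zero to the reference tables' decimals).
* `refit_pulp_calibration()` refits the quadratic form to the nine
  depulping measurements by least squares under declared representative
  areas (4, 6.5, 9.5 cm² per class). The representative areas behind the
  shipped coefficients are unknown, so the refit documents the procedure
  and supports recalibration from a user's own depulping table; it does
  not claim to reproduce the default coefficients.
* Problem sizes in the tests — 320-px canvases with ~6 fruits for unit
  tests, twenty 1024-px 15-fruit scenes for the end-to-end check, 200
  random matching instances and 1000 random polynomial points for oracle
  equivalence — were chosen to exercise the code at realistic geometry
  while keeping the suite fast to run routinely.

## Known limitations

* The fixed px/cm scale is only valid at the calibrated capture distance;
  no automatic distance or scale estimation is attempted.
* The reference detector assumes a near-neutral background and separated
  fruit; it will merge touching fruit and is not robust to field scenes.
* The pulp model is calibrated for camu-camu at commercial stages; the
  Green stage has no pulp prediction under the quadratic model.
* Published system-vs-laboratory values depend on the original image set
  and trained detector and are used here only as evaluation inputs, never
  as quantities the package claims to regenerate from images.
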