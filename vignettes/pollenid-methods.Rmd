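---
title: "pollenid: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pollenid: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage assumes, which parameters matter, what the synthetic
generator does and does not emulate, and where the design was genuinely
open. The README shows the user-facing workflow; here we explain the
choices behind it.

## Setting

Urticaceae pollen monitoring poses an open-set, fine-grained image
classification problem. Grains of *Urtica* and *Parietaria* are
morphologically near-identical under brightfield optics: small (~11–20 µm),
rounded, tri- to zonoporate, with a thin psilate-to-scabrate exine. The
discriminative features are weak and three-dimensional — the annulus (a
thickening of the exine around each pore, pronounced in *Urtica*, weak in
*Parietaria*), surface ornamentation (coarser in *Parietaria*), outline
angularity, overall size, and, for *U. membranacea*, a small diameter
(~10–12 µm) combined with more than six pores. No single focal plane shows
all of them, which is why the pipeline consumes Z-stacks (20 slices, 1.8 µm
apart by default) rather than single images, and why aerobiological samples
(unacetolyzed, debris-laden) are hard: organic content obscures wall
features and debris occludes grains in some planes.

## Grain detection

The detector binarizes a single reference image per stack. We use the
minimum-intensity projection of all slices as that reference: stained
grains are dark in at least one plane, so the projection gives every grain
its best contrast regardless of its focal depth; a per-slice union mode is
available (`binarization_reference = "slice_union"`). The default threshold
is Otsu's method followed by hole filling and one 3×3 opening — standard
and parameter-light. Candidates are then filtered in a fixed order and
every rejection is logged with the first rule that failed:

1. `border` — the bounding box touches the frame edge (the grain may be
   incomplete);
2. `size` — equivalent circular diameter `2·sqrt(A/π)·pixel_size` at most
   5 µm. "Size" is interpreted as diameter, the palynological convention
   for grain size, not area;
3. `circularity` — `4πA/P²` at most 0.3. The value is perimeter-estimator
   dependent, so the estimator is fixed and named: we trace the boundary
   (`EBImage::ocontour`) and sum chain steps with weight 1 (axial) or √2
   (diagonal). Under this estimator a digital square scores ≈ π/4 and a
   disc ≈ 0.9; values may slightly exceed 1 for small discs, hence the
   documented range (0, ~1.1];
4. `overlap` — "non-overlapping" is operationalized as *separated by at
   least one background pixel*: if dilating the candidate mask by one pixel
   connects it to another candidate, both are rejected.

Two grains that physically overlap merge into a single connected component
during binarization. Such a blob is usually rejected by the circularity
rule; when it is compact enough to pass, it enters the output as a single
(wrong) region whose centroid lies between the true grains. The guarantee
the detector makes — and the property the tests assert — is that neither
*member* of an overlapping pair is ever reported; splitting merged pairs
(watershed) is explicitly out of scope. Accepted regions are returned
sorted by bounding-box position so results are deterministic.

## Focus selection

Defocused brightfield slices lose both intensity extremes: shadows (rim,
pores) wash out and the bright surround dims. The keep-rule is therefore:
slice minimum ≤ `min_pixel_threshold` AND slice maximum ≥
`max_pixel_threshold`, evaluated inside the grain mask dilated by the crop
margin (so the bright surround is included but distant clutter is not).
The thresholds default to calibration-free percentiles of the per-slice
statistics — minimum threshold at the 25th percentile of slice minima,
maximum threshold at the 75th percentile of slice maxima — so the rule
adapts to bit depth and staining intensity. These defaults are this
package's interpretation; the reference workflow's actual values are not
published and ours must not be mistaken for them. On degraded grains
(debris occlusion, no slice passing both cuts) the filter falls back to
the `min_kept_slices` (default 3) best-contrast slices and warns, so a
projection always exists. The output is always an ordered subsequence of
the input; tightening either threshold can only shrink it.

One realism caveat: in our phantoms the background stays bright in every
slice, so the maximum-value criterion is nearly non-informative and the
minimum-value criterion does the work. On real stacks with specular
highlights the maximum criterion contributes; the contrast-percentile
alternative (`method = "contrast_percentile"`) behaves similarly in both
regimes.

## Projections and framing

Three complementary projections summarize a grain's focal series as the
three channels of the classifier input:

- **standard deviation** (channel 1): per-pixel sample standard deviation
  (n−1) across kept slices; rims and pores, whose intensity changes
  strongly with focus, appear bright. The n−1 denominator matches the
  common image-stack convention; a population-variance flag exists.
- **minimum intensity** (channel 2): per-pixel minimum; the darkest
  silhouette of the grain.
- **extended depth of field** (channel 3): per pixel, the value from the
  slice with the highest local focus score. The score is squared Sobel
  gradient magnitude averaged over a `focus_window_px` window (default
  9 px), optionally Gaussian-smoothed (`smoothing_px`, default 2) across
  the score volume before the argmax to suppress speckle in the slice-index
  map. Selection is hard (no blending), so every output pixel provably
  exists in its slice column and the index map is exactly testable against
  a brute-force loop at zero smoothing. Ties go to the earlier slice. The
  window and smoothing defaults are exposed and logged because the
  reference macro's values are not published.

Each channel is min-max normalized independently (stddev and intensity
channels have incommensurate ranges and the classifier needs a defined
input scale; the constants are recorded per frame), then placed *unscaled*
into a 276 × 276 frame with the grain centroid at the frame centre ± 1 px.
Padding uses the channel's own border median. Grains larger than the frame
are an error, never downscaled: size is a class feature, and the fixed
frame is what lets the network see absolute scale. Normalization makes the
frame invariant to uniform intensity rescaling of the stack, which the
tests assert.

## Classifier

The engine (RcppArmadillo) implements valid convolutions via im2col,
average and max pooling, fully connected layers with ReLU, softmax
cross-entropy, inverted dropout, L2 weight decay and Adam, with its own
seeded RNG so training is bit-reproducible independent of R's RNG state.
Four compact architectures are provided — `tiny_test` (the desk-scale
default: 3× average-pool stem, three 8/16/32-filter conv blocks, 32-unit
hidden layer), two `light_*` variants, and `deep_baseline` (stacked 3×3
blocks, three FC layers). None of them is a published large-scale
backbone; `pretrained` mode exists for externally supplied weight files
and errors when the file is absent rather than silently training from
scratch. The `tiny_test` stem keeps ~92 px resolution because the pore
spots that identify *U. membranacea* are only ~2 px after pooling; a
coarser stem loses them and over-relies on size.

Cross-validation is stratified: 5 folds (80/20 per fold) or 10 (90/10),
each image validated exactly once, augmentation applied to training
portions only, per-fold confusion matrices summed into pooled metrics.
Because the reference protocol does not state whether accuracy is
fold-pooled or fold-averaged, both are reported (`pooled`, `averaged`).
When per-plant/sample identifiers are available the folds can keep all
images of one plant together (`group_by_sample = TRUE`, the default when
`sample_id` is given) — stricter than plain stratification, which a flag
restores, and the variant used by the package's own end-to-end benchmark
since it matches the reference protocol. A class with fewer groups than
folds falls back to plain stratification with a warning.

Augmentation is deliberately minimal: random horizontal/vertical flips and
one multiplicative brightness factor drawn uniformly from 0.1–2 (then
clipped to [0, 1]), applied online so every epoch sees fresh draws. No
rotation, zoom, shear or translation — those would alter the morphology
(size, outline) that carries class information. Optimizer (Adam,
learning rate 1e-3, batch 16), L2 weight 1e-4 and dropout 0.25 are this
package's defaults, documented as such: they are conventional small-CNN
settings, not reference values. Epochs default to 30 per fold.

Metrics follow the standard one-vs-rest definitions: precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and CCR (accuracy)
`(TP+TN)/(TP+TN+FP+FN)`; averages are weighted by class support, and for a
complete confusion matrix the weighted recall equals the CCR — an identity
the tests check on random matrices. Division by zero yields 0 with a
warning and a flag, since the convention is unstated in the reference
formulas.

Open-set assignment applies an identity threshold to the top softmax
score: at or above the threshold the top class is assigned, below it the
grain is "unknown". Thresholds of 0.60 and 0.70 are the monitoring
defaults; the unknown share is non-decreasing in the threshold by
construction. Monitoring reports aggregate per sample: grain count, class
percentages and unknown percentage (one decimal), plus the unweighted mean
of per-sample unknown percentages per threshold.

## The synthetic generator

The generator exists because reference pollen stacks are not
redistributable; it renders what the pipeline needs to be testable, not
photorealistic optics. A grain is a dark-rimmed disc on a bright
background (stained brightfield convention): interior at 0.62, rim 0.30,
pores 0.12, background 1.0 before scene scaling. The outline is a disc
perturbed by low-order radial harmonics (3–6) with total relative
amplitude 0.16 × `outline_angularity` — enough to emulate "rounded to
slightly ellipsoidal" through "angular". The rim has base thickness
max(1.5 px, 6% of radius) and widens near each pore by a factor
`1 + 2.5·annulus_strength·Gaussian(angle; σ = 0.35 rad)`; at
`annulus_strength = 0` the rim width is exactly flat. Pores are dark discs
of radius ~0.8 µm placed just inside the boundary at jittered
equally-spaced angles. Ornamentation is multiplicative smoothed Gaussian
texture with amplitude `texture_amplitude`. Defocus follows
`σ(z) = 0.5 px + 0.35 px/µm · |z − focal_z|`, applied per slice as a
Gaussian blur — the simplest model that produces the focus-dependent
contrast the focus filter needs. Debris particles are strongly perturbed
dark blobs with their own focal depth, so they can occlude grains in some
slices only; detector noise is additive Gaussian. The default pixel size,
0.16 µm/px, is a plausible value for a 100× oil objective on an EM-CCD
camera and is configurable everywhere.

Class presets encode only the *direction* of the documented contrasts —
no quantitative ornamentation measurements exist to calibrate against.
Magnitudes were chosen once so that each contrast is visible at the
default sampling: urtica 13–20 µm, 3–4 pores, annulus 0.80 ± 0.06;
parietaria 11–16 µm, 3–4 pores, annulus 0.25 ± 0.06, texture 0.20;
membranacea 10–12 µm, 6–8 pores, angularity 0.30. Grains are attributed
to plants (8/8/5 per class, consistent with pooling two species per genus
at a minimum of four plants each) and plants carry small random shifts in
diameter, annulus and texture, emulating between-plant variability.
Everything is reproducible bit-for-bit from the scene seed at the stored
bit depth.

What the phantoms do *not* emulate — and what passing tests therefore do
not show about real data: optical PSF structure beyond Gaussian blur,
refractive halos, staining variability between slides, touching-grain
clumps that need splitting, the texture statistics of real exine, or the
full debris ecology of Hirst tapes. Results on phantoms bound what the
pipeline can do on ideal data; they do not predict accuracy on real
aerobiological samples.

## Numerical and procedural choices

- Coordinates are (row, col), 1-based, slice 1 = first acquired plane.
- Stacks persist as 8- or 16-bit quantized TIFF with a JSON sidecar as the
  calibration source of truth (TIFF resolution-tag dialects vary);
  quantization is the only intensity change and round trips are
  bit-identical at the stored depth. Missing calibration is an error,
  never a silent default.
- EDoF argmax ties break toward the earlier slice; the index map at zero
  smoothing is compared exactly against a per-pixel loop in the tests.
- Degenerate inputs: constant images binarize to an empty mask; a
  single-slice stack is an error for the standard-deviation projection
  (with a pointer to the focus fallback) and the identity for the others;
  constant channels normalize to zero with a flag.
- The end-to-end benchmark (also run by `scripts/acceptance.R`) uses 100
  grains per class, 5 folds, 30 epochs and plain stratification; at that
  size the phantom classes are separable by construction and pooled CCR
  lands around 0.95–0.99 with *U. membranacea* among the best-recalled
  classes. These sizes are the package's documented study conditions for
  desk-scale verification.
- Scene rendering, fold assignment, initialization, shuffling, dropout and
  augmentation are all driven by explicit seeds; two runs with one seed
  agree exactly.

## Known limitations

Merged overlapping grains can survive the circularity cut as a single
false region (see above). The focus filter's maximum-value criterion is
weakly informative on phantom data. The CNN engine is single-threaded and
CPU-bound by design; large-scale backbones require external weights and
are not trained here. Species-level distinctions within *Urtica* or
*Parietaria* are not attempted: the projections do not resolve exine
ornamentation at that level, and the monitoring classes do not require it.
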