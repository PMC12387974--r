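---
title: "Measuring wound size, depth and tissue composition from depth maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wound size, depth and tissue composition from depth maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`woundlidar` is a desk-scale implementation of a LiDAR-based wound
assessment pipeline for hard-to-heal wounds: surface area, depth against a
reconstructed healthy-skin reference surface, and slough/necrosis
composition via two sequential U-Nets, together with the agreement
statistics used to validate such devices against digital planimetry and
probe measurements. This vignette explains the models, the defaults, and
the choices made where the design was genuinely open.

## The measurement model

**Geometry.** The sensor is modelled as a pinhole camera with a 192 x 256
range image (the native resolution of current mobile LiDAR depth maps),
focal length 210 px (about a 60-degree horizontal field of view), pixel
coordinates 0-based with the sample point at the pixel center. The sensor
measures *range along the ray* — what a time-of-flight device actually
reports — and `backproject()` converts to metric camera-frame points,
dividing by the ray norm to obtain the optical-axis depth z. (A published
shorthand treats the stored value as z directly; `depth_map()` therefore
records which convention its values use, and both are supported.) The
focal length is a free parameter: the device literature gives the sensor
resolution and a greater-than-30-cm working distance but no optics, so the
default was chosen once to put a 350 mm scene comfortably inside the frame.

**Surface area.** Each wound-mask pixel contributes its physical footprint
`(z/f)^2` mm^2 — the area a pixel covers on a fronto-parallel plane at
depth z. Summation makes the estimate independent of capture distance
because the quadratic footprint growth exactly cancels the quadratic loss
of pixels. This projected area under-measures an obliquely viewed wound by
the cosine of the view angle, so the angle-adjustment step fits the
surrounding-skin plane and divides by `cos(tilt)`. The exact angle
correction used by the production device is described only by citation in
its literature, so the cosine correction here is a declared reconstruction
with the right first-order behavior (verified against rendered 30-degree
tilts). Distance invariance holds while the wound stays well resolved; a
25 mm-radius wound at 500 mm covers only ~330 px and pixel rasterization
alone can shift its area a few percent, mirroring the device's own caveats
about small wounds.

**Depth.** The boundary between healthy and wounded tissue serves as the
reference surface: the wound mask is dilated by a 5 px ring (the
literature names the boundary but not its extent), the ring's valid pixels
are back-projected, and a plane is fitted by total least squares
(orthogonal regression via the covariance eigen-decomposition — symmetric
in all axes and robust to tilt; no fitting method is prescribed by the
source). A curved reference sheet was deliberately not used: the
validation phantoms have flat surroundings and a plane is the minimal
model. Depth is the signed distance of wound points along the plane
normal — *along the normal*, not the optical axis, so the estimate is
invariant to small camera tilt. The per-pixel distance image is smoothed
with a 3 x 3 mean before taking the extremum, suppressing single-pixel
noise spikes that would otherwise bias a max-statistic upward by several
noise standard deviations. Depression is positive; a hypergranulation bump
that rises above the skin is reported as a negative depth; when both
exist the larger magnitude wins with ties going to depression.

**The +/-3 mm sentinel.** The depth resolution of the modelled sensor is
+/-3 mm: extrema below that magnitude are reported as `depth_mm = 0` with
`sentinel = TRUE`, rendered `"+/-3"` in reports, which keeps numeric
pipelines clean while matching how clinical tables print such rows.
On noise-free renders the sentinel triggers exactly when the cavity is
shallower than 3 mm.

## The phantom simulator

The in-vitro bench model is two adjustable cubes forming a wound opening
over a flat floor: pushing the cubes together narrows the aperture while
deepening the cavity. `phantom_spec()` parametrizes exactly that: skin
distance (default 350 mm, honoring the >30 cm working distance), aperture
(width, length), depth 0–35 mm (negative = bump height), wall steepness
(90 degrees = vertical), rectangular or elliptical opening, skin tilt, and
Gaussian range noise (default sd 1.0 mm — together with the 0.1 mm disk
quantization this reproduces the +/-3 mm effective resolution scale; it is
configurable). The floor width is `aperture - 2*depth/tan(edge_angle)`; when
that reaches zero the walls meet in a V-groove and the physical cavity is
shallower than the nominal setting — the geometric origin of the
under-estimation seen for deep, narrow, or flat-walled wounds.

Rendering casts one ray per pixel analytically against the piecewise
planar primitives (skin plane, floor plane, sloped or vertical walls; the
elliptical wall is a cone solved as a quadratic). Every candidate hit is
validated against the height-field definition to 1e-6 mm, so the renderer
cannot drift from the scene it claims to render; the test suite separately
checks first-hit ranges against a dense-sampling-plus-bisection oracle to
0.05 mm. For the elliptical shape the wall inset is measured radially and
scaled by the mean semi-axis (exact for circles, slightly steeper walls
along the minor axis of eccentric ellipses — documented, not a bug).
Occlusion needs no special code: the first surface along the ray wins.

The bench sweep (`sweep_invitro()`) renders each (depth, edge-angle)
configuration several times with fresh noise, mirroring the 8–10 repeated
examinations per phantom setting in the original protocol. By default the
aperture is coupled to the depth to keep a 24 mm flat floor, as the bench
protocol co-varied opening and depth; crossing fixed apertures with all
depths would silently turn deep configurations into V-grooves whose true
depth is not the nominal one. The individual bench configurations of the
original 51-wound protocol are not published, so the sweep grid is a
stand-in with the same ranges, not a reconstruction.

## The synthetic photo corpus

The clinical training corpus (thousands of annotated wound photos) is
proprietary, so the tissue U-Nets train on a fully specified generator:
beige skin, red granulation, yellow fibrous slough (with a sinusoidal
streak texture), near-black necrosis, each drawn from fixed per-class
color distributions, modulated by a seeded lattice-noise patch field, a
depth-shading cue, a mild lighting gradient, and per-pixel Gaussian noise.
Tissue patches are rank-thresholded on the smooth field so the target
slough/necrosis area fractions are met exactly up to pixelation. Images
are 128 x 128, rendered through a 200 px-focal-length camera with the
wound framed the way clinical photos frame wounds (apertures 25–80 mm at
250–400 mm, random offsets and tilts, 10% intact-skin negatives); early
experiments with wounds covering under 1% of the frame were unlearnable
and unrealistic as clinical photographs. Splits are 70/20/10
train/validation/test, disjoint and exhaustive, deterministic per seed.

What passing tests on this corpus show — and do not show. The generator's
classes are separable by color with modest texture confounds; a small
U-Net therefore reaches validation dice well above what any model achieves
on real clinical photographs. Passing the pipeline tests demonstrates
that the architecture, losses, training loop, masking contract and
fraction bookkeeping are correct, and that the two-stage design recovers
known tissue fractions (regression slope 1 +/- 0.15 on held-out images).
It says nothing about accuracy on real wounds, where tissue boundaries
are ambiguous even between experts.

## The segmentation stack

The U-Net is the textbook encoder–decoder: per level two 3 x 3
convolutions (ReLU) then 2 x 2 max pooling with filter doubling; the
decoder upsamples (nearest neighbour), concatenates the same-level encoder
features, and convolves twice; a final 1 x 1 convolution yields per-pixel
class scores. Desk-scale defaults: 3 levels, 16 base filters (~0.5 M
parameters) — deliberately not a production network. Stage 1 maps RGB to
background/wound; stage 2 receives the RGB zeroed outside the stage-1 mask
plus the mask as a fourth channel (the source says only that the stage-1
output "serves as the input mask"; this is the chosen mechanics) and
labels other/slough/necrosis, with out-of-mask pixels forced to "other".

The loss is pixel-wise cross-entropy plus one minus the mean soft dice,
equally weighted — the training literature for this device reports loss,
accuracy, dice and IoU without naming a loss, and this choice tracks all
the reported metrics while handling the ~5% foreground fraction. Adam at
1e-3, batch 8, He initialization, early stopping when validation loss
fails to improve by more than 1e-4 for 10 consecutive epochs, returning
the best-validation weights. Everything is single-precision C++
(im2col + GEMM) with its own seeded RNG, so training is bit-reproducible
run to run. Reported dice/IoU are macro averages over foreground classes,
with empty-vs-empty defined as 1; "accuracy" is pixel accuracy over all
classes.

An instructive coupling surfaced while validating the two-stage design:
the accuracy of recovered tissue *fractions* is governed primarily by the
stage-1 mask, not by stage 2. Fractions are percentages of predicted
wound-bed pixels, so any skin that leaks into the stage-1 mask is labelled
"other" by stage 2 and dilutes the denominator — a stage-1 dice of 0.92
already drags the predicted-vs-true fraction slope to ~0.75 even under a
well-trained stage 2. The physical device shares this structure (its
tissue percentages are likewise relative to the stage-1 delineation).
The fraction-recovery analysis therefore trains stage 1 to mask
convergence (10 epochs on this corpus, dice ~0.98) and stage 2 for 8
epochs at 2e-3, where its boundary sharpness has converged.

Problem sizes used by the test suite and acceptance script: n = 200
images; 3 training seeds x 5 epochs for the stage-1 dice median
(validation dice plateaus above 0.9 by epoch 3-5 on this corpus);
10 + 8 epochs for the fraction-recovery pipeline; 30 held-out images for
fraction recovery; and a 51-configuration x 3-repeat bench sweep. These
sizes were chosen as the smallest that exercise every claim stably.

## Agreement statistics

The validation statistics are reverse-engineered from published per-row
columns and locked by fixture tests, because no formulas are stated
anywhere in the source material:

* accuracy vs reference: `e = |device - reference| / device`
  (device-value denominator), accuracy `100(1 - mean e)`;
* paired reproducibility: `r = diff / min`, CV `=(diff/sqrt 2)/mean`
  (two-value sample sd over mean);
* depth vs probe: signed `s = |device_mean - probe| / device_mean`
  (negative for hypergranulation rows), precision from
  `|m1 - m2| / min(|m1|, |m2|)`, sentinel rows contributing zero;
* repeated groups: spread `(max - min)/min` with all-zero groups counting
  0 (a "none measured every time" wound agrees perfectly), CV = sample
  (n-1) sd over mean;
* per-wound fraction agreement: min/max ratio with 0/0 = 1.

Each report records the formula identifier it used. Computations run in
full precision; rounding happens only at presentation. Three rows of the
bundled per-wound agreement table are internally inconsistent with the
min/max rule that reproduces every other row, so the headline means are
computed from the printed agreement columns rather than re-derived ratios;
similarly one published binary-evaluation total disagrees with its own
marginals by one image, so per-class accuracies are computed from the
class counts.

## File formats and determinism

Depth maps are stored as 16-bit grayscale PNG at 0.1 mm per unit (well
under the 3 mm resolution floor) with a JSON sidecar carrying the scale,
missing-value code and camera intrinsics; missing returns are NA in
memory and a reserved code on disk. The 16-bit PNG encoder is built into
the package's compiled code (a minimal writer using stored deflate
blocks); reading uses the `png` package. Masks and tissue maps are
palette-style 8-bit PNGs (gray level = class index), which round-trip
losslessly. Bilinear depth upsampling (e.g. 192 x 256 to 512 x 683) is
implemented in the package so that missing regions propagate as missing —
a contract resampling libraries do not offer — and never extrapolates
outside the source range; it adds no information and is off by default in
measurement. Reports are canonical JSON (sorted keys, fixed float format,
MD5 config stamp), so any rerun with the same seed and configuration is
byte-identical.

## Known limitations

* The reference surface is a plane; strongly curved anatomy (a heel, a
  shin) would need a curved sheet and is out of scope.
* Undermined cavities — wound beds wider than their opening — cannot be
  reconstructed from a single viewpoint and are underestimated, as with
  the physical device.
* The cosine angle adjustment is first-order; at extreme tilts the mask
  itself degrades before the correction does.
* Generator realism bounds what segmentation results mean (see above).
* The elliptical wall steepness is exact only for circular openings.
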