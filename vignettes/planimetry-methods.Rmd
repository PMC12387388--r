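---
title: "Measuring mitral valve area from echocardiogram videos: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mitral valve area from echocardiogram videos: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoplanim)
```

## The measurement problem

In a 3D transesophageal echocardiogram rendered en face, the mitral valve
apparatus appears as brightly coloured tissue and the blood pool as near
black. When the valve opens in diastole, a dark orifice appears between the
coloured surfaces; the area of that orifice at its maximum opening — the
mitral valve area, MVA — is the planimetric criterion for grading stenosis
severity. Manual planimetry traces the orifice edge by hand on a vendor
workstation; `echoplanim` automates the same measurement on exported AVI
videos.

## The planimetry engine

**Grayscale.** Frames are RGB; intensity is reduced by the luminance
weighting $L = 0.2989R + 0.5870G + 0.1140B$, rounded half-up. The G channel
dominates, matching the eye's sensitivity.

**Binarisation.** A single-band fixed threshold maps gray to binary:
$v^{out}_{ij} = 1$ iff $v^{in}_{ij} > t$, with $0 < t < 255$. The
inequality is deliberately *strict*: the formal definition of the operator
uses ">", and the package follows it even though an informal reading
("pixels with values lower than t become black") would suggest "≥". For
integer images the two conventions differ only by relabeling $t \to t-1$,
so no measurable quantity depends on the choice; we document it because the
scan's threshold indices do.

**Orifice detection.** In the binary frame the orifice is a dark (0) region
*fully enclosed* by bright pixels. Enclosure — the region does not touch
the image border — is what separates the orifice from the dark background
surrounding the tissue, which always reaches the edge. Dark regions are
labelled with 4-connectivity (so the bright enclosure cannot be breached
through a diagonal), and the largest enclosed region is taken; ties break
to the first region in scan order. Absence of any enclosed dark region is a
valid result (valve closed, area 0).

**Area and perimeter.** Area is the enclosed pixel count times the
physical area of one pixel, exactly. The contour is the Moore
(8-neighbour) boundary trace of the region's outermost pixels; the
perimeter is the arc length of that closed polygon through pixel centres,
with each step scaled per axis (`cm_per_px_x`, `cm_per_px_y`) and diagonal
steps combining both in the Euclidean norm. We use arc length rather than
a raw pixel-edge count because the stop rule below compares perimeters
across thresholds and needs a metric that is stable under contour
orientation; an edge-count metric overestimates diagonal boundaries by up
to $\sqrt2$. For a single-pixel region the perimeter is 0 by convention.

**Calibration.** Physical pixel size comes from vendor markers. Philips
exports carry a ruler of green dots: a pixel is "green" when G ≥ 100 and
exceeds R and B by a configurable margin (default 60); dots are
8-connected blobs, centroids are unweighted coordinate means, and the
cm-per-pixel factor is the configured dot spacing divided by the median
consecutive centroid gap (the median makes one spurious blob harmless).
GE exports carry a bright scale line in the lower right; pixel width is
the configured line length divided by the line's pixel extent, and pixel
height is assumed equal (symmetric-pixel assumption). Marker spacing and
line length are configuration, not image content — the vendors print them
in cm or mm but the video itself does not encode them; the default is
1.0 cm. An explicit calibration object is the escape hatch when markers
are absent. Areas scale exactly as the product of the two per-axis
factors, so anisotropic pixels are handled throughout.

**The threshold scan.** Thresholds $t = 10, \dots, 30$ are applied in
order; at each, every frame is measured and the frame with the largest
orifice is recorded. The scan stops early at the first $t$ where the
best-contour perimeter differs from the previous threshold's by more than
1.0 cm — an abrupt contour change signalling that the threshold started
merging the orifice with other dark structure — and then selects the
penultimate threshold analysed; otherwise it runs to 30 and selects 30.
Two ambiguities had to be resolved: the perimeter difference is taken in
absolute value, and each threshold independently selects its own best
frame (so consecutive perimeters may belong to different frames). Both
choices are the ones that make the guard symmetric and the per-threshold
records self-contained; the brute-force oracle in the test suite applies
the same rules post hoc to confirm the incremental implementation. A
threshold with no orifice contributes area 0 and perimeter 0, and the jump
test still applies — collapsing from a real contour to nothing is exactly
the instability the guard exists to catch.

**Grading.** MVA ≥ 4.0 cm² is no stenosis, 1.5 < MVA < 4.0 mild,
1.0 ≤ MVA ≤ 1.5 moderate, MVA < 1.0 severe. The boundary convention (4.0
itself is "no stenosis", 1.5 itself "moderate") is the one consistent with
the packaged 30-exam reference cohort, whose 4.0 cm² exam is filed under
no stenosis; looser prose statements of the same intervals ("between 4 and
5 cm²") conflict with it and were rejected. There is deliberately no upper
bound on the no-stenosis grade (the reference cohort contains 7.4 cm²).

## The phantom generator

Clinical recordings are not redistributable, so every stage is validated
on synthetic phantoms with analytic ground truth. A phantom renders what
the engine actually relies on:

- a bright multi-coloured tissue disk (angular colour sectors, radial
  brightness ripple; all luminances well above the top scan threshold);
- a central dark orifice, an ellipse (axis ratio 1.25) or smoothly
  perturbed blob, whose area follows a raised-cosine open–close
  trajectory peaking at a configurable frame with a configurable diastolic
  maximum; ground truth per frame is the *rendered* orifice pixel count
  times the pixel area, so rasterisation is part of the truth;
- dark background touching the border, vendor markers per dialect;
- optional additive Gaussian channel noise, clipped to [0, 255], default
  σ = 8 — strong enough to speckle the binarised masks and exercise the
  perimeter guard, weak enough that tissue and orifice stay separable
  across thresholds 10–30;
- a lower-echogenicity annulus ring (luminance ≈ 69, i.e. above every scan
  threshold and therefore invisible to the planimetry arm) whose radius
  tracks the diastolic orifice size, rendered in *every* frame. Real TEE
  renders show the valve apparatus throughout the cycle — that is why the
  screening CNN is trained on all frames of each video, not only diastolic
  ones — and the ring is the phantom's stand-in for that persistent
  anatomy. Without it, systolic frames of stenotic and non-stenotic
  phantoms would be pixel-identical and frame-level screening accuracy
  would be bounded away from 1 by construction, which would say something
  about the phantom, not the classifier.

Default geometry: 192×192 px, 40 frames, 0.025 cm/px. Grade-labelled
cohorts sample the diastolic MVA uniformly inside each grade's interval,
inset about 5% from the cutoffs so rasterisation cannot flip a label;
severe draws start at 0.3 cm² so the orifice spans enough pixels to be a
meaningful raster object. Rendering is deterministic for a fixed seed and
the AVI container is lossless, so a phantom written twice is
byte-identical.

What a green phantom test establishes: the measurement chain (decode,
calibrate, segment, trace, scale, grade) is numerically correct. What it
does not establish: performance on clinical data — phantoms have no true
ultrasound speckle statistics, no shadowing or dropout, no anatomical
variability, and their class cue is by construction learnable. The
packaged 30-exam reference cohort is a fixture of printed measurements,
not pixel data.

## The screening CNN

Architecture, fixed: four conv(3×3, stride 1, 'same' padding, ReLU) +
max-pool(2×2) stages with filters 32, 64, 128, 256; flatten; dense 512
(ReLU); softmax over 2 classes. Training: Adam (default step 1e-3),
categorical cross-entropy, batch 100, at most 10 epochs, early stopping
monitoring test loss with patience 3 and restoration of the best weights.
Inputs are frames resized by nearest neighbour and divided by 255. The
input resolution is configurable (default 128, divisible by 2⁴; the
acceptance experiment uses 64 to fit a single-CPU time budget — at four
pooling stages an input below 16 px is rejected). Augmentation follows
the stated recipe (rotation ≤ 40°, shifts ≤ 20%, shear, zoom, horizontal
flip, nearest-neighbour fill, six copies per frame); shear and zoom
magnitudes are not pinned anywhere, so both default to 0.2 (≈ 11° of
shear) and are configurable. The video-level verdict is a majority vote
over frame argmaxes with ties going to *has stenosis* — the clinically
conservative direction. Since no deep-learning framework is available in
the supported toolchain, the conv/pool forward and backward passes are
implemented in the package (im2col + GEMM in C++); backpropagation is
verified against numerical differentiation to ~1e-10 relative error in
the test suite.

Two counts in the surrounding workflow are knowingly left configurable
rather than reconciled: the number of whole videos held out per class
(stated as two per class, but validated elsewhere on five videos) and the
epoch accounting of the original experiment (ten configured, eleven
reported, seven relevant). The defaults are two held-out videos per class
and patience 3.

## Numerical conventions

- Grayscale rounding is half-up (`floor(x + 0.5)`), giving a total,
  deterministic mapping; R's default banker's rounding would make results
  depend on parity at exact halves.
- Frame indices are 1-based, as everywhere in R.
- Ties for the maximum-area frame resolve to the earliest frame.
- All randomness (phantom rendering, MVA draws, augmentation, weight
  initialisation, minibatch shuffling) flows through explicit seeds;
  derived seeds stay below 2³¹.
- The AVI container is RIFF with uncompressed 24-bit DIB payloads
  (bottom-up, BGR, 4-byte row stride); in-memory frames are always RGB,
  and the BGR conversion happens only at the container boundary.

## Known limitations

- The decoder reads only the package's own AVI dialect; compressed
  clinical exports need transcoding.
- Orifice detection assumes one dominant enclosed dark region; a frame
  with two near-equal openings reports only the larger.
- The perimeter guard compares best frames across thresholds, which can
  differ; a pathological video alternating between two distinct openings
  could trip the guard without segmentation instability.
- The CNN arm is a screener: it cannot localise, measure, or grade beyond
  the binary verdict, and the desk-scale experiments here say nothing
  about clinical accuracy.
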