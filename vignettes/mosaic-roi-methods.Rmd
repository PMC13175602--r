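---
title: "Mosaic composite inputs and ROI-guided localization evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic composite inputs and ROI-guided localization evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MosaicROI)
```

## The problem this package addresses

In thyroid ultrasound, a classifier can reach a correct benign/malignant
call while attending to tissue far from the nodule a radiologist would point
at. Deciding whether a model's evidence coincides with the expert's region
of interest (ROI) requires two pieces of machinery that are easy to get
subtly wrong: (i) constructing training inputs in which several labeled
nodules share one raster with exactly tracked box coordinates, and (ii)
scoring the overlap between a detected region *D* and the reference ROI *R*
consistently across heatmap-style and box-style detectors. MosaicROI
implements both, together with a synthetic data source and a reference
detector so that every stage is testable end to end.

## Coordinate and raster conventions

Boxes are 0-based, half-open, with x indexing columns and y indexing rows
from the top-left pixel: box $(x, y, w, h)$ covers $[x, x+w) \times
[y, y+h)$. This makes a box's pixel set unambiguous — its rasterization has
exactly $w \cdot h$ one-pixels, translation preserves area, and the tight
bounding box of a rasterized box recovers it exactly. A converter
(`fromOneBasedInclusive`) accepts the 1-based inclusive corner dialect used
by some annotation environments. Intensities are normalized to $[0, 1]$ at
load time, decoupling all downstream computation from the PNG bit depth.
Box coordinates produced by scaling are rounded half-up, which unlike
banker's rounding is platform-stable at ties.

The reference ROIs are handled as rectangles. Whether expert annotations
originate as rectangles or as free-form masks reduced to boxes does not
change the machinery; the rectangular representation is assumed throughout,
and non-rectangular masks are out of scope.

## Composite (mosaic) inputs

A composite places harmonized tiles on a fixed grid. The 2×2 layout fixes
class positions — benign tiles at cells (1,1) and (2,2), malignant at (1,2)
and (2,1) by default — and the 1×2 layout concatenates one benign and one
malignant tile side by side. Class balance is achieved beforehand by
oversampling the minority class with replacement under a seeded generator.
Oversampling precedes pairing: balancing first makes the pairing pool
well-defined and keeps the two steps independently reproducible, and the
alternative order is not observably different downstream. Pairing of sources
into composites is then a seeded shuffle; no pairing scheme is imposed
beyond determinism.

Clinical images come in unequal sizes, and concatenation needs a common tile
size, so each source is *harmonized*: resized preserving aspect ratio to fit
the tile (bilinear, via EBImage), then zero-padded symmetrically. ROI boxes
are scaled by the realized per-axis factors and translated by the padding
offsets; a box that would collapse to zero width or height raises an error
suggesting a larger tile. Every scale and pad parameter is recorded in the
composite's provenance table, so inverting the recorded transform recovers
each source box exactly when no scaling occurred and within 1 px otherwise
(rounding). After harmonization, placing a tile only *translates* its box:
the upper-left corner gains the cell offset while width and height are
preserved.

"Rotational arrangements" of a 2×2 composite are implemented, by default, as
cyclic permutation of the four tiles around the grid (90°, 180°, 270° steps
of the ring (1,1)→(1,2)→(2,2)→(2,1)), not as pixel rotation: the intent of
the arrangements is that every class appears at every grid position during
training, and rotating ultrasound pixels would alter the clinical
orientation of the anatomy. Boxes are regenerated by pure translation, so
area and shape are untouched. A pixel-rotation mode
(`rotationalArrangements(..., mode = "pixels")`, square tiles only) is kept
behind a flag for completeness; it transforms boxes by the corresponding
raster rotation and records the rotation in provenance so source recovery
still inverts it.

## Top-k% regionization of score maps

A score map (a per-pixel non-negative relevance grid, such as a
gradient-based class activation map) is converted to a detected region by
keeping its top $k\%$ of pixels. Two readings of "top $k\%$" exist —
pixel-count percentile versus a fraction of the maximum score value — and
the pixel-count reading is used here: it is invariant to monotone rescaling
of the map and makes the masks at increasing $k$ strictly nested, which in
turn forces IoR to be non-decreasing in $k$ (the qualitative trend one
expects across 30/50/70 columns of an overlap table). The threshold is the
smallest score $t$ such that at least $k\%$ of pixels score $\ge t$; all
pixels tied at $t$ are included, a deterministic and order-independent rule,
and the realized area fraction is reported alongside the request. A constant
map has no rank structure; it returns the full mask with a warning rather
than an arbitrary subset.

## Overlap metrics

With $|\cdot|$ pixel counts, the three localization metrics are

$$\mathrm{IoU} = \frac{|R \cap D|}{|R \cup D|} \times 100, \quad
\mathrm{IoR} = \frac{|R \cap D|}{|R|} \times 100, \quad
\mathrm{IoD} = \frac{|R \cap D|}{|D|} \times 100.$$

IoU is the strictest: $0 \le \mathrm{IoU} \le \min(\mathrm{IoR},
\mathrm{IoD}) \le 100$, and when the intersection is nonempty the three are
tied by $100/\mathrm{IoU} = 100/\mathrm{IoR} + 100/\mathrm{IoD} - 1$. Both
identities are asserted property-style over random box pairs against
closed-form rectangle arithmetic, which serves as the independent oracle for
the rasterized implementation. IoR alone saturates when the detector
over-covers; IoD alone saturates when it under-covers; IoU penalizes both,
which is why a map can cover 86% of the ROI (high IoR) yet spend most of its
mass elsewhere (IoU near 34).

Conventions for edge cases: the reference ROI may never be empty (the
framework presumes an expert box per nodule; an empty $R$ is an error), and
an empty detection yields the all-zero triple with an explicit flag rather
than NaN from $|D| = 0$. Dataset summaries are unweighted per-image means —
a small image counts as much as a large one — rounded to two decimals for
reporting. Among correctly classified images, the fraction with
$\mathrm{IoU} \ge 30\%$ (inclusive) is reported separately for true
positives and true negatives; a class with no correct records is *undefined*
rather than zero.

For 2×2 composites at evaluation time, overlap is scored per nodule, not on
the union over the whole composite: each reference box is compared against
the union of detections whose centers fall in the same grid cell. Per-nodule
scoring keeps one record per lesion (so one composite contributes four
records) and does not let a well-detected nodule mask a missed one, which a
composite-level union would.

## Region-to-image aggregation and classification rates

Two aggregation rules map region-level labels to an image-level call on a
2×2 composite. The *anchor-cell* rule returns the label of the
highest-confidence detection whose box center lies in cell (1,1); detections
are assigned to cells by box-center membership, with centers exactly on a
cell boundary going to the lower-index cell. When nothing lands in (1,1) the
rule falls back to the vote with a flag rather than abstaining — silently
returning nothing would bias rate estimates. The *vote* rule sums detection
confidences per label and takes the heavier side; "aggregating the outputs"
admits several readings (any-malignant, unweighted majority, score sum), and
the confidence-weighted majority is used because it degrades gracefully to
the single-region case and uses the information the detector already
provides. Exact ties are called malignant: in this clinical setting a false
negative (missed cancer) is costlier than a false positive, so the
sensitivity-favoring side wins ties, including regions sitting exactly on
the detector's shape cutoff.

Rates follow the standard confusion definitions with malignant positive:
accuracy $(TP+TN)/(TP+TN+FP+FN)$, sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, each undefined (NA) on a zero denominator and reported to four
decimals. Accuracy is algebraically the prevalence-weighted blend of
sensitivity and specificity, which the tests assert as an identity. Epoch
stability is summarized as mean ± standard deviation over a stated late
window (e.g. epochs 31–40); the *sample* (n−1) deviation is used, the
default estimator for a handful of epochs treated as draws from the
converged regime, and a window of length one reports sd 0 with a flag.

## The phantom generator

The generator emulates the essential structure of a clinical thyroid
ultrasound dataset — grayscale speckle-textured images, one hypoechoic
nodule per image, a tight expert-style ROI box, a benign/malignant label,
and class-imbalanced splits — without modeling echo physics. Background
texture is blurred multiplicative noise (exponential field, Gaussian-blurred
at `speckleGrain` = 1.5 px, scaled to mean 0.5 with relative amplitude
`speckleStrength`). The nodule is an ellipse whose intensity is lowered by
`contrast`; class is encoded in shape following standard sonographic risk
caricatures: benign nodules are wider than tall with sharp margins,
malignant nodules taller than wide (axis ratio 1.25–1.5) with a sinusoidal
radial boundary perturbation (relative amplitude 0.15, 5–9 lobes) and a
Gaussian-blurred margin (1.5 px). The ROI is the tight bounding box of the
rendered support mask, so ground-truth recovery is exact by construction,
and increasing the irregularity amplitude strictly increases the boundary's
$\mathrm{perimeter}^2/(4\pi\,\mathrm{area})$ compactness — the property the
detector's shape rule keys on. Defaults are 128×128 px rasters with nodule
mean diameters of 26–44 px (roughly the relative lesion scale of clinical
crops); `easyPhantomParams()` raises contrast to 0.55 and lowers speckle to
0.12 for pipeline checks where the detector should not be the limiting
factor. Everything is a deterministic function of the seed; dataset
generation derives one seed per image from the master seed.

What the phantoms deliberately do **not** model: acoustic shadowing and
enhancement, cystic or calcified internal texture, multiple nodules, probe
and depth-dependent resolution, and the ambiguity of real lesion margins.
Passing tests on phantoms therefore validate the *bookkeeping and metric*
machinery and the internal consistency of the pipeline — not clinical
detection performance.

## The reference detector

The detector exists so the pipeline has a deterministic stand-in for a
trained network; all thresholds sit in one config block
(`detectorConfig()`). Pipeline: Gaussian smooth (σ = 2 px) → candidate
pixels below min(the 8th intensity percentile, median − 0.10) → connected
components → discard components under 60 px → tight box per component.
The percentile term adapts to the image's intensity distribution; the
absolute `minContrast` guard keeps a blank speckle image from yielding
spurious components out of its own dark tail. Detection confidence is the
component's contrast against the image median scaled by `contrastScale`
(0.35, the default phantom contrast). Region classification applies the
shape rule on the thresholded support: malignant iff height/width ≥ 1 or
compactness ≥ 1.30, with a logistic transform (gain 8) of the margin as
confidence. The cutoffs sit between the generator's class geometries
(benign aspect ≈ 0.7–0.8 and compactness near 1; malignant aspect ≈ 1.3–1.5
or visibly roughened boundaries); they are harness tuning, visible and
documented, not a claim about ultrasound.

## Problem sizes and numerical choices

The test suite exercises: 1,000 random box pairs for the metric oracle; ten
randomized 2×2 datasets (tiles 112 px, sources 90–200 px) for bookkeeping
and provenance inversion; forty random score maps for top-k nesting; and an
end-to-end run of 40 easy-configuration phantoms → 2×2 composites with all
rotational arrangements (40 composites, 160 nodules) → detection →
evaluation, asserting mean IoU ≥ 70 and region-classification accuracy
≥ 0.9 — thresholds that mirror the qualitative claim that ROI-aware
detection attains high overlap, chosen for the easy phantom configuration
before the harness makes them comfortable. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch under a
caller-supplied seed. These sizes keep a full run in tens of seconds on one
CPU while leaving each property's failure modes (rounding, tie handling,
boundary cells, empty detections) well covered.

## Known limitations

- Rectangular ROIs only; free-form masks must be reduced to boxes upstream.
- The 2×2 evaluation assumes detections can be attributed to grid cells by
  box center; a detection straddling a tile boundary is attributed to one
  cell, not split.
- The vote and anchor rules are two points in a larger space of aggregation
  schemes; alternates (any-malignant, score-sum) are not built in beyond the
  config switch between the two provided rules.
- Phantom realism is intentionally limited (above); conclusions about
  clinical detectors require clinical data.
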