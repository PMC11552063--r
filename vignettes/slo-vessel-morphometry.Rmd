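---
title: "Retinal vessel morphometry from SLO images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel morphometry from SLO images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slomorph)
```

## What the package computes

Infrared scanning laser ophthalmoscopy (SLO) produces en face grayscale
images of the retina, typically as localizers alongside OCT capture: a
30-degree field (~9 mm) sampled over 768 or 1536 pixels, i.e. roughly 11.7
or 5.9 microns per pixel. `slomorph` turns such an image, plus a
segmentation of its vasculature, into standard retinal vascular
parameters:

* **vessel density** — segmented vessel pixels over region pixels;
* **fractal dimension** — Minkowski–Bouligand box-counting slope of the
  vessel pattern, a summary of branching complexity;
* **global caliber** — vessel pixels divided by skeleton pixels, the mean
  width of the whole map;
* **local caliber** — per-segment mean width from the Euclidean distance
  transform sampled along the skeleton, aggregated over segments;
* **tortuosity density** — a Grisan-type segment measure combining the
  number of curvature inflections with sub-arc arc-to-chord excess;
* **CRAE / CRVE / AVR** — Knudtson central retinal artery and vein
  equivalents from the six widest branches of each class, and their ratio.

Metrics are computed per vessel class (all/artery/vein) and per region of
interest. Macula-centered scans use the whole image; disc-centered scans
additionally use the peripapillary annuli **zone B** (0.5–1 disc diameters
from the disc margin, i.e. radii 1.0 D–1.5 D from the disc center for a
disc of diameter D) and **zone C** (0–2 diameters, radii 0.5 D–2.5 D).
Density, fractal dimension and global caliber are whole-image metrics
only; local caliber and tortuosity are computed in every region; CRAE,
CRVE and AVR attach to artery, vein and all-vessel records respectively,
in every region.

## Segmentation: pluggable by design

The pipeline treats segmentation as an input. The supported and preferred
path is ingesting externally produced (or manually corrected) masks — a
single label PNG (0 background, 1 artery, 2 vein, 3 crossing, 4 optic
disc) plus optional binary all-vessel and fovea masks. A corrected mask
saved next to the originals with the `_corrected` suffix takes absolute
precedence on a rerun, and only that image's measurements change.

When no masks are given, a classical baseline produces them:

1. the image is resized to the 768×768 working resolution (bilinear);
2. a Frangi-style multiscale Hessian ridge filter (`vesselness()`,
   scales 1–8 px, β = 0.5, scale-normalized eigenvalues, response maximum
   over scales, rescaled to [0, 1]) locates bright curvilinear ridges;
3. `vessel_probability()` converts the peaked ridge response into a
   saturated probability map: ridge crests (response ≥ 0.5) define
   support, and a white top-hat of the image — structuring element wider
   than the largest expected vessel — supplies cross-sectional intensity
   evidence, normalized by half its median value over the crests (the
   half-maximum of a smooth bright profile) and clipped to [0, 1]. This
   mimics the saturated maps a trained segmenter emits, so a fixed 0.5
   threshold recovers most of the vessel width;
4. the fovea detector smooths the image (σ = 15 px) and places a disc of
   radius 60 px at the darkest central minimum, with a peak value scaled
   by the dip depth so flat images fall below the 0.5 threshold and the
   fovea is reported absent; ties break to the leftmost, then topmost
   pixel;
5. the disc detector keeps the largest bright smooth blob after heavy
   smoothing, thresholding above the median, and morphological opening;
6. probability maps are resized back to native resolution and thresholded
   at 0.5 (`p ≥ 0.5` inclusive). Thresholding at native rather than
   working resolution is a documented, switchable choice.

The baseline is deterministic — the same image always yields bit-identical
maps — and is validated on synthetic scenes (all-vessel Dice ≥ 0.80,
fovea localization error ≤ 15 px on clean images). It is a classical
image-processing detector in its own right, not a learned model, and its
artery/vein split (component-wise intensity midpoint split) is a
heuristic that only separates classes not merged by crossings; real-image
artery/vein classification is out of scope.

## Post-processing and landmarks

Binary maps are cleaned by removing 8-connected components below
`postprocess.min_area_px` (default 10 px at 768², scaled quadratically
with resolution; a component exactly at the threshold is kept) and by
bridging small gaps: skeleton endpoints of different components are
joined when the empty gap between the components is at most
`postprocess.max_gap_px` (default 3 px) and the endpoint tangents are
collinear within 30 degrees; the join is drawn at the local vessel width,
so bridging can only merge components, never split them. Both operations
are idempotent. These two parameters are package choices, exposed in the
configuration, not values taken from a publication.

The foveal pit is the centroid of the fovea mask. The optic disc is the
largest component of the disc mask modelled as an ellipse by image
moments (a uniform ellipse with semi-axis a has variance a²/4 along that
axis); its diameter D is the mean of the two axis lengths. The moments
fit was preferred over boundary least squares because it is deterministic,
iteration-free and robust for filled masks. Laterality and location, when
not supplied, are inferred from the landmarks: disc within the central
third of the image width ⇒ disc-centered; otherwise a central fovea ⇒
macula-centered; disc right of the fovea ⇒ right eye (disc in the right
half if the fovea is absent); exact ties resolve to "unknown" rather than
a guess.

Zones treat the fitted disc as a circle of radius D/2 at the ellipse
center, because both annuli are defined by multiples of the single
diameter D; an elliptical-offset variant is available via
`zones.shape = "elliptical"`. Whole-image metrics include vessels inside
the disc by default (`zones.exclude_disc_from_whole` flips this).
Segments crossing a zone boundary contribute only their interior portion
(`zones.boundary_rule = "clip"`; midpoint assignment available).

## Measurement details and numerical choices

**Skeletons and segments.** Skeletonization is Zhang–Suen thinning
(sparse implementation; topology-preserving, 8-connected). Junctions are
pixels where three or more distinct skeleton branches meet, detected by
the crossing number (0→1 transitions around the 8-neighbourhood) rather
than the raw neighbour count, which misfires on diagonal staircases.
Removing junctions splits the skeleton into simple paths; paths shorter
than `metrics.min_segment_len` (10 px at 768², scaled with resolution)
are discarded. Arc length counts 1 per axial and √2 per diagonal step;
the chord is the endpoint distance.

**Caliber.** Per-point width is derived from the Euclidean distance
transform (EDT) at skeleton points. The EDT measures distance between
pixel centers, so a vessel rasterized w pixels wide has EDT (w+1)/2 at
its center line and the width is 2·EDT − 1; when the true medial axis
falls between two pixel rows (even rasterized widths) the discrete EDT
plateaus one half-pixel low, which is detected via a non-skeleton
4-neighbour attaining the same EDT value and corrected by +1. With this
calibration both parities of straight synthetic vessels are recovered
exactly, and the package asserts ±0.5 px recovery for widths 3–15 px.
Region aggregation of segment calibers is arc-length-weighted by default
(`metrics.aggregation = "mean"` for a plain mean).

**Tortuosity density.** For each segment the centerline is lightly
smoothed, resampled at 4 px arc-length spacing (suppressing pixel-level
direction flicker), and partitioned at curvature-sign inflections into n
sub-arcs; the measure is `(n−1)/n + (1/L) Σᵢ (Lᵃᵢ/Lᶜᵢ − 1)` with L the
total arc length. A straight segment gives 0; the measure grows with both
the number of twists and their amplitude. Curvature-sign runs shorter
than 2 resampled points are treated as noise, not inflections.

**Fractal dimension.** Box counting uses dyadic grid sizes from 2 px to a
quarter of the shorter side of the region bounding box, anchored at the
box origin; the dimension is minus the OLS slope of log N(s) on log s,
undefined (NA, with a warning) when fewer than three sizes fit. It is
computed on the full-thickness mask by default; `metrics.fd_on_skeleton`
switches to the skeleton, which shifts values systematically — the flag
exists precisely because the choice matters.

**Knudtson equivalents.** Branch widths are sorted and the current
largest is iteratively paired with the current smallest, each pair
replaced by k·√(w₁² + w₂²) — k = 0.88 for arteries, 0.95 for veins, the
Knudtson revision's branching coefficients — until one value remains; an
odd middle value carries over unchanged. The conventional input is the
mean widths of the six widest segments of the class in the region; with
fewer than six, the largest even number is used with a warning, and with
fewer than two the result is NA. The procedure is permutation-invariant
and positively homogeneous, so pixel and micron results commute with the
scale factor.

Metrics undefined for a class or region are always NA, never 0.

## The synthetic scene generator

Because cohort SLO images cannot ship with the package, every stage is
validated on generated scenes with exact ground truth: a dark background
(0.25), raised-cosine vessel ridges (veins 9–13 px wide at contrast 0.35,
arteries 6–9 px at 0.8× that contrast — giving an artery/vein separator
something to work with), an optional central light-reflex strip (≤ w/3
wide, emulating the bright centerline stripe that can split a wide vessel
into two apparent vessels), a bright ellipse for the disc (~1.5 mm ≈ 128
px diameter, axes 1.1 D × 0.9 D), a dark Gaussian foveal spot (depth
0.12, σ = 30 px), and seeded Gaussian noise (default SD 0.02). Vessel
centerlines are smooth random-walk polylines radiating from the disc
(analytic arc length = summed segment lengths, exact) or parametric
sinusoids (arc length by adaptive quadrature of the exact integrand).
Masks are disc-brush strokes — every pixel within w/2 of the centerline —
so widths are analytically known; calibration fixtures use axis-aligned,
grid-aligned centerlines with butt ends so the rasterized caliber equals
the nominal width exactly. All randomness flows through one injected
seed; scenes are byte-reproducible.

Repeated-pair generation re-renders the same vessel tree under a small
translation and an independent noise realization, emulating unregistered
repeat capture of one eye.

What the generator does **not** emulate: confocal optics, shading and
vignetting, pathology (drusen, hemorrhage), capillary-scale texture, or
realistic artery/vein color/contrast statistics. Passing tests therefore
demonstrate correctness of the measurement machinery on known geometry,
not clinical segmentation performance on real images.

## Reproducibility statistics

For paired repeated measurements per eye the package reports MAE, Pearson
and Spearman correlations, Bland–Altman mean difference with 1.96·SD
limits of agreement (sample SD, n−1), ICC(3,1) — the two-way mixed,
single-measure, consistency intraclass correlation, with the standard
F-based 95% CI; an absolute-agreement variant is exposed but not default —
and the eye-level measurement noise λ: each eye's within-repeat SD as a
percentage of the SD of eye-level means across the population (0 is
optimal; the population denominator uses eye-level means, a documented
choice). Dice uses 2|A∩B|/(|A|+|B|) with dice(∅,∅) := 1; AUC is the
rank-based Mann–Whitney statistic with midranks for ties.

The parameter-recovery simulation draws eye means from N(µ, σb²) and
forms each pair as mean ± σw/√2 with random sign order, so every eye's
within-eye SD equals σw exactly rather than in expectation. Under that
design the estimators must recover median λ = 100·σw/σb and ICC(3,1) =
σb²/(σb² + σw²); the validation suite checks both at n = 200 eyes with
σw/σb = 0.25 (λ ≈ 25%, ICC ≈ 0.941). With Gaussian within-eye noise at
two repeats the per-eye sample SD is half-normal (median ≈ 0.67 σw), so
the fixed-spread design is what makes the stated ratio a per-eye
property; this is deliberate and documented here.

## Problem sizes and determinism

The validation suite and the acceptance script run entirely on generated
data: 768² scenes for pipeline checks, 10-image batches for determinism,
20 straight vessels for caliber calibration, 200 simulated eyes for the
statistics, 512² fixtures for fractal-dimension limits. Batch processing
is lexicographic by filename and every stage is deterministic, so an
unchanged batch reproduces its collated CSV byte for byte; tables are
written atomically (temp file + rename) so interrupted runs never leave
partial output.

## Known limitations

* The baseline artery/vein split is an intensity heuristic that fails
  whenever crossings merge the classes into one component; quantitative
  A/V metrics should come from supplied (or corrected) masks.
* Width estimates below ~3 px are dominated by rasterization; tortuosity
  of segments shorter than ~20 px is noisy.
* Zone areas assume the disc fits the circularized model; strongly
  eccentric discs should use the elliptical zone variant.
* The collated CSV schema is fixed and documented, but is this package's
  convention, not a byte-level match to any other tool's spreadsheet.
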