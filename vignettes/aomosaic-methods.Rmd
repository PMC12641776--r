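---
title: "Morphometry of retinal cell mosaics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of retinal cell mosaics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`aomosaic` quantifies the two cellular monolayers that adaptive-optics (AO)
fundus imaging resolves in vivo: the retinal pigment epithelium (RPE), which
appears as a honeycomb of dim cell centers with bright borders, and the cone
photoreceptor (PR) mosaic, which appears as bright dots on a dark ground.
From a 2048x2048 acquisition with known eye-side, axial length, and
fixation-relative field center, the pipeline produces per-cell morphometry
(Voronoi area in um^2, perimeter in um, neighbor count), per-grid-square
aggregates (local density in cells/mm^2), eccentricity profiles, spatial
heatmaps, PR/RPE descriptor ratios, and cohort statistics.

Because clinical AO acquisitions cannot be redistributed, the package ships a
first-class synthetic-scene generator that emulates the relevant image
structure, and every stage of the analysis is validated against that
generator's ground truth.

## Coordinate system and magnification

**Pixel size.** Retinal magnification is modeled from axial length alone with
the Bennett–Littmann relation, implemented as

```
pixel_size_um = 0.504 * 0.01306 * (axial_length_mm - 1.82) * 6.5
```

a linear map that vanishes at the 1.82 mm nodal-point offset. At a typical
axial length of 24 mm one pixel covers 0.949 um, so a 6.7 degree, 2048-pixel
field spans about 1.94 mm of retina. Axial lengths at or below 1.82 mm are
rejected as invalid biometry rather than clamped. More elaborate
magnification models using additional biometry are out of scope.

**Degrees and eccentricity.** Pixel indices are 0-based and refer to pixel
centers; the image center is at index (N-1)/2, and displacement scales as
`fov_deg / N` degrees per pixel. The horizontal axis is mirrored between
right (OD) and left (OS) eyes inside `pixel_to_global_degrees()` — and only
there — so that +x is temporal for both sides and all downstream code is
side-agnostic. +y is superior; row indices grow downward. Signed
eccentricity is `sign(x) * sqrt(x^2 + y^2)` with `sign(0) = +1`, a
measure-zero convention that avoids a third branch. The coordinate origin is
the *fixation target*, which only approximates the anatomical fovea; the
package records coordinates as fixation-relative and never claims anatomical
registration. A consequence of the pixel-center convention is that the
outermost pixel centers span `(N-1)/N` of the field of view, not the full
field; the image *rectangle* (pixel extents) spans the full field and is
what the Voronoi clipping uses.

## Masking: where cells may be measured

Three boolean layers restrict the analysis, mirroring how AO images fail:

* **quality_visible** — in-focus, analyzable area. The statistic is the
  windowed mean square of a high-pass residual (background removed at twice
  the expected cell spacing; window also twice the spacing), thresholded at
  an absolute level (default `1e-3` on intensities in [0,1]) and
  morphologically closed. Defocused regions lose fine-scale energy and fall
  below threshold; a constant image is entirely non-analyzable; a threshold
  of zero accepts everything.
* **vessel** — retinal vessels, detected as wide dark elongated structures:
  smooth at the vessel scale (sigma 5 px, which suppresses cellular
  texture), mark pixels darker than 0.75 of the smoothed median, and keep
  components that are large (>= 2000 px) and elongated (principal-moment
  ratio >= 2.5). On synthetic ribbons this footprint overlaps the rendered
  ground truth with a Jaccard index above 0.9.
* **mosaic** — the target cellular structure is actually present. Within
  `quality & !vessel`, a pixel is mosaic when the windowed energy of a
  band-pass (difference-of-Gaussians at 0.25/0.50 of the expected spacing)
  response is at least 1.5% of the windowed high-pass energy and above an
  absolute floor. Structureless noise spreads its energy across the spectrum
  and scores an order of magnitude lower on this periodicity ratio than a
  true mosaic does.

Expected cell spacing comes from the hexagonal-packing relation
`density = 2 / (sqrt(3) * spacing^2)` evaluated at a nominal modality
density (6313 cells/mm^2 for RPE, 10,207 for PR), converted to pixels via
the eye's pixel size.

Mask boundaries are only defined up to the analysis window (about two cell
spacings): a defocused patch is excluded reliably in its interior, but the
transition band around it is ambiguous. Tests therefore compare masks away
from ground-truth boundaries, and in heavily artifacted scenes the
transition band depresses measured density by a few percent — an effect
that shrinks with frame size and is absent in clean scenes. This mirrors
the visibility-related bias that any quality-gated in-vivo analysis carries
for older eyes.

The **visible cell mosaic area ratio** — mosaic area over analyzable
(`quality & !vessel`) area — summarizes how much of the *usable* image
actually shows a cellular mosaic. Normalizing by visible rather than total
area separates biological mosaic loss from acquisition artifacts.

## Detection and tessellation

Cell centroids are detected classically (the commercial ML detector that
inspired this interface is proprietary): a difference-of-Gaussians matched
filter at 0.18/0.40 of the expected spacing (computed on the inverted image
for RPE, whose cell centers are dim), non-maximum suppression over a square
window of half-width `0.5 * spacing / sqrt(2)` (which guarantees a minimum
Euclidean separation while never suppressing two true neighbors at
realistic jitter), and an adaptive amplitude threshold at 30% of the 99th
percentile of the in-mosaic response. Only maxima whose pixel lies in the
mosaic mask are kept. The DoG scales were chosen so that adjacent cells at
0.7x spacing — the closest pairs the jitter model produces — remain
separate maxima; broader kernels merge such pairs and bias density low by
2–4%.

The Voronoi tessellation is computed cell-by-cell in C++: each region
starts as the image rectangle and is cut by perpendicular bisectors of
nearby generators, visited in order of increasing distance through a
uniform bucket grid, with the standard termination bound (a generator
farther than twice the current maximum vertex distance cannot cut). This is
exact, deterministic, and linear-time for locally uniform mosaics (a 2048
frame with 24k cells tessellates in ~0.1 s). The test suite checks it
against an independently written brute-force half-plane oracle to 1e-6
relative error, including identical neighbor graphs.

Per-cell measures follow the field's conventions: area and perimeter of the
clipped region scaled by the pixel size; neighbors are regions sharing an
edge of positive length. Regions touching the image rectangle, or whose
polygon reaches outside the mosaic mask, carry `boundary_flag`; they are
*counted* for density but *excluded* from area/perimeter/neighbor summaries,
because truncated regions are geometric artifacts. Mask membership is
decided by the centroid's raster position; regions are clipped to the image
rectangle only, never to mask polygons, so the tessellation depends only on
the centroids and the frame. Exact duplicate centroids are removed with a
warning; fewer than four distinct points is an error.

## The filtering and aggregation cascade

The cascade applies, in order:

1. **Image exclusion**: an image with *strictly more than* 90% of its area
   masked is dropped (mask fraction = 1 - mosaic fraction).
2. **Grid aggregation**: the frame is divided into 256x256-pixel squares
   (64 per image), each cell assigned by its centroid pixel; squares with
   fewer than 200 cells are dropped, which removes small detection islands
   inside masked areas. The count filter includes boundary-flagged cells
   (it is a detection-count criterion, not a geometry one). Local density
   is the cell count over the mosaic-visible area of the square, so partial
   masking does not bias it.
3. **PR central exclusion**: photoreceptor records strictly inside
   (-2.5, 2.5) degrees of eccentricity are removed — the device cannot
   resolve foveal cones. The band is treated as an open interval (a record
   at exactly 2.5 degrees is kept), a measure-zero reading of "between".
   In the image pipeline the same band is also removed from the PR mosaic
   mask *before* detection, so counts and visible areas stay consistent;
   the standalone record filter is then idempotent.
4. **Eccentricity binning**: grid-square summaries are quantized into 25
   equal-width bins over a configurable range, default [-10, +10] degrees,
   and averaged per bin (mean, SD, count). The averaging unit is the grid
   square, consistent with the 200-cell filter; averaging raw cells instead
   would weight squares by their counts.

Heatmaps bin summaries on the coordinate plane at the grid pitch (0.8375
degrees) and smooth with a support-normalized Gaussian of sigma equal to one
sampling distance; unsupported bins stay missing rather than being
interpolated. RPE and PR grid squares of the same eye are matched
nearest-first, one-to-one, within half a grid pitch (0.41875 degrees) —
half-pitch guarantees unambiguous pairing on aligned grids — and unmatched
squares are dropped from ratio profiles.

## Validation statistics

Manual-count validation uses an n-patches x k-raters matrix. Agreement is
ICC(3,k) — two-way mixed, consistency, average of k raters — computed from
the ANOVA decomposition as `(MS_targets - MS_error) / MS_targets`, with the
exact Shrout–Fleiss F-bounds for the confidence interval (not a bootstrap).
The per-patch spread is the min–max range normalized by the mean count, and
the automatic count is compared to the manual range after dividing by the
patch's unmasked fraction (projecting to a full-patch count; scaling the
manual counts down instead is algebraically equivalent for the interval
test). Descriptor–covariate associations are pairwise-complete Pearson
correlations with two-sided t-test p-values, flagged at p < 0.001 and
reported without multiple-testing correction to match the conventional
presentation; Benjamini–Hochberg q-values are provided alongside. Age
trends are ordinary least squares on per-eye mean density; eyes are treated
as independent observations (within-participant correlation is not
modeled), a deliberate replication of common practice in normative studies.
Percentiles throughout use linear interpolation between order statistics.

## The synthetic-scene generator

The generator exists so that detection, tessellation, aggregation, and
statistics can each be tested against known truth. One scene consists of:

* **Centroids** on a jittered hexagonal lattice. Local spacing follows
  `density = 2/(sqrt(3) s^2)` for a density field linear in absolute
  eccentricity (referenced at 0 degrees for RPE, 2.5 degrees for PR) and in
  age. The lattice advances column-by-column along the horizontal axis, so
  the density field is evaluated along the frame's horizontal midline;
  vertical density variation within one frame is not simulated. Jitter is
  uniform within +/-0.15 of the local spacing per coordinate — at that
  amplitude the closest pairs sit near 0.7x spacing, which keeps a
  hexagonal neighbor topology (interior mean neighbor count 6.0) while
  breaking lattice symmetry. Densities implying a spacing below 2 px are
  rejected as sub-resolution.
* **Appearance**: Gaussian blobs (sigma 0.22x spacing) splatted with
  bilinear sub-pixel placement — added to a dark ground for PR, subtracted
  from a bright ground for RPE (dim centers, bright borders).
* **Artifacts**: dark vessel ribbons with a near-flat super-Gaussian cross
  profile and sinusoidal course; structureless visible patches
  (variance-matched white noise, in focus but not mosaic); defocus patches
  (Gaussian blur at 2.5x spacing). Sensor noise (sd 0.05) is added before
  the defocus blur is applied, since defocus acts on everything the camera
  records — this ordering is what makes defocus detectable as a loss of
  fine-scale energy.
* **Aging model**: defocus and non-mosaic patch fractions grow linearly
  with age (defaults 0.05 + 0.005/yr and 0.03 + 0.004/yr above age 23,
  capped at 0.5). The study this design emulates reports visibility loss
  with age qualitatively but gives no quantitative model, so the linear
  ramp is a modeling choice, not an empirical fact; it produces the
  expected sharp decline of the visible-mosaic-area ratio with age. RPE
  density declines at 12 cells/mm^2 per year around a reference age of 50
  (within the range in-vivo and histology reports suggest); PR density is
  age-flat by default; PR density falls at 600 cells/mm^2 per degree of
  eccentricity referenced at 2.5 degrees, reaching ~6300 at 9 degrees.
  Between-eye density random effects (sd 300 RPE / 500 PR cells/mm^2) are
  drawn once per eye in the cohort generator.
* **Cohorts**: ages uniform on 23–80, axial length normal (23.6 +/- 1.1 mm,
  truncated to 21–27), 65% of participants imaged in both eyes, five
  acquisition zones per eye (fixation-centered plus 5-degree offsets in the
  four cardinal directions, reaching ~10 degrees of eccentricity at the
  frame corners). Published sources differ on whether five or six zones
  were used; the zone list is configurable and defaults to five, with the
  numeric centers being package defaults rather than reported values.

What the generator does *not* emulate: optical point-spread/wavefront
physics of the instrument, rod photoreceptors (below the device's
detection threshold), disease patterns (drusen, atrophy), vertical density
gradients within a frame, and anatomical fixation offsets. Passing
recovery tests on these scenes therefore demonstrates the *pipeline's*
correctness on idealized mosaics, not detector performance on clinical
images.

All generators are pure functions of (configuration, seed): the RNG state
is saved and restored around every draw, and repeated calls are
byte-identical.

## Numerical choices and degenerate inputs

* Voronoi neighbor edges count only when longer than 1e-9 px, which also
  guards the oracle comparison; exactly duplicated centroids are
  deduplicated with a warning.
* Image filters use reflect-101 boundary handling; windowed means are
  edge-aware (normalized by the in-frame window size).
* Empty mosaic masks yield an empty centroid list, not an error; an image
  whose detection yields fewer than 4 centroids contributes no cells.
* Grid squares with zero visible area are dropped; empty eccentricity bins
  report count 0 with missing means; a zero-variance rater matrix is an
  explicit error for ICC, as are zero visible area for the area ratio and
  zero mean for the normalized range.
* The non-maximum-suppression window is Chebyshev (square), so the
  guaranteed minimum separation is the window half-width in Euclidean
  terms; the half-width is set to `0.5 s / sqrt(2)` so that diagonal true
  pairs survive.

## Problem sizes used in the shipped experiments

The package's own validation runs at sizes chosen to exercise every code
path at full fidelity where it matters: tessellation topology and density
recovery experiments use full 2048-pixel frames (about 24k RPE or 39k PR
cells per frame), while cohort-level trend experiments use 512-pixel frames
with proportionally scaled grid squares (128 px) and count filters (50
cells), which preserves per-square cell counts within a factor of ~1.5 of
the full-scale setting. The acceptance script reports the full-scale
quantities: the interior mean neighbor count of a jittered honeycomb, and
the pipeline-recovered mean densities of clean RPE and PR scenes generated
at the normative mean densities.

## Known limitations

* The classical detector is tuned for the synthetic appearance model; real
  AO images (speckle, uneven illumination, mixed rod/cone signal) would
  need threshold re-tuning and possibly a learned detector behind the same
  `detect_centroids()` interface.
* Fixation-relative coordinates inherit fixation error; steep foveal
  density gradients are blurred accordingly, and no anatomical (ETDRS)
  mapping is attempted.
* Boundary-truncated cells are excluded from shape summaries by flag; the
  alternative (including them) changes mean area by a few percent at
  512-pixel frames and under 1% at 2048.
* Eyes are treated as independent in all cohort statistics.
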