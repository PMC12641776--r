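# aomosaic

Morphometric characterization of retinal cell mosaics from adaptive-optics
(AO) fundus images, for vision scientists and reading centers that quantify
the retinal pigment epithelium (RPE) and cone photoreceptor (PR) layers in
vivo.

AO fundus cameras resolve two cellular monolayers: the RPE, a honeycomb of
dim cell centers with bright borders, and the cone mosaic, bright dots on a
dark ground. `aomosaic` turns a 2048×2048 acquisition with per-eye metadata
(eye side, axial length, fixation-relative field center) into normative
morphometry:

- **Magnification and coordinates.** Pixel size from axial length by the
  Bennett–Littmann relation, `pixel size (µm) = 0.504 · 0.01306 ·
  (AL − 1.82) · 6.5`; pixel → degree mapping with the horizontal axis
  mirrored between OD and OS so +x is temporal for both eyes; signed
  eccentricity `e = sign(x)·√(x² + y²)` (temporal positive, nasal negative).
- **Masking.** Quality (focus), vessel, and mosaic-presence masks restrict
  the analysis to regions where cells are actually measurable.
- **Detection + tessellation.** Classical difference-of-Gaussians centroid
  detection matched to the expected cell spacing, then an exact clipped
  Voronoi tessellation (Rcpp) giving per-cell area (µm²), perimeter (µm),
  and neighbor counts, with boundary-truncated regions flagged.
- **Aggregation cascade.** Exclusion of images more than 90% masked;
  256×256-px grid squares keeping only squares with ≥ 200 cells; local
  density = cells / mosaic-visible area (cells/mm²); removal of PR records
  within ±2.5° of fixation; 25-bin eccentricity profiles; Gaussian-smoothed
  density heatmaps; one-to-one RPE↔PR grid-square matching for PR/RPE
  descriptor ratios.
- **Statistics.** Gender-stratified summary tables (mean, median, SD,
  quartiles); ICC(3,k) with Shrout–Fleiss confidence bounds, normalized
  min–max range, and the adjusted within-range check for manual-count
  validation; Pearson correlation matrices with p < 0.001 flags; linear age
  trends.
- **Synthetic scenes.** A first-class generator of AO-like cohorts —
  jittered hexagonal mosaics with configurable density fields (eccentricity
  and age slopes), vessels, defocus and non-mosaic patches — with ground
  truth, so every stage is testable without clinical data.

## Worked example

Render a clean synthetic RPE scene at the normative mean density and push it
through the full pipeline:

```r
library(aomosaic)

eye <- eye_meta("P001_OD", side = "OD", age = 40, gender = "female",
                axial_length = 24)
scene <- render_mosaic_image(eye, center_deg = c(5, 0),
                             model = clean_mosaic_model("RPE", 6313),
                             seed = 1, image_size = 512L)
res <- analyze_image(scene$record, default_config())
gs <- grid_summaries(res$cells, res$masks, scene$record,
                     grid_px = 128L, min_cells = 50L)
mean(gs$local_density); mean(gs$mean_neighbors)
```

which prints

```
pixel size: 0.949 um;  cells detected: 1493
retained grid squares: 16
mean local density: 6324 cells/mm^2 (generated at 6313)
mean Voronoi neighbors (interior cells): 5.998
mean cell area: 158.5 um^2;  mean perimeter: 47.3 um
```

The recovered density is within 0.2% of the generating value; 5.998
neighbors reflects the near-hexagonal packing of an RPE mosaic (the
Euler-formula limit is 6 for interior cells). Mean area × density ≈ 1 — the
two descriptors are duals on fully visible mosaic.

Whole cohorts run through `simulate_cohort()` + `run_pipeline()`, which
emit per-image cell tables, grid summaries, eccentricity profiles, PR/RPE
ratio tables, stratified summary tables, age trends, correlation matrices,
a filter-bookkeeping manifest, and a markdown report.

## Package layout

- `R/optics.R` — magnification, coordinates, eccentricity
- `R/masks.R`, `R/detect.R`, `R/voronoi.R`, `src/` — masking, detection,
  tessellation (Rcpp core)
- `R/aggregate.R` — the filtering/aggregation cascade
- `R/stats.R` — summary and validation statistics
- `R/synthetic.R` — cohort and scene generators
- `R/pipeline.R`, `R/io.R` — orchestration, configuration, report, file I/O
- `vignettes/aomosaic-methods.Rmd` — models, parameter choices, and
  limitations in detail
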