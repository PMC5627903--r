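# endomosaic

Quantitative viability assessment of corneal endothelial grafts from
calcein-AM fluorescence images, with a fully ground-truthed synthetic
endothelial-mosaic generator to validate every step.

DMEK (Descemet membrane endothelial keratoplasty) grafts are a single layer
of non-regenerating endothelial cells on a basement membrane; how many of
those cells survive preparation and insertion decides the clinical outcome.
Calcein AM stains metabolically active cells brightly while attached dead
cells and bare membrane stay near black, so a single fluorescence image of
the graft *in situ* carries a whole-graft viability map. `endomosaic` is for
researchers who want to quantify such images — or to test an analysis
pipeline against synthetic grafts whose per-cell truth is known exactly.

## What it computes

* **Patch photometry.** Mean fluorescence over 25×25-pixel arrays; per-patch
  signal-to-noise ratio `SNR = mean / SD`; fluorescence contrast
  `C = mean viable patch fluorescence / mean non-viable patch fluorescence`,
  with a bootstrap CI. The peripheral rim serves as the standard non-viable
  reference region.
* **ROC-calibrated threshold segmentation.** Sensitivity/specificity sweep of
  integer grey-level cutoffs for classifying patches as viable (positive
  class, strict `mean > t`), trapezoidal AUC, and whole-graft segmentation of
  the viable area at the calibrated cutoff (40 grey levels by default):
  `viable area fraction = viable pixels / graft-disc pixels`, with
  `damage fraction = 1 − viable area fraction`.
* **Cell-scale morphometry.** ITCN-style nuclear counting by smoothed
  local-maxima detection; endothelial cell density (cells/mm²);
  hexagonality (% of cells with exactly six Voronoi neighbours); coefficient
  of variation of cell area `CoV = SD(area)/mean(area)`; percent dead cells
  from co-registered live/dead channels.
* **Method agreement.** Bland–Altman analysis of paired density estimates
  (bias = mean(reference − test), 95% limits of agreement bias ± 1.96·SD,
  t-based CI of the bias) and Pearson correlation.
* **Staining kinetics.** `I(dose, t) = slope · dose · min(t/2, 1) ·
  exp(−k·max(0, t−2))`: linear in dose, peaking 2 h after incubation, then
  decaying at a storage-dependent rate (fast in organ culture at 37 °C, very
  slow in Optisol at 4 °C), plus OLS fits for dose–response and decay.
* **Synthetic grafts.** Centroidal-Voronoi cell mosaics on an 8-mm disc with
  surgical damage primitives (peripheral rim, incarceration wedge, ejection
  streaks, polygon patches, tears, orientation mark), rendered to 8-bit
  fluorescence images through a calibrated intensity model (Gaussian PSF,
  additive read noise, nuclear contrast, a configurable fraction of nuclei
  rendered without contrast) — with exact per-cell ground truth.

## Worked example

Simulate a damaged graft, image it, and measure it back:

```r
library(endomosaic)

spec <- mosaic_spec(graft_diameter = 8, target_density = 2500, rng_seed = 42)
gt <- generate_mosaic(spec)
gt <- apply_damage(gt, damage_spec(
  damage_rim(200, mode = "dead_attached"),
  damage_wedge(center_angle = 120, angular_width = 45,
               radial_depth_um = 1200)))
glance(gt)
#> # A tibble: 1 × 6
#>   n_cells density_cells_mm2 live_density_cells_mm2 viable_fraction ...
#> 1  125664             2500.                  2126.           0.851

render <- calibrate_render(target_contrast = 15.41, target_snr = 14.27)
img <- render_mosaic(gt, render, seed = 42)

mask <- detect_graft_mask(img)
mask
#> <graft_mask> center (849.6, 849.4) px, radius 799.8 px, area 50.24 mm^2

report <- segment_viable(img, mask, threshold = 40, truth = gt)
report
#> <viability_report> threshold 40: viable area 85.3%, damage 14.7%
#>   vs truth: sensitivity 1, specificity 0.992, Dice 0.999
```

The true viable fraction was 85.1%; threshold-40 segmentation reports 85.3%
and agrees with the pixel truth at Dice 0.999. Damage attribution assigns the
detected non-viable area back to the simulated lesions:

```r
attribute_damage(report, gt)
#> # A tibble: 2 × 8
#>   primitive type  mode          footprint_px footprint_mm2 detected_px recall
#> 1         1 rim   dead_attached       196028          4.90      191998  0.979
#> 2         2 wedge bare_dm             128182          3.20      127397  0.994
```

Patch photometry on the same image recovers the calibrated optical
parameters:

```r
reg <- patch_regions(dim(img), mask$center, mask$radius, 40)
pv <- sample_patches(img, mask = reg$viable & report$viable, n = 50,
                     label = "viable", seed = 1)
pn <- sample_patches(img, mask = reg$non_viable, n = 50,
                     label = "non_viable", min_coverage = 1, overlap = TRUE,
                     seed = 2)
patch_contrast(dplyr::bind_rows(pv, pn))
#> <contrast_result> contrast 15.6 (95% CI 15.41-15.86); viable mean 101.9
#>   over 50 patches, non-viable mean 6.53 over 50
mean(pv$snr)
#> [1] 14.22
```

`patch_roc()` adds the threshold sweep (with `autoplot()` for the ROC
curve), `paired_density_benchmark()` + `bland_altman()` reproduce the
density-agreement analysis, `field_morphometry()` summarizes
high-magnification fields (density, hexagonality, area CoV, % dead), and
`run_pipeline()` chains detection, segmentation and photometry over a
longitudinal image series with one seeded configuration.

## Vignette

`vignettes/endothelial-viability.Rmd` describes the intensity model and its
calibration, the mosaic generator, the detection and segmentation
algorithms, every tunable default with its units and rationale, and what
passing synthetic benchmarks does and does not say about real images.
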