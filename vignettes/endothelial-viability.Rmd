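---
title: "Methods: synthetic endothelial mosaics and calcein viability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic endothelial mosaics and calcein viability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`endomosaic` quantifies corneal endothelial graft viability from single-channel
calcein-AM fluorescence images and provides a ground-truthed simulator of such
images. This vignette is the package's own account of the underlying models,
the defaults and their rationale, and the limits of what the synthetic
benchmarks demonstrate.

## The measurement problem

A DMEK graft is an 8-mm trephined disc of Descemet membrane carrying a
monolayer of corneal endothelial cells. Calcein AM is cleaved by intracellular
esterases to fluorescent calcein, so metabolically active cells with intact
membranes fluoresce brightly; attached dead cells retain almost no dye and are
only marginally brighter than bare membrane from which cells have been
scraped. A scanning-laser ophthalmoscope image of the stained graft inside the
eye therefore encodes a whole-graft viability map on an 8-bit grey scale. The
package's analysis layer turns such images into: patch photometry (contrast,
SNR), a threshold viability segmentation, cell-scale morphometry, and
method-agreement statistics for density estimates.

Because no public image set with per-cell truth exists for this assay, the
package pairs the analysis with a generator whose truth is exact by
construction. Every analysis claim the test suite makes is a *recovery* claim:
simulate at known parameters, measure, and compare against the generator's
record.

## The mosaic generator

**Geometry.** `generate_mosaic()` seeds `round(density × π(d/2)²)` points
uniformly in the graft disc and applies Lloyd relaxation toward the centroidal
Voronoi tessellation, clipped to the disc. The tessellation is computed on the
pixel raster itself (bucketed nearest-seed assignment in C++): cell areas,
adjacency, and the viable-area fraction are then exact with respect to the
raster, and the raster *is* the ground truth against which pixelwise
segmentation is scored. Boundary polygons, when exported to JSON, are traced
from the label raster. Relaxation runs on a grid coarsened to roughly five
pixels per cell width — centroids move by far less than a cell width per
iteration, so finer grids only add cost — and the final assignment is at full
resolution.

Defaults: 8 mm graft, 2500 cells/mm² (mid-range for transplant-grade donor
tissue, whose usable range runs roughly 1700–3600 cells/mm²), 10 Lloyd
iterations. Ten iterations produce area CoV ≈ 0.19 and hexagonality ≈ 50%,
values typical of healthy endothelium; `regularity = 0` gives a Poisson–Voronoi
mosaic (CoV ≈ 0.5) useful as a degraded-regularity comparator.

**Nuclei.** Each cell's nucleus sits at its centroid plus a uniform jitter of
at most 15% of the equivalent cell radius. The nucleus radius is 0.27 of the
*mean* cell radius, constant across cells: endothelial nuclei vary far less
than cell footprints, and a constant nuclear size keeps the rendered nuclear
peak height narrowly distributed, which is what makes a fixed prominence
threshold meaningful for counting (see Detection below).

**Damage.** Damage primitives (`damage_rim`, `damage_wedge`,
`damage_streaks`, `damage_polygon`, `damage_tear`, `damage_mark`) are analytic
footprints in the graft frame, applied in order; a cell whose centroid falls
in a footprint switches to the primitive's mode — `dead_attached` (cells
present, non-viable) or `bare_dm` (cells absent). This mirrors the
surgical phenotypes seen in wet-lab practice: trephination/handling kills a
peripheral rim, wound incarceration kills a wedge, graft ejection scrapes
linear streaks, and the peripheral orientation mark removes a small triangle
of tissue. The default rim is 200 µm of attached dead cells (~10% of graft
area, the low end of reported iatrogenic damage).
`calibrate_streak_damage()` bisects the streak width so the residual viable
fraction lands on a requested target (e.g. 0.73 for the ejected-graft
scenario); viable fraction is monotone in streak width, so bisection is exact
up to cell granularity.

**Rendering.** `render_mosaic()` paints per-state means (0 outside the
graft), overlays nucleus discs for viable cells, convolves with a Gaussian
PSF, adds Gaussian read noise *after* blurring (so patch SD is directly
controlled), clips to [0, 255] and quantizes to 8 bits. A seeded fraction
`undetectable_nucleus_fraction` of viable cells is rendered flat, without
nuclear contrast; those cells are invisible to nuclear peak counting on the
calcein channel and are the modelled mechanism for the known under-count of
calcein-based density estimates (default 0.075, chosen so the paired density
benchmark at 2500 cells/mm² under-counts by ≈ 187 cells/mm²; the
measured bias, not its mechanism, is the published quantity). Companion
channels emulate counterstains: `nuclei` marks all attached cells' nuclei,
`dead` only attached dead ones. Shot noise is not modelled — no photon-count
information is available to fit it — and illumination is uniform.

Intensity defaults put viable cytoplasm at 100 grey, nuclei at 130 (nuclear
staining exceeds cytoplasmic), attached dead tissue 3 grey above bare
membrane, and interpret the published "grey units" on the 8-bit 0–255 export
scale. The PSF default is 1.2 px at the global 5 µm/px view, leaving single
cells unresolved as in 30° whole-graft imaging; high-magnification fields
default to 0.8 µm/px where cells and nuclei are resolved. The pixel pitch of
the original instrument exports is not published; both pitches are
configurable and all geometry is specified in micrometres.

**Calibration.** `calibrate_render()` fixes the two free intensity parameters
against photometric targets (defaults: contrast 15.41, viable-patch SNR
14.27). The viable-patch mean µ_v and the within-patch *structural* variance
(the blurred nucleus/cytoplasm mix) are measured on a noiseless render of a
small calibration graft; the read-noise SD is then
`sqrt((µ_v / SNR_target)² − var_struct)` (an error if structural variance
alone exceeds the target — the requested SNR would need negative noise). The
non-viable rim mean is solved through the clipped-noise model: a region with
true mean d and noise σ has observed mean `d·Φ(d/σ) + σ·φ(d/σ)` after
clipping at 0, and this is inverted with `uniroot` so the *observed* rim mean
equals `µ_v / contrast_target`. A seeded Monte-Carlo self-check (200 rendered
patches) must reproduce both targets within 5% or calibration aborts.
Kinetic scaling multiplies viable intensities by
`I(dose, t, storage) / I(2.67 µM, 2 h)`.

**Staining kinetics.** `I = slope·dose · min(t/2, 1) · exp(−k·max(0, t−2))`,
with dose in µM and t in hours. Decay constants are fixed by published
whole-tissue endpoint pairs: organ culture at 37 °C falls 109 → 36 grey over
the 24 h following the 2-h peak (`k = ln(109/36)/24 ≈ 0.0462 h⁻¹`), Optisol
at 4 °C falls 99 → 89 over 7 days (`k = ln(99/89)/168 ≈ 6.3×10⁻⁴ h⁻¹`), so
both endpoint ratios hold by construction. The exponential form itself is an
assumption — only endpoint pairs are published — and the linear rise to the
2-h peak is a convenience; nothing downstream depends on the pre-peak shape.
The dose slope default (109/2.67 grey/µM) places the standard 2.67 µM dose at
its observed peak brightness.

## The analysis layer

**Patch photometry.** Patches are 25×25 px squares; mean and *population* SD
are computed over all 625 pixels; SNR = mean/SD. Auto-sampling draws
non-overlapping patches by rejection within a region mask, requiring ≥ 90% of
the patch area inside the mask (configurable; region masks are additionally
eroded by 4 px before sampling so patches do not straddle blurred region
boundaries). Overlap can be permitted where a region is too small to pack the
requested patches disjointly — for means this only correlates estimates
slightly; the narrow peripheral rim annulus is the usual case. Contrast is
the ratio of group mean-of-means with a seeded 2000-resample bootstrap CI.
The non-viable reference defaults to the peripheral rim annulus, and the
calibration targets that same reference, so contrast measured on default
grafts recovers the calibration target.

**ROC.** Thresholds sweep the integer grey levels 0–255. "Viable" is the
positive class and classification is strict (`mean > t`), so cutoff 40
excludes a patch mean of exactly 40. Sensitivity is non-increasing in t by
construction; AUC is the trapezoid over the swept curve with the
all-positive corner appended; the Youden-optimal cutoff breaks ties toward
the lower threshold. The implementation is cross-checked in the tests against
a brute-force double loop and, for AUC, against an independent ROC package
on integer-valued data (where the integer sweep is exact).

**Graft detection.** The bright viable core is segmented by Otsu's threshold
on a smoothed copy; all substantial connected components are kept (damage
streaks can sever the core), and a circle is fitted (Kasa least squares) to
the convex hull of the component boundary to fix the center. The graft
*radius* is then read off the radial mean-intensity profile about that
center: the outermost shelf at least 1.5 grey above background is found, and
the edge is placed at the half-maximum crossing of the local shelf height.
The half-maximum rule is unbiased whether the outermost tissue is the bright
core (no rim damage) or a dim dead rim barely above background — a global
histogram threshold cannot serve both cases, which is why detection is
profile-based. Degenerate inputs (flat images, pure noise, no component
covering 1% of the image) raise "no graft found" errors.

**Segmentation.** Pixels strictly above the cutoff (default 40) inside the
graft mask are viable. Morphological cleanup removes viable specks below 5
nominal cell areas and fills non-viable holes below 1 cell area: at SNR ≈ 14
noise speckle is sub-cellular, so these defaults cannot delete real lesions,
and cleanup can be disabled (`min_object_px = 0, min_hole_px = 0`; the
monotonicity-in-threshold property is stated and tested for the cleanup-free
map). Viable and damage fractions sum to 1 exactly over mask pixels. The
published damage range is area-based, so the headline fraction is area-based;
cell-count summaries remain available from the ground truth
(`true_live_density`). When truth is supplied, pixelwise sensitivity,
specificity and Dice are reported against the truth raster.

**Nuclear detection.** ITCN-style counting re-implemented as smoothed
local-maxima detection: Gaussian smoothing at 0.2× the expected cell width; a
maximum filter over a disc of diameter 0.7× cell width (the minimum peak
separation); a prominence floor of 5 grey levels measured against the
minimum-filtered image over a cell-width disc; tied plateaus collapse to
their centroid; points return in raster order. The original plugin's
parameters are unpublished; these defaults are set so that recall on the
clean nuclei channel is ≈ 1 at the default render, making the nuclei channel
a faithful reference method, while the calcein channel misses exactly the
cells rendered without nuclear contrast. The grayscale minimum filter is the
complemented maximum filter, since the installed image library's erosion is
binary-only.

**Morphometry.** Neighbour analysis builds the discrete Voronoi tessellation
of the detected centroids on a raster (~30 px per cell width, capped at
4000² cells), counts as neighbours cells sharing at least 2 boundary pixel
pairs — so corner-point contacts, as in a square lattice, do not count, which
is the documented resolution of the four-fold degeneracy — and excludes cells
whose region touches the field boundary (standard morphometry practice).
Hexagonality is the percentage of interior cells with exactly six
neighbours. Area CoV uses the population SD. `dead_fraction()` de-duplicates
points across channels within a matching radius, resolving conflicts to dead
(the dead stain is the specific one). Report-grade morphometry expects at
least 1000 analyzed cells; smaller fields warn.

**Agreement.** Bland–Altman differences are `reference − test` with the
nuclear-counterstain count as reference, so a positive bias reads directly as
"the calcein method under-counts". Limits of agreement use the 1.96 normal
quantile (a t-quantile variant is available); the bias CI is t-based;
differences are absolute (cells/mm²), matching how the bias is reported in
the field. Pearson correlation comes from the standard t transform
(`cor.test`).

## Benchmark problem sizes

The acceptance benchmarks run at the full study geometry: ten 8-mm grafts at
2500 cells/mm² (≈ 126,000 cells each) for contrast/SNR recovery with 50
viable + 50 peripheral patches per graft; twenty damaged-graft patch
benchmarks for the cutoff-40 operating point; twenty 0.56-mm
high-magnification fields for the density-bias benchmark; one streak-damaged
graft calibrated to 73% true viability for segmentation recovery. Unit tests
use 1–3-mm grafts, which exercise identical code paths at lower cell counts.

## What the synthetic benchmarks do and do not show

The generator reproduces the *photometric* structure of the assay — bimodal
intensities, calibrated contrast and SNR, nuclear contrast, a dim dead rim,
realistic damage geometry, and realistic mosaic regularity. Passing its
benchmarks shows the measurement code is correct and unbiased under that
model. Real images additionally contain non-uniform illumination, optical
(pincushion) distortion at wide field, motion and frame-averaging artefacts,
scrolled or folded graft geometry, out-of-focus regions, and spatially
correlated biological heterogeneity (dead-attached tissue contiguous with
bare cores). None of these are modelled; the package deliberately makes no
claim that threshold 40 or the detection defaults transfer to other
instruments without recalibration. The ROC machinery exists precisely so a
user can recalibrate the cutoff on their own labelled patches.

## Known limitations

* Raster-native geometry: cell polygons are pixel-exact, not algebraic;
  sub-pixel morphometry at the global 5 µm/px view is not meaningful (use
  the high-magnification pitch for cell-scale work).
* The decay model is exponential by assumption, anchored to two published
  endpoint pairs per storage condition.
* Graft detection assumes one roughly circular graft on a darker background;
  severely fragmented or folded grafts violate the radial-profile model and
  are reported via the non-circularity warning.
* `dead_fraction()` removes every live point within the matching radius of a
  dead point; in extremely dense fields with radius close to the cell
  spacing this can over-remove.
* The pipeline compares time points by summary statistics only; there is no
  image registration across time points.
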