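#' Simulate a complete graft: mosaic, damage, calibrated render
#'
#' Convenience wrapper producing the standard study object: a default-geometry
#' graft (8 mm, 2500 cells/mm^2, 5 um/px global view), the requested damage,
#' and a calcein render under the calibrated default render spec (contrast
#' 15.41, viable-patch SNR 14.27).
#'
#' @param seed Seed for mosaic generation and rendering.
#' @param damage A [damage_spec()]; the default peripheral dead rim when
#'   omitted. `NULL` applies no damage.
#' @param density Target density, cells/mm^2.
#' @param diameter Graft diameter, mm.
#' @param pixel_size Pixel pitch, um/px.
#' @param render A [render_spec()]; the cached calibrated default when
#'   omitted.
#' @param channels Channels to render (see [render_mosaic()]).
#' @return A list: `gt` (the `endomosaic`), `image` (or named list of
#'   channels), `render` (the render spec used).
#' @export
simulate_graft <- function(seed = 1, damage = default_damage(),
                           density = 2500, diameter = 8, pixel_size = 5,
                           render = NULL, channels = "calcein") {
  spec <- mosaic_spec(graft_diameter = diameter, target_density = density,
                      pixel_size = pixel_size, rng_seed = seed)
  gt <- generate_mosaic(spec)
  if (!is.null(damage)) gt <- apply_damage(gt, damage)
  if (is.null(render)) render <- calibrate_render()
  img <- render_mosaic(gt, render, seed = seed + 7919, channels = channels)
  list(gt = gt, image = img, render = render)
}

#' Standard labelled-patch benchmark
#'
#' Builds the patch sets the threshold classifier is assessed on: a graft
#' with the default dead peripheral rim, an incarceration wedge (dead border
#' around a bare core) and linear streaks, rendered under the calibrated
#' defaults; 50 viable and 50 non-viable 25x25 patches are drawn from the
#' ground-truth state rasters (patches need only 90% coverage of their
#' region, so some straddle boundaries — the realistic heterogeneity that
#' costs sensitivity and specificity).
#'
#' @param seed Seed controlling the graft, damage placement and sampling.
#' @param n_per_class Patches per class.
#' @param diameter,density,pixel_size Graft geometry.
#' @return A labelled patch tibble (see [sample_patches()]).
#' @export
patch_benchmark <- function(seed = 1, n_per_class = 50, diameter = 8,
                            density = 2500, pixel_size = 5) {
  ang <- withr::with_seed(seed, runif(2, 0, 360))
  dmg <- damage_spec(
    damage_rim(200, mode = "dead_attached"),
    damage_wedge(center_angle = ang[1], angular_width = 50,
                 radial_depth_um = 1300, mode = "dead_attached"),
    damage_wedge(center_angle = ang[1], angular_width = 40,
                 radial_depth_um = 1100, mode = "bare_dm"),
    damage_streaks(count = 3, width_um = 150, orientation = ang[2],
                   spacing_um = 900, mode = "bare_dm"))
  sim <- simulate_graft(seed, damage = dmg, diameter = diameter,
                        density = density, pixel_size = pixel_size)
  st <- mosaic_state_raster(sim$gt)
  pv <- sample_patches(sim$image, mask = st == 1L, n = n_per_class,
                       label = "viable", seed = seed + 1)
  pn <- sample_patches(sim$image, mask = st > 1L, n = n_per_class,
                       label = "non_viable", seed = seed + 2)
  dplyr::bind_rows(pv, pn)
}

#' Simulate a high-magnification field with companion channels
#'
#' Generates a small mosaic at high-magnification pixel pitch (0.8 um/px by
#' default), renders calcein, nuclear-counterstain and dead channels, and
#' crops a central square field away from the graft edge. The field carries
#' its ground truth (cells whose nucleus lies inside the window).
#'
#' @param seed Mosaic/render seed.
#' @param density Target density, cells/mm^2.
#' @param dead_fraction Fraction of in-field cells converted to attached-dead
#'   (scattered single cells), 0 for an all-viable field.
#' @param pixel_size Pixel pitch, um/px.
#' @param diameter Carrier graft diameter, mm.
#' @param field_px Side of the cropped field, px.
#' @param render A [render_spec()]; calibrated default when omitted.
#' @return A list: `calcein`, `nuclei`, `dead` (fluorescence images),
#'   `truth` (tibble of in-field cells), `area_mm2`, `params`
#'   (calcein-channel [detection_params()]).
#' @export
simulate_field <- function(seed = 1, density = 2500, dead_fraction = 0,
                           pixel_size = 0.8, diameter = 0.9,
                           field_px = 700, render = NULL) {
  spec <- mosaic_spec(graft_diameter = diameter, target_density = density,
                      pixel_size = pixel_size, rng_seed = seed)
  gt <- generate_mosaic(spec)
  if (dead_fraction > 0) {
    kill <- withr::with_seed(seed + 13,
                             runif(nrow(gt$cells)) < dead_fraction)
    gt$cells$state[kill] <- "dead_attached"
  }
  if (is.null(render)) render <- calibrate_render()
  imgs <- render_mosaic(gt, render, seed = seed + 7919,
                        channels = c("calcein", "nuclei", "dead"))
  n <- gt$spec$image_size
  if (field_px > n) stop("field larger than the rendered image", call. = FALSE)
  lo <- floor((n - field_px) / 2) + 1
  hi <- lo + field_px - 1
  crop <- function(im) fluorescence_image(im$data[lo:hi, lo:hi], pixel_size)
  # field window in the graft frame (um), for the truth record
  c_px <- gt$center_px[["x"]]
  w_lo <- (lo - 1 - c_px) * pixel_size
  w_hi <- (hi - 1 - c_px) * pixel_size
  truth <- dplyr::filter(gt$cells,
                         .data$nucleus_x_um >= w_lo, .data$nucleus_x_um <= w_hi,
                         .data$nucleus_y_um >= w_lo, .data$nucleus_y_um <= w_hi)
  list(calcein = crop(imgs$calcein), nuclei = crop(imgs$nuclei),
       dead = crop(imgs$dead), truth = truth,
       area_mm2 = (field_px * pixel_size)^2 / 1e6,
       params = detection_params(cell_width_px(density, pixel_size)))
}

#' Paired density benchmark: calcein counts vs nuclear counterstain counts
#'
#' Simulates all-viable high-magnification fields and estimates cell density
#' twice per field: from calcein local maxima (misses cells rendered without
#' nuclear contrast) and from the nuclear counterstain channel (sees every
#' attached cell). The paired table feeds [bland_altman()]; its bias measures
#' the systematic calcein under-count.
#'
#' @param n_fields Number of fields.
#' @param seed Base seed; field `i` uses `seed + i`.
#' @param density Target density, cells/mm^2.
#' @param ... Passed to [simulate_field()].
#' @return A tibble: `field`, `truth_density`, `hoechst`, `calcein`
#'   (cells/mm^2).
#' @export
paired_density_benchmark <- function(n_fields = 20, seed = 1,
                                     density = 2500, ...) {
  rows <- purrr::map(seq_len(n_fields), function(i) {
    f <- simulate_field(seed = seed + i, density = density, ...)
    pts_cal <- detect_nuclei(f$calcein, f$params)
    pts_nuc <- detect_nuclei(f$nuclei, nuclei_channel_params(f$params))
    tibble::tibble(
      field = i,
      truth_density = nrow(f$truth) / f$area_mm2,
      hoechst = nrow(pts_nuc) / f$area_mm2,
      calcein = nrow(pts_cal) / f$area_mm2)
  })
  dplyr::bind_rows(rows)
}
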