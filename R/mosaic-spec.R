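#' Specify the geometry of a synthetic endothelial graft
#'
#' A `mosaic_spec` fixes everything the mosaic generator needs: the trephined
#' graft diameter, the target endothelial cell density, how far the cell
#' tessellation is relaxed toward a centroidal Voronoi mosaic, and the imaging
#' raster (pixel pitch and image side). Donor endothelial densities of roughly
#' 1700--3600 cells/mm^2 are realistic for transplant-grade tissue; the default
#' of 2500 cells/mm^2 sits in the middle of that range.
#'
#' @param graft_diameter Graft diameter in mm (an 8-mm trephine punch by
#'   default).
#' @param target_density Target endothelial cell density, cells per mm^2.
#' @param regularity Number of Lloyd relaxation iterations applied to the cell
#'   seed points; 0 gives a plain Poisson-Voronoi mosaic, ~10 a visibly
#'   regular, near-hexagonal mosaic.
#' @param pixel_size Physical pixel pitch in micrometres per pixel. 5 um/px
#'   corresponds to a global whole-graft view, 0.8 um/px to a
#'   high-magnification field in which single cells are resolved.
#' @param image_size Image side in pixels. Defaults to the graft diameter in
#'   pixels plus a 100-px margin.
#' @param rng_seed Integer seed controlling all randomness in mosaic
#'   generation; identical specs generate identical mosaics.
#'
#' @return An object of class `mosaic_spec`.
#' @seealso [generate_mosaic()]
#' @export
#' @examples
#' mosaic_spec(target_density = 3000, rng_seed = 7)
mosaic_spec <- function(graft_diameter = 8,
                        target_density = 2500,
                        regularity = 10,
                        pixel_size = 5,
                        image_size = NULL,
                        rng_seed = 1) {
  stopifnot(graft_diameter > 0, target_density > 0, pixel_size > 0,
            regularity >= 0, regularity == round(regularity))
  d_px <- graft_diameter * 1000 / pixel_size
  if (is.null(image_size)) image_size <- ceiling(d_px) + 100
  if (d_px > image_size) {
    stop("graft does not fit in the image: diameter is ", round(d_px),
         " px but image_size is ", image_size, " px", call. = FALSE)
  }
  structure(
    list(graft_diameter = graft_diameter, target_density = target_density,
         regularity = as.integer(regularity), pixel_size = pixel_size,
         image_size = as.integer(image_size), rng_seed = as.integer(rng_seed)),
    class = "mosaic_spec")
}

#' @export
print.mosaic_spec <- function(x, ...) {
  cat("<mosaic_spec> ", x$graft_diameter, " mm graft, ",
      x$target_density, " cells/mm^2, regularity ", x$regularity,
      ", ", x$pixel_size, " um/px, ", x$image_size, " px image, seed ",
      x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Specify how a mosaic is rendered to a fluorescence image
#'
#' Region mean intensities are on the 8-bit 0--255 grey-level scale. Viable
#' cytoplasm is bright, viable nuclei brighter still (esterase product
#' accumulates in the nucleus), attached dead cells are only marginally
#' brighter than bare Descemet membrane, and bare membrane is near black. The
#' point-spread function is an isotropic Gaussian; zero-mean Gaussian read
#' noise is added after blurring, then the image is clipped to \[0, 255\] and
#' quantized to 8 bits.
#'
#' A fraction of viable cells is rendered without nuclear contrast
#' (`undetectable_nucleus_fraction`); such cells carry no local intensity
#' maximum and are invisible to nuclear peak counting on the calcein channel,
#' which is what makes calcein-based density estimates under-count.
#'
#' @param cytoplasm_mean,nucleus_mean,dead_attached_mean,bare_dm_mean Region
#'   mean intensities (grey levels, 0--255).
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param noise_sigma Additive Gaussian noise SD in grey levels (post-blur).
#' @param undetectable_nucleus_fraction Probability that a viable cell's
#'   nucleus is rendered at cytoplasm intensity.
#' @param dose Calcein-AM incubation dose in micromolar.
#' @param time_since_stain Hours since the start of incubation.
#' @param storage `"organ_culture_37C"` or `"optisol_4C"`; sets the
#'   post-peak decay rate of the staining-kinetics model.
#'
#' @return An object of class `render_spec`.
#' @seealso [render_mosaic()], [calibrate_render()], [staining_intensity()]
#' @export
render_spec <- function(cytoplasm_mean = 100,
                        nucleus_mean = 130,
                        dead_attached_mean = 8,
                        bare_dm_mean = 5,
                        psf_sigma = 1.2,
                        noise_sigma = 6.5,
                        undetectable_nucleus_fraction = 0.075,
                        dose = 2.67,
                        time_since_stain = 2,
                        storage = c("organ_culture_37C", "optisol_4C")) {
  storage <- match.arg(storage)
  means <- c(cytoplasm_mean, nucleus_mean, dead_attached_mean, bare_dm_mean)
  if (any(means < 0) || any(means > 255)) {
    stop("region mean intensities must lie in [0, 255]", call. = FALSE)
  }
  if (dead_attached_mean <= bare_dm_mean) {
    stop("dead_attached_mean must exceed bare_dm_mean (attached dead cells ",
         "are marginally brighter than bare membrane)", call. = FALSE)
  }
  if (nucleus_mean <= cytoplasm_mean) {
    stop("nucleus_mean must exceed cytoplasm_mean", call. = FALSE)
  }
  stopifnot(psf_sigma >= 0, noise_sigma >= 0,
            undetectable_nucleus_fraction >= 0,
            undetectable_nucleus_fraction <= 1,
            dose >= 0, time_since_stain >= 0)
  structure(
    list(cytoplasm_mean = cytoplasm_mean, nucleus_mean = nucleus_mean,
         dead_attached_mean = dead_attached_mean, bare_dm_mean = bare_dm_mean,
         psf_sigma = psf_sigma, noise_sigma = noise_sigma,
         undetectable_nucleus_fraction = undetectable_nucleus_fraction,
         dose = dose, time_since_stain = time_since_stain, storage = storage),
    class = "render_spec")
}

#' @export
print.render_spec <- function(x, ...) {
  cat("<render_spec> cytoplasm ", round(x$cytoplasm_mean, 2), ", nucleus ",
      round(x$nucleus_mean, 2), ", dead ", round(x$dead_attached_mean, 2),
      ", bare DM ", round(x$bare_dm_mean, 2), " grey; psf ", x$psf_sigma,
      " px; noise sd ", round(x$noise_sigma, 2), "; ",
      100 * x$undetectable_nucleus_fraction, "% nuclei undetectable\n",
      sep = "")
  invisible(x)
}
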