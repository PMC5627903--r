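#' Render a ground-truth mosaic to fluorescence images
#'
#' Paints each pixel at its cell-state mean intensity (viable cytoplasm,
#' attached-dead, bare membrane; 0 outside the graft), overlays nucleus discs
#' at `nucleus_mean` for viable cells — except a seeded random fraction
#' `undetectable_nucleus_fraction` rendered without nuclear contrast —
#' convolves with the Gaussian point-spread function, adds seeded Gaussian
#' read noise, clips to \[0, 255\] and quantizes to 8 bits. Viable-cell
#' intensities are scaled by the staining-kinetics factor implied by the
#' spec's dose, time since staining and storage condition (1 at the default
#' 2.67 uM / 2 h peak).
#'
#' Optional companion channels mirror counterstains: `"nuclei"` marks the
#' nuclei of all attached (non-absent) cells, `"dead"` only those of
#' attached dead cells; both are rendered with the same PSF and noise model.
#'
#' @param gt An `endomosaic`.
#' @param spec A [render_spec()].
#' @param seed Seed for the undetectable-nucleus draw and the noise.
#' @param channels Subset of `c("calcein", "nuclei", "dead")`.
#' @return A single [fluorescence_image()] when one channel is requested,
#'   otherwise a named list of them.
#' @export
render_mosaic <- function(gt, spec = render_spec(), seed = 1,
                          channels = "calcein") {
  stopifnot(inherits(gt, "endomosaic"), inherits(spec, "render_spec"))
  channels <- match.arg(channels, c("calcein", "nuclei", "dead"),
                        several.ok = TRUE)
  px <- gt$pixel_size
  kin <- staining_intensity(spec$dose, spec$time_since_stain, spec$storage) /
    staining_intensity(2.67, 2)
  cells <- gt$cells
  nuc_x <- gt$center_px[["x"]] + cells$nucleus_x_um / px
  nuc_y <- gt$center_px[["y"]] + cells$nucleus_y_um / px
  nuc_r <- cells$nucleus_r_um / px

  out <- withr::with_seed(seed, {
    undetect <- runif(nrow(cells)) < spec$undetectable_nucleus_fraction
    res <- list()
    for (ch in channels) {
      if (ch == "calcein") {
        means <- c(viable = spec$cytoplasm_mean * kin,
                   dead_attached = spec$dead_attached_mean,
                   absent = spec$bare_dm_mean)
        lut <- c(0, means[cells$state])
        base <- matrix(lut[gt$labels + 1L], nrow = nrow(gt$labels))
        vis <- cells$state == "viable" & !undetect
        base <- cpp_draw_discs(base, nuc_x[vis], nuc_y[vis], nuc_r[vis],
                               rep(spec$nucleus_mean * kin, sum(vis)))
      } else {
        keep <- if (ch == "nuclei") cells$state != "absent"
                else cells$state == "dead_attached"
        base <- matrix(0, nrow(gt$labels), ncol(gt$labels))
        base <- cpp_draw_discs(base, nuc_x[keep], nuc_y[keep], nuc_r[keep],
                               rep(220, sum(keep)))
      }
      m <- blur_image(base, spec$psf_sigma)
      if (spec$noise_sigma > 0) {
        m <- m + matrix(rnorm(length(m), sd = spec$noise_sigma),
                        nrow = nrow(m))
      }
      res[[ch]] <- fluorescence_image(pmin(pmax(round(m), 0), 255), px)
    }
    res
  })
  if (length(out) == 1) out[[1]] else out
}

# expected value of round(clip(N(mu, sigma), 0, 255)); lower clip only,
# which is the regime of the dim non-viable regions
clipped_normal_mean <- function(mu, sigma) {
  if (sigma <= 0) return(max(0, mu))
  mu * pnorm(mu / sigma) + sigma * dnorm(mu / sigma)
}

#' Calibrate a render spec to target contrast and SNR
#'
#' Solves for the bare-membrane intensity and the read-noise SD such that
#' patch photometry on rendered grafts reproduces a target viable/non-viable
#' contrast ratio and a target viable-patch SNR. The within-patch structural
#' variance contributed by the nucleus/cytoplasm intensity mix is measured on
#' a noiseless render of a small calibration graft, so the noise SD accounts
#' for it; the non-viable (peripheral dead-cell rim) mean is solved through
#' the clipped-noise model, since near-black regions gain apparent mean from
#' clipping at 0. The returned spec is verified by a seeded Monte-Carlo
#' self-check (rendered patches must reproduce both targets within 5%).
#'
#' @param target_contrast Target viable/non-viable contrast ratio (> 1).
#' @param target_snr Target viable-patch mean/SD ratio (> 1).
#' @param base Starting [render_spec()]; cytoplasm/nucleus means, PSF and
#'   nucleus geometry are taken from it.
#' @param density Cell density of the calibration graft, cells/mm^2.
#' @param rim_width_um Width of the non-viable reference rim, um.
#' @param seed Seed for the calibration renders.
#' @return A calibrated `render_spec`.
#' @export
#' @examples
#' \donttest{
#' spec <- calibrate_render(15.41, 14.27)
#' spec
#' }
calibrate_render <- function(target_contrast = 15.41, target_snr = 14.27,
                             base = render_spec(), density = 2500,
                             rim_width_um = 200, seed = 1089) {
  if (target_contrast <= 1) {
    stop("target_contrast must exceed 1 (no separation otherwise)",
         call. = FALSE)
  }
  if (target_snr <= 1) stop("target_snr must exceed 1", call. = FALSE)
  key <- rlang::hash(list(target_contrast, target_snr, base, density,
                          rim_width_um, seed))
  if (!is.null(the$calibration_cache[[key]])) {
    return(the$calibration_cache[[key]])
  }

  cal_spec <- mosaic_spec(graft_diameter = 2, target_density = density,
                          pixel_size = 5, rng_seed = seed)
  gt <- generate_mosaic(cal_spec)
  gt <- apply_damage(gt, damage_rim(rim_width_um, mode = "dead_attached"))
  regions <- patch_regions(dim(gt$labels), gt$center_px, gt$radius_px,
                           rim_width_um / gt$pixel_size)

  # structural variance and viable mean from a noiseless render
  spec0 <- base
  spec0$noise_sigma <- 0
  img0 <- render_mosaic(gt, spec0, seed = seed)
  pv <- sample_patches(img0, mask = regions$viable, n = 150,
                       min_coverage = 1, overlap = TRUE, seed = seed)
  mu_v <- mean(pv$mean)
  var_struct <- mean(pv$sd^2)
  sd_target <- mu_v / target_snr
  if (var_struct >= sd_target^2) {
    stop("structural variance alone (", signif(sqrt(var_struct), 4),
         " grey) exceeds the patch SD implied by target_snr (",
         signif(sd_target, 4), "); reduce nuclear contrast or the target",
         call. = FALSE)
  }
  noise_sigma <- sqrt(sd_target^2 - var_struct)

  # solve the rim (dead-attached) mean through the clipped-noise model
  m_nv <- mu_v / target_contrast
  dead <- uniroot(function(d) clipped_normal_mean(d, noise_sigma) - m_nv,
                  lower = -4 * noise_sigma, upper = m_nv + 4 * noise_sigma,
                  tol = 1e-8)$root
  bare <- dead - (base$dead_attached_mean - base$bare_dm_mean)
  if (bare < 0) {
    warning("calibrated bare-membrane mean clipped to 0")
    bare <- 0
  }
  out <- base
  out$noise_sigma <- noise_sigma
  out$dead_attached_mean <- dead
  out$bare_dm_mean <- bare

  # Monte-Carlo self-check on rendered patches
  img <- render_mosaic(gt, out, seed = seed + 1)
  pv <- sample_patches(img, mask = regions$viable, n = 100, label = "viable",
                       min_coverage = 1, overlap = TRUE, seed = seed + 2)
  pn <- sample_patches(img, mask = regions$non_viable, n = 100,
                       label = "non_viable", min_coverage = 1, overlap = TRUE,
                       seed = seed + 3)
  got_contrast <- mean(pv$mean) / mean(pn$mean)
  got_snr <- mean(pv$snr)
  if (abs(got_contrast / target_contrast - 1) > 0.05 ||
      abs(got_snr / target_snr - 1) > 0.05) {
    stop("calibration self-check failed: rendered contrast ",
         signif(got_contrast, 4), " vs target ", target_contrast,
         ", SNR ", signif(got_snr, 4), " vs target ", target_snr,
         call. = FALSE)
  }
  if (is.null(the$calibration_cache)) the$calibration_cache <- list()
  the$calibration_cache[[key]] <- out
  out
}
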