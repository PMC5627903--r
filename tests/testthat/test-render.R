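test_that("a noiseless unblurred render is piecewise constant at region means", {
  gt <- generate_mosaic(mosaic_spec(graft_diameter = 1, pixel_size = 2,
                                    rng_seed = 2))
  gt <- apply_damage(gt, damage_spec(
    damage_wedge(center_angle = 0, angular_width = 60, radial_depth_um = 300,
                 mode = "dead_attached"),
    damage_wedge(center_angle = 180, angular_width = 60,
                 radial_depth_um = 300, mode = "bare_dm")))
  spec <- render_spec(cytoplasm_mean = 100, nucleus_mean = 130,
                      dead_attached_mean = 8, bare_dm_mean = 5,
                      psf_sigma = 0, noise_sigma = 0)
  img <- render_mosaic(gt, spec, seed = 1)
  expect_setequal(unique(as.vector(as.matrix(img))), c(0, 5, 8, 100, 130))
})

test_that("an all-absent mosaic renders at the bare-membrane level", {
  gt <- generate_mosaic(mosaic_spec(graft_diameter = 1, pixel_size = 2,
                                    rng_seed = 3))
  gt$cells$state[] <- "absent"
  spec <- render_spec(bare_dm_mean = 20, dead_attached_mean = 23,
                      noise_sigma = 4)
  img <- render_mosaic(gt, spec, seed = 5)
  inside <- gt$labels > 0
  expect_equal(mean(as.matrix(img)[inside]), 20, tolerance = 0.05)
  expect_gt(sd(as.matrix(img)[inside]), 3)
})

test_that("renders are deterministic in the seed", {
  sim <- fix_small_sim()
  img2 <- render_mosaic(sim$gt, sim$render, seed = 21 + 7919)
  expect_identical(as.matrix(img2), as.matrix(sim$image))
  img3 <- render_mosaic(sim$gt, sim$render, seed = 999)
  expect_false(identical(as.matrix(img3), as.matrix(sim$image)))
})

test_that("the calibrated default render reproduces contrast and SNR targets", {
  spec <- fix_cal_spec()
  expect_gt(spec$dead_attached_mean, spec$bare_dm_mean)
  # independent graft, not the calibration mosaic
  sim <- fix_small_sim()
  gm <- sim$mask
  reg <- patch_regions(dim(as.matrix(sim$image)), gm$center, gm$radius,
                       200 / 5)
  pv <- sample_patches(sim$image, mask = reg$viable, n = 40,
                       label = "viable", seed = 31)
  pn <- sample_patches(sim$image, mask = reg$non_viable, n = 40,
                       label = "non_viable", min_coverage = 1, overlap = TRUE,
                       seed = 32)
  ctr <- patch_contrast(dplyr::bind_rows(pv, pn))
  expect_equal(ctr$contrast, 15.41, tolerance = 0.10)
  expect_equal(mean(pv$snr), 14.27, tolerance = 0.10)
})

test_that("the pixel histogram of a calibrated graft is bimodal at the region means", {
  sim <- fix_small_sim()
  m <- as.matrix(sim$image)
  inside <- sim$gt$labels > 0
  d <- density(m[inside], bw = 2)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  peaks <- peaks[d$y[peaks] > 0.05 * max(d$y)]
  modes <- sort(d$x[peaks])
  expect_gte(length(modes), 2)
  expect_lt(abs(modes[1] - sim$render$dead_attached_mean), 5)
  expect_lt(abs(modes[length(modes)] - sim$render$cytoplasm_mean), 5)
})

test_that("calibration rejects impossible targets", {
  expect_error(calibrate_render(target_contrast = 1), "exceed 1")
  # an SNR so high that structural variance alone exceeds the implied SD
  expect_error(calibrate_render(target_snr = 200), "structural variance")
})

test_that("companion channels mark the right nuclei", {
  f <- fix_field()
  # dead channel of an all-viable field is background only
  expect_lt(mean(as.matrix(f$dead)), 5)
  # nuclei channel carries one bright blob per attached cell
  expect_gt(max(as.matrix(f$nuclei)), 150)
})

test_that("patch SNR and contrast are invariant under intensity scaling", {
  sim <- fix_small_sim()
  m <- as.matrix(sim$image)
  loc <- tibble::tibble(x = c(200, 300), y = c(260, 330))
  p1 <- sample_patches(m, locations = loc)
  p2 <- sample_patches(m * 1.7, locations = loc)  # pre-clipping scale
  expect_equal(p2$snr, p1$snr, tolerance = 1e-12)
  expect_equal(p2$mean / p1$mean, rep(1.7, 2), tolerance = 1e-12)
})
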