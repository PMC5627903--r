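test_that("graft detection recovers the simulated disc geometry", {
  sim <- fix_small_sim()
  gm <- sim$mask
  expect_lt(abs(gm$center[["x"]] - sim$gt$center_px[["x"]]), 2)
  expect_lt(abs(gm$center[["y"]] - sim$gt$center_px[["y"]]), 2)
  expect_lt(abs(gm$radius - sim$gt$radius_px) / sim$gt$radius_px, 0.01)
  # mask area of a 3-mm graft at 5 um/px
  expect_equal(sum(gm$mask), pi * 300^2, tolerance = 0.02)
})

test_that("images without a graft are rejected", {
  expect_error(detect_graft_mask(matrix(0, 200, 200), pixel_size = 5),
               "no graft")
  noise <- withr::with_seed(2, matrix(rnorm(200 * 200, 50, 3), 200))
  expect_error(detect_graft_mask(noise, pixel_size = 5), "no graft")
})

test_that("thresholding is strict and fraction bounds are exact", {
  mask <- matrix(TRUE, 80, 80)
  r39 <- segment_viable(matrix(39, 80, 80), mask, pixel_size = 5)
  expect_equal(r39$viable_area_fraction, 0)
  r41 <- segment_viable(matrix(41, 80, 80), mask, pixel_size = 5)
  expect_equal(r41$viable_area_fraction, 1)
  r40 <- segment_viable(matrix(40, 80, 80), mask, pixel_size = 5)
  expect_equal(r40$viable_area_fraction, 0)  # cutoff 40 excludes value 40
  expect_error(segment_viable(matrix(41, 80, 80), mask, threshold = 300,
                              pixel_size = 5), "255")
  expect_equal(r41$viable_area_fraction + r41$damage_fraction, 1)
})

test_that("viable fraction is monotone non-increasing in the threshold", {
  sim <- fix_small_sim()
  vf <- vapply(seq(0, 250, by = 25), function(t) {
    segment_viable(sim$image, sim$mask, threshold = t,
                   min_object_px = 0, min_hole_px = 0)$viable_area_fraction
  }, numeric(1))
  expect_true(all(diff(vf) <= 0))
})

test_that("segmentation matches the truth raster almost pixel-perfectly", {
  sim <- fix_small_sim()
  rep <- segment_viable(sim$image, sim$mask, truth = sim$gt)
  expect_gt(rep$metrics$dice, 0.95)
  expect_equal(rep$viable_area_fraction, true_viable_fraction(sim$gt),
               tolerance = 0.03)
})

test_that("cleanup removes speckle but keeps real damage", {
  sim <- fix_small_sim()
  m <- as.matrix(sim$image)
  # inject an isolated sub-cell bright speck in the dead rim
  yx <- round(sim$gt$center_px[["y"]]) + c(0, 1)
  m[yx, round(sim$gt$center_px[["x"]]) + 292 + 0:1] <- 200
  rep <- segment_viable(m, sim$mask, pixel_size = 5)
  rep_raw <- segment_viable(m, sim$mask, min_object_px = 0, min_hole_px = 0,
                            pixel_size = 5)
  expect_lt(rep$viable_area_fraction, rep_raw$viable_area_fraction)
})

test_that("damage attribution credits footprints and reports leakage", {
  gt <- generate_mosaic(mosaic_spec(graft_diameter = 3, rng_seed = 77))
  gt <- apply_damage(gt, damage_wedge(center_angle = 45, angular_width = 72,
                                      radial_depth_um = 900,
                                      mode = "bare_dm"))
  img <- render_mosaic(gt, fix_cal_spec(), seed = 6)
  gm <- detect_graft_mask(img)
  rep <- segment_viable(img, gm, truth = gt)
  att <- attribute_damage(rep, gt)
  expect_equal(nrow(att), 1)
  expect_equal(att$type, "wedge")
  expect_gte(att$recall, 0.9)
  expect_false(att$overlaps_other)
  expect_true(attr(att, "leakage_px") >= 0)

  # overlapping primitives are credited to both and flagged
  gt2 <- apply_damage(gt, damage_rim(150, mode = "dead_attached"))
  img2 <- render_mosaic(gt2, fix_cal_spec(), seed = 7)
  rep2 <- segment_viable(img2, detect_graft_mask(img2), truth = gt2)
  att2 <- attribute_damage(rep2, gt2)
  expect_true(all(att2$overlaps_other))

  # no damage: empty table, leakage equals all detected non-viable area
  gt0 <- generate_mosaic(mosaic_spec(graft_diameter = 2, pixel_size = 2,
                                     rng_seed = 5))
  img0 <- render_mosaic(gt0, fix_cal_spec(), seed = 8)
  rep0 <- segment_viable(img0, matrix(gt0$labels > 0, nrow(gt0$labels)),
                         pixel_size = 2)
  att0 <- attribute_damage(rep0, gt0)
  expect_equal(nrow(att0), 0)
  expect_equal(attr(att0, "leakage_px"),
               sum(rep0$mask & !rep0$viable))
})
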