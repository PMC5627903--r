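small_gt <- function(seed = 9) {
  generate_mosaic(mosaic_spec(graft_diameter = 2, pixel_size = 2,
                              rng_seed = seed))
}

test_that("an empty damage spec is the identity", {
  gt <- small_gt()
  gt2 <- apply_damage(gt, damage_spec())
  expect_identical(gt$cells, gt2$cells)
  expect_equal(true_viable_fraction(gt2), 1)
})

test_that("cell counts are conserved under any damage composition", {
  gt <- small_gt()
  dmg <- damage_spec(
    damage_rim(150, mode = "dead_attached"),
    damage_wedge(center_angle = 30, angular_width = 45,
                 radial_depth_um = 400, mode = "bare_dm"),
    damage_streaks(count = 3, width_um = 80, orientation = 120,
                   spacing_um = 300),
    damage_mark(cbind(c(-50, 50, 0), c(-980, -980, -860))))
  out <- apply_damage(gt, dmg)
  expect_equal(nrow(out$cells), nrow(gt$cells))
  states <- table(out$cells$state)
  expect_equal(sum(states), nrow(gt$cells))
  expect_true(all(c("viable", "dead_attached", "absent") %in% names(states)))
})

test_that("a peripheral rim spares the center and removes the annulus share", {
  gt <- small_gt()
  out <- apply_damage(gt, damage_rim(width_um = 200, mode = "dead_attached"))
  r <- sqrt(out$cells$x_um^2 + out$cells$y_um^2)
  expect_true(all(out$cells$state[r < 750] == "viable"))
  expect_true(all(out$cells$state[r > 820] == "dead_attached"))
  # central live density unchanged
  central <- r < 500
  expect_equal(sum(out$cells$state[central] == "viable"), sum(central))
  expect_equal(1 - true_viable_fraction(out), 1 - (1 - 200 / 1000)^2,
               tolerance = 0.015)
})

test_that("later primitives override earlier ones where they overlap", {
  gt <- small_gt()
  out <- apply_damage(gt, damage_spec(
    damage_rim(300, mode = "dead_attached"),
    damage_rim(150, mode = "bare_dm")))
  r <- sqrt(out$cells$x_um^2 + out$cells$y_um^2)
  expect_true(all(out$cells$state[r > 870] == "absent"))
  expect_true(all(out$cells$state[r > 720 & r < 830] == "dead_attached"))
})

test_that("a primitive outside the graft warns and is a no-op", {
  gt <- small_gt()
  far <- damage_polygon(cbind(c(2000, 2100, 2050), c(2000, 2000, 2100)))
  expect_warning(out <- apply_damage(gt, far), "no cells")
  expect_identical(out$cells, gt$cells)
  expect_length(out$damage, 0)
})

test_that("streak damage can be calibrated to a target viable fraction", {
  gt <- apply_damage(small_gt(), damage_rim(100, mode = "dead_attached"))
  cal <- calibrate_streak_damage(gt, target = 0.73)
  expect_equal(cal$achieved, 0.73, tolerance = 0.01)
  expect_equal(true_viable_fraction(cal$gt), cal$achieved)
  expect_error(calibrate_streak_damage(cal$gt, target = 0.9),
               "already at or below")
})

test_that("tears and orientation marks carve their footprints", {
  gt <- small_gt()
  torn <- apply_damage(gt, damage_tear(cbind(c(-900, -400), c(0, 150)),
                                       gape_um = 120))
  expect_lt(true_viable_fraction(torn), 1)
  marked <- apply_damage(gt, damage_mark(cbind(c(-60, 60, 0),
                                               c(-990, -990, -850))))
  expect_true(any(marked$cells$state == "absent"))
  expect_gt(true_viable_fraction(marked), 0.99)
})
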