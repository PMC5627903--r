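test_that("a single Gaussian blob yields one detection at its center", {
  m <- matrix(0, 120, 120)
  xs <- matrix(rep(0:119, each = 120), 120); ys <- t(xs)
  m <- 80 * exp(-((xs - 61)^2 + (ys - 57)^2) / (2 * 4^2))
  pts <- detect_nuclei(m, detection_params(cell_width_px = 25))
  expect_equal(nrow(pts), 1)
  expect_lt(abs(pts$x - 61), 1.01)
  expect_lt(abs(pts$y - 57), 1.01)
})

test_that("a rendered grid of nuclei is recovered point for point", {
  centers <- expand.grid(x = seq(20, 290, by = 30), y = seq(20, 290, by = 30))
  m <- matrix(100, 310, 310)
  m <- endomosaic:::cpp_draw_discs(m, centers$x, centers$y,
                                   rep(4, nrow(centers)),
                                   rep(130, nrow(centers)))
  m <- endomosaic:::blur_image(m, 1.5)
  pts <- detect_nuclei(m, detection_params(cell_width_px = 30))
  expect_equal(nrow(pts), nrow(centers))
  mm <- match_points(pts, centers, radius = 2)
  expect_equal(mm$recall, 1)
})

test_that("separation and plateau rules are honoured", {
  m <- matrix(0, 60, 400)
  expect_error(detect_nuclei(m, detection_params(cell_width_px = 100)),
               "larger than the image")
  # an exact plateau collapses to its centroid
  m2 <- matrix(0, 60, 60); m2[28:31, 28:31] <- 50
  pts <- detect_nuclei(m2, detection_params(cell_width_px = 20,
                                            smooth_sigma = 0.01,
                                            prominence = 5))
  expect_equal(nrow(pts), 1)
  expect_equal(pts$x, 28.5)
  expect_equal(pts$y, 28.5)
})

test_that("channel recall matches the rendered nucleus visibility", {
  f <- fix_field()
  tr <- field_truth_px(f)
  rad <- f$params$cell_width_px / 2
  mc <- match_points(detect_nuclei(f$calcein, f$params), tr, radius = rad)
  mn <- match_points(detect_nuclei(f$nuclei, nuclei_channel_params(f$params)),
                     tr, radius = rad)
  expect_gte(mn$recall, 0.99)
  expect_equal(mc$recall, 0.925, tolerance = 0.035)
  expect_gte(mc$precision, 0.95)
})

test_that("greedy point matching agrees with the optimal assignment", {
  skip_if_not_installed("igraph")
  f <- fix_field()
  tr <- field_truth_px(f)[1:150, ]
  det <- detect_nuclei(f$nuclei, nuclei_channel_params(f$params))
  det <- det[det$x < max(tr$x) + 20 & det$y < max(tr$y) + 20, ]
  rad <- f$params$cell_width_px / 2
  mm <- match_points(det, tr, radius = rad)
  # optimal-assignment oracle: maximum bipartite matching on the radius graph
  d2 <- outer(det$x, tr$x, "-")^2 + outer(det$y, tr$y, "-")^2
  idx <- which(d2 <= rad^2, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    c(rep(TRUE, nrow(det)), rep(FALSE, nrow(tr))),
    as.vector(t(cbind(idx[, 1], nrow(det) + idx[, 2]))))
  opt <- igraph::max_bipartite_match(g)$matching_size
  expect_equal(nrow(mm$matches), opt)
})

test_that("density estimation is count over area", {
  pts <- tibble::tibble(x = runif(250), y = runif(250))
  expect_equal(estimate_density(pts, 0.1)$density_cells_mm2, 2500)
  expect_equal(estimate_density(pts[0, ], 0.1)$density_cells_mm2, 0)
  expect_error(estimate_density(pts, 0), "positive")
})

test_that("nuclei-channel density is an unbiased estimate of truth", {
  f <- fix_field()
  pts <- detect_nuclei(f$nuclei, nuclei_channel_params(f$params))
  d <- estimate_density(pts, f$area_mm2, "nuclei_channel")
  expect_equal(d$density_cells_mm2, nrow(f$truth) / f$area_mm2,
               tolerance = 0.03)
})

test_that("hexagonality of reference lattices is exact", {
  hx <- expand.grid(i = 0:19, j = 0:19)
  hex <- data.frame(x = hx$i + 0.5 * (hx$j %% 2), y = hx$j * sqrt(3) / 2)
  na <- neighbor_analysis(hex)
  expect_equal(na$hexagonality, 100)
  expect_true(all(na$cells$n_neighbors[na$cells$interior] == 6))

  sq <- expand.grid(x = 0:19, y = 0:19)
  sq <- withr::with_seed(1, dplyr::mutate(sq, x = x + runif(400, -1e-6, 1e-6),
                                          y = y + runif(400, -1e-6, 1e-6)))
  ns <- neighbor_analysis(sq)
  expect_equal(ns$hexagonality, 0)
  expect_true(all(ns$cells$n_neighbors[ns$cells$interior] == 4))

  expect_error(neighbor_analysis(data.frame(x = 1:5, y = 2 * (1:5) + 1)),
               "collinear")
})

test_that("neighbour counts satisfy the handshake identity", {
  gt <- generate_mosaic(mosaic_spec(graft_diameter = 1, pixel_size = 1,
                                    rng_seed = 14))
  adj <- endomosaic:::cpp_adjacency(gt$labels, nrow(gt$cells))
  deg <- tabulate(c(adj$i, adj$j), nbins = nrow(gt$cells))
  expect_equal(sum(deg), 2 * length(adj$i))
})

test_that("hexagonality is invariant under similarity transforms", {
  gt <- generate_mosaic(mosaic_spec(graft_diameter = 1, pixel_size = 1,
                                    rng_seed = 15))
  pts <- data.frame(x = gt$cells$x_um, y = gt$cells$y_um)
  h0 <- neighbor_analysis(pts)$hexagonality
  expect_equal(neighbor_analysis(dplyr::mutate(pts, x = 3 * x + 40,
                                               y = 3 * y - 17))$hexagonality,
               h0)
  th <- 30 * pi / 180
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y,
                    y = sin(th) * pts$x + cos(th) * pts$y)
  expect_equal(neighbor_analysis(rot)$hexagonality, h0, tolerance = 0.04)
})

test_that("relaxation increases hexagonality across seeds", {
  wins <- 0
  for (s in 1:6) {
    g10 <- generate_mosaic(mosaic_spec(graft_diameter = 0.8, pixel_size = 1,
                                       rng_seed = 300 + s))
    g0 <- generate_mosaic(mosaic_spec(graft_diameter = 0.8, pixel_size = 1,
                                      regularity = 0, rng_seed = 300 + s))
    pts <- function(g) data.frame(x = g$cells$x_um, y = g$cells$y_um)
    if (neighbor_analysis(pts(g10))$hexagonality >
        neighbor_analysis(pts(g0))$hexagonality) wins <- wins + 1
  }
  expect_equal(wins, 6)
})

test_that("area CoV follows its population definition", {
  expect_equal(area_cov(rep(5, 10)), 0)
  expect_equal(area_cov(c(1, 3)), 0.5)
  expect_error(area_cov(c(1)), "at least 2")
  expect_error(area_cov(c(1, -2)), "positive")
  # Voronoi-reconstructed areas from nucleus points vs generator truth
  f <- fix_field()
  tr <- field_truth_px(f)
  va <- endomosaic:::voronoi_cell_areas(tr, dim(as.matrix(f$calcein)))
  cov_rec <- area_cov(va$area_px[va$interior])
  cov_truth <- area_cov(f$truth$area_um2[va$interior])
  expect_equal(cov_rec, cov_truth, tolerance = 0.05)
})

test_that("dead fraction de-duplicates across channels", {
  live <- tibble::tibble(x = as.numeric(1:990), y = 0)
  dead <- tibble::tibble(x = seq(2000, by = 5, length.out = 10), y = 0)
  expect_equal(dead_fraction(live, dead, radius = 1), 1)
  expect_equal(dead_fraction(live, dead[0, ], radius = 1), 0)
  expect_error(dead_fraction(live[0, ], dead[0, ], radius = 1), "empty")
  # a conflicted point counts as dead, not twice
  both <- tibble::tibble(x = c(1, 50), y = 0)
  expect_equal(dead_fraction(live, both, radius = 0.9),
               100 * 2 / (988 + 2))
})

test_that("a field with scattered dead cells reports the right dead share", {
  f <- simulate_field(seed = 5, dead_fraction = 0.04, render = fix_cal_spec())
  live <- detect_nuclei(f$calcein, f$params)
  dead <- detect_nuclei(f$dead, nuclei_channel_params(f$params))
  pct <- dead_fraction(live, dead, radius = f$params$cell_width_px / 2)
  truth_pct <- 100 * mean(f$truth$state == "dead_attached")
  expect_lt(abs(pct - truth_pct), 1)  # within 1 percentage point
  expect_lt(abs(pct - 4), 2)
})

test_that("field morphometry assembles a coherent report", {
  f <- fix_field()
  expect_warning(rep <- field_morphometry(f$calcein, f$nuclei, f$dead,
                                          params = f$params,
                                          area_mm2 = f$area_mm2),
                 "1000")
  expect_gt(rep$hexagonality_pct, 30)
  expect_lt(rep$hexagonality_pct, 80)
  expect_gt(rep$area_cov, 0.05)
  expect_equal(rep$dead_pct, 0, tolerance = 0.6)
  expect_equal(rep$density_nuclei, nrow(f$truth) / f$area_mm2,
               tolerance = 0.05)
  expect_lt(rep$density_calcein, rep$density_nuclei)
})
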