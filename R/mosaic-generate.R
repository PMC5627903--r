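#' Generate a ground-truthed synthetic endothelial mosaic
#'
#' Seeds `round(density * graft area)` cell nuclei uniformly in the graft
#' disc, relaxes them `spec$regularity` Lloyd iterations toward the centroidal
#' Voronoi tessellation of the disc, and assigns every in-disc pixel to its
#' nearest seed. The resulting label raster is the cell mosaic: cells
#' partition the disc exactly, so areas and the viable-area fraction are exact
#' on the raster. Every cell starts viable, with its nucleus placed at the
#' cell centroid plus a small jitter (at most 15% of the equivalent cell
#' radius) and a nucleus radius of 0.27 times the cell radius.
#'
#' @param spec A [mosaic_spec()].
#' @return An object of class `endomosaic` with fields `cells` (a tibble of
#'   per-cell records: centroid and nucleus position in um relative to the
#'   graft center, area, state), `labels` (the integer label raster, 0 outside
#'   the graft), graft geometry in pixels, and the applied damage list.
#' @export
#' @examples
#' gt <- generate_mosaic(mosaic_spec(graft_diameter = 1, rng_seed = 2))
#' glance(gt)
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  area_mm2 <- pi * (spec$graft_diameter / 2)^2
  n <- round(spec$target_density * area_mm2)
  if (n < 50) {
    stop("degenerate mosaic: density/diameter combination yields ", n,
         " cells (< 50)", call. = FALSE)
  }
  r_px <- spec$graft_diameter * 1000 / spec$pixel_size / 2
  c_px <- (spec$image_size - 1) / 2
  # ~5 px per cell width during relaxation keeps centroids accurate while
  # bounding the cost of Lloyd iterations on large grafts
  spacing_px <- sqrt(pi * r_px^2 / n)
  coarse <- max(1L, floor(spacing_px / 5))

  res <- withr::with_seed(spec$rng_seed, {
    rad <- r_px * sqrt(runif(n))
    ang <- runif(n, 0, 2 * pi)
    out <- cpp_lloyd(c_px + rad * cos(ang), c_px + rad * sin(ang),
                     spec$image_size, spec$image_size,
                     c_px, c_px, r_px, spec$regularity, coarse)
    jit_r <- runif(n)  # jitter drawn inside the same seed scope
    jit_a <- runif(n, 0, 2 * pi)
    c(out, list(jit_r = jit_r, jit_a = jit_a))
  })
  if (any(res$area_px == 0)) {
    stop("mosaic generation produced empty cells; increase image resolution",
         call. = FALSE)
  }

  px <- spec$pixel_size
  area_um2 <- res$area_px * px^2
  cell_r_um <- sqrt(area_um2 / pi)
  jr <- 0.15 * cell_r_um * sqrt(res$jit_r)
  cells <- tibble::tibble(
    id = seq_len(n),
    x_um = (res$centroid_x - c_px) * px,
    y_um = (res$centroid_y - c_px) * px,
    area_px = res$area_px,
    area_um2 = area_um2,
    cell_r_um = cell_r_um,
    nucleus_x_um = (res$centroid_x - c_px) * px + jr * cos(res$jit_a),
    nucleus_y_um = (res$centroid_y - c_px) * px + jr * sin(res$jit_a),
    nucleus_r_um = 0.27 * mean(cell_r_um),
    state = rep("viable", n))
  structure(
    list(cells = cells, labels = res$labels, spec = spec,
         center_px = c(x = c_px, y = c_px), radius_px = r_px,
         pixel_size = px, damage = list()),
    class = "endomosaic")
}

#' @export
print.endomosaic <- function(x, ...) {
  g <- glance(x)
  cat("<endomosaic> ", g$n_cells, " cells on a ", x$spec$graft_diameter,
      " mm graft (", round(g$density_cells_mm2), " cells/mm^2); viable fraction ",
      round(g$viable_fraction, 3), "; ", length(x$damage),
      " damage primitive(s)\n", sep = "")
  invisible(x)
}

#' Graft area in mm^2 (area of the rasterized disc)
#' @param gt An `endomosaic`.
#' @return Graft area in mm^2.
#' @export
graft_area_mm2 <- function(gt) {
  sum(gt$cells$area_um2) / 1e6
}

#' True viable-area fraction of a ground-truth mosaic
#'
#' Area of viable cells divided by the total graft area, computed exactly from
#' the raster tessellation.
#' @param gt An `endomosaic`.
#' @return A fraction in \[0, 1\].
#' @export
true_viable_fraction <- function(gt) {
  sum(gt$cells$area_px[gt$cells$state == "viable"]) / sum(gt$cells$area_px)
}

#' True live cell density of a ground-truth mosaic
#'
#' Counts only viable cells, per mm^2 of graft area.
#' @param gt An `endomosaic`.
#' @return Density in cells/mm^2.
#' @export
true_live_density <- function(gt) {
  sum(gt$cells$state == "viable") / graft_area_mm2(gt)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname generate_mosaic
#' @param x An `endomosaic`.
#' @param ... Unused.
#' @method tidy endomosaic
#' @export
tidy.endomosaic <- function(x, ...) {
  x$cells
}

#' @rdname generate_mosaic
#' @method glance endomosaic
#' @export
glance.endomosaic <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    density_cells_mm2 = nrow(x$cells) / graft_area_mm2(x),
    live_density_cells_mm2 = true_live_density(x),
    viable_fraction = true_viable_fraction(x),
    damage_fraction = 1 - true_viable_fraction(x),
    n_damage_primitives = length(x$damage))
}

# pixel-center coordinate grids in um relative to the graft center
mosaic_coord_um <- function(gt) {
  n <- nrow(gt$labels)
  px <- gt$pixel_size
  list(x = (seq_len(n) - 1 - gt$center_px[["x"]]) * px,
       y = (seq_len(n) - 1 - gt$center_px[["y"]]) * px)
}

# rasterize per-state truth at image resolution: states indexed by label
mosaic_state_raster <- function(gt) {
  state_code <- c(viable = 1L, dead_attached = 2L, absent = 3L)
  lut <- c(0L, state_code[gt$cells$state])
  matrix(lut[gt$labels + 1L], nrow = nrow(gt$labels))
}
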