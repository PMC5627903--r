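#' Nuclear peak-detection parameters
#'
#' Local-maxima nucleus counting is parameterized by the expected cell width;
#' defaults follow from it: smoothing sigma 0.2x, minimum peak separation
#' 0.7x, and a 5 grey-level prominence floor. These defaults are tuned so
#' that nucleus recall on a clean nuclear counterstain channel is ~1 at the
#' default render settings.
#'
#' @param cell_width_px Expected cell width in pixels.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @param min_separation Minimum distance between detected peaks, px.
#' @param prominence Minimum height of a peak above the local background
#'   (grey levels), measured against the minimum-filtered smoothed image.
#' @return A `detection_params` object.
#' @export
#' @examples
#' detection_params(cell_width_px = 27)
detection_params <- function(cell_width_px,
                             smooth_sigma = 0.2 * cell_width_px,
                             min_separation = 0.7 * cell_width_px,
                             prominence = 5) {
  stopifnot(cell_width_px > 0, smooth_sigma > 0, min_separation > 0,
            prominence > 0)
  structure(list(cell_width_px = cell_width_px, smooth_sigma = smooth_sigma,
                 min_separation = min_separation, prominence = prominence),
            class = "detection_params")
}

#' Expected cell width in pixels at a given density
#'
#' Width of a square of the mean cell area: `sqrt(1e6 / density) /
#' pixel_size`.
#' @param density Cell density, cells/mm^2.
#' @param pixel_size Pixel pitch, um/px.
#' @return Width in pixels.
#' @export
cell_width_px <- function(density = 2500, pixel_size = 0.8) {
  sqrt(1e6 / density) / pixel_size
}

odd_disc <- function(diameter) {
  d <- max(3L, as.integer(2 * floor(diameter / 2) + 1))
  EBImage::makeBrush(d, "disc")
}

#' Detect nuclei as smoothed local intensity maxima
#'
#' Gaussian-smooths the image, keeps pixels that equal the maximum over a
#' disc of diameter `min_separation` and rise at least `prominence` grey
#' levels above the local background (the minimum-filtered smoothed image
#' over a cell-width disc). Plateaus of tied maxima are collapsed to their
#' centroid. Points are returned in deterministic raster order.
#'
#' @param image A single-channel [fluorescence_image()] or matrix.
#' @param params A [detection_params()].
#' @return A tibble of 0-based pixel coordinates `x`, `y`, one row per
#'   detected nucleus, plus the smoothed peak `intensity`.
#' @export
detect_nuclei <- function(image, params) {
  m <- img_data(image)
  stopifnot(inherits(params, "detection_params"))
  if (params$min_separation >= min(dim(m))) {
    stop("min_separation is larger than the image", call. = FALSE)
  }
  s <- blur_image(m, params$smooth_sigma)
  mx <- dilate_mat(s, odd_disc(params$min_separation))
  bg <- min_filter(s, odd_disc(params$cell_width_px))
  peaks <- (s >= mx - 1e-9) & (s - bg >= params$prominence)
  if (!any(peaks)) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          intensity = numeric(0)))
  }
  lab <- label_components(peaks)
  idx <- which(lab > 0, arr.ind = TRUE)
  ord <- order(lab[lab > 0])
  grp <- lab[lab > 0][ord]
  xs <- (idx[, 2] - 1)[ord]
  ys <- (idx[, 1] - 1)[ord]
  cx <- rowsum(xs, grp) / tabulate(grp)
  cy <- rowsum(ys, grp) / tabulate(grp)
  out <- tibble::tibble(x = as.vector(cx), y = as.vector(cy))
  out$intensity <- s[cbind(round(out$y) + 1, round(out$x) + 1)]
  dplyr::arrange(out, .data$y, .data$x)
}

#' Cell density from detected points
#'
#' @param points A data frame of detected points (one row per cell).
#' @param area_mm2 Area of the counted region in mm^2.
#' @param method Method tag carried into the result
#'   (`"calcein_maxima"` or `"nuclei_channel"`).
#' @return A one-row tibble: `n`, `area_mm2`, `density_cells_mm2`, `method`.
#' @export
estimate_density <- function(points, area_mm2,
                             method = c("calcein_maxima", "nuclei_channel")) {
  method <- match.arg(method)
  if (area_mm2 <= 0) stop("area must be positive", call. = FALSE)
  tibble::tibble(n = nrow(points), area_mm2 = area_mm2,
                 density_cells_mm2 = nrow(points) / area_mm2,
                 method = method)
}

#' Voronoi neighbour analysis and hexagonality
#'
#' Builds the discrete Voronoi tessellation of the centroids on a raster
#' (about `px_per_cell` pixels per cell width), takes as neighbours cells
#' whose Voronoi regions share at least `min_shared_px` boundary pixel pairs
#' (so corner-point contacts, as in a square lattice, do not count), and
#' excludes cells whose region touches the field boundary. Hexagonality is
#' the percentage of interior cells with exactly six neighbours.
#'
#' @param centroids Data frame with columns `x`, `y` (any common unit).
#' @param px_per_cell Raster resolution, pixels per expected cell width.
#' @param min_shared_px Minimum shared boundary, pixels, for adjacency.
#' @return A list with `hexagonality` (percent), `n_interior`, and `cells`
#'   (a tibble: `id`, `x`, `y`, `n_neighbors`, `interior`).
#' @export
neighbor_analysis <- function(centroids, px_per_cell = 30,
                              min_shared_px = 2) {
  centroids <- tibble::as_tibble(centroids)
  n <- nrow(centroids)
  if (n < 3) stop("need at least 3 centroids", call. = FALSE)
  xr <- range(centroids$x); yr <- range(centroids$y)
  if (diff(xr) == 0 || diff(yr) == 0 ||
      qr(cbind(centroids$x - mean(centroids$x),
               centroids$y - mean(centroids$y)))$rank < 2) {
    stop("centroids are collinear", call. = FALSE)
  }
  w <- sqrt(diff(xr) * diff(yr) / n)  # expected cell width in data units
  scale <- px_per_cell / w
  ncol_g <- ceiling(diff(xr) * scale) + 1
  nrow_g <- ceiling(diff(yr) * scale) + 1
  cap <- 4000
  if (max(ncol_g, nrow_g) > cap) {
    shrink <- cap / max(ncol_g, nrow_g)
    scale <- scale * shrink
    ncol_g <- ceiling(diff(xr) * scale) + 1
    nrow_g <- ceiling(diff(yr) * scale) + 1
  }
  gx <- (centroids$x - xr[1]) * scale
  gy <- (centroids$y - yr[1]) * scale
  labels <- cpp_assign_grid(gx, gy, nrow_g, ncol_g)
  adj <- cpp_adjacency(labels, n)
  keep <- adj$shared >= min_shared_px
  deg <- tabulate(c(adj$i[keep], adj$j[keep]), nbins = n)
  interior <- !adj$boundary
  hex <- 100 * mean(deg[interior] == 6)
  cells <- tibble::tibble(id = seq_len(n), x = centroids$x, y = centroids$y,
                          n_neighbors = deg, interior = interior)
  list(hexagonality = hex, n_interior = sum(interior), cells = cells)
}

#' Coefficient of variation of cell areas
#'
#' Population SD of cell areas divided by their mean (polymegethism index).
#' @param areas Positive cell areas (at least two).
#' @return The CoV, dimensionless.
#' @export
area_cov <- function(areas) {
  if (length(areas) < 2) stop("need at least 2 areas", call. = FALSE)
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  mu <- mean(areas)
  sqrt(mean((areas - mu)^2)) / mu
}

#' Percentage of dead cells from co-registered live/dead point sets
#'
#' De-duplicates points closer than `radius` across channels (a cell cannot
#' be both live and dead; conflicts are resolved to dead, since the
#' dead-cell stain is the specific one) and reports
#' `100 * dead / (live + dead)`.
#'
#' @param live,dead Data frames of points (`x`, `y`) from the live and dead
#'   channels.
#' @param radius Matching radius in the same unit as the coordinates.
#' @return Percentage of dead cells.
#' @export
dead_fraction <- function(live, dead, radius) {
  nl <- nrow(live); nd <- nrow(dead)
  if (nl + nd == 0) stop("both point sets are empty", call. = FALSE)
  if (nl > 0 && nd > 0) {
    d2 <- outer(live$x, dead$x, "-")^2 + outer(live$y, dead$y, "-")^2
    dup <- apply(d2, 1, min) <= radius^2
    nl <- sum(!dup)
  }
  100 * nd / (nl + nd)
}

#' Greedy nearest-neighbour matching of detected points to truth
#'
#' Pairs detected and truth points in order of increasing distance, each
#' point used at most once, up to a maximum matching radius. Used for
#' detection recall/precision against generator truth.
#'
#' @param detected,truth Data frames of points (`x`, `y`).
#' @param radius Maximum matching distance.
#' @return A list: `matches` tibble (`detected`, `truth`, `distance`),
#'   `recall`, `precision`.
#' @export
match_points <- function(detected, truth, radius) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(matches = tibble::tibble(detected = integer(0),
                                         truth = integer(0),
                                         distance = numeric(0)),
                recall = 0, precision = if (nd == 0) NA_real_ else 0))
  }
  d2 <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  cand <- which(d2 <= radius^2, arr.ind = TRUE)
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  di <- integer(0); ti <- integer(0); dist <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    di <- c(di, i); ti <- c(ti, j); dist <- c(dist, sqrt(d2[i, j]))
  }
  list(matches = tibble::tibble(detected = di, truth = ti, distance = dist),
       recall = length(ti) / nt, precision = length(di) / nd)
}

#' Morphometry report for a high-magnification field
#'
#' Runs nuclear detection on the calcein channel (and, when supplied, the
#' nuclear and dead-cell channels), then assembles the cell-scale summary:
#' density, hexagonality, cell-area CoV (from Voronoi-reconstructed areas of
#' interior cells) and percent dead cells. Report-grade morphometry expects
#' at least 1000 analyzed cells; smaller fields are reported with a warning.
#'
#' @param calcein A [fluorescence_image()] (calcein channel).
#' @param nuclei,dead Optional companion channel images.
#' @param params A [detection_params()]; defaults to the expected cell width
#'   at 2500 cells/mm^2 for the image's pixel size.
#' @param area_mm2 Counted area; defaults to the full image area.
#' @return A one-row tibble: `n_cells`, `density_calcein`, `density_nuclei`
#'   (NA without a nuclei channel), `hexagonality_pct`, `area_cov`,
#'   `dead_pct`.
#' @export
field_morphometry <- function(calcein, nuclei = NULL, dead = NULL,
                              params = NULL, area_mm2 = NULL) {
  px <- img_pixel_size(calcein)
  if (is.null(params)) params <- detection_params(cell_width_px(2500, px))
  if (is.null(area_mm2)) {
    area_mm2 <- prod(dim(img_data(calcein))) * px^2 / 1e6
  }
  pts_cal <- detect_nuclei(calcein, params)
  dens_cal <- estimate_density(pts_cal, area_mm2, "calcein_maxima")
  pts_ref <- pts_cal
  dens_nuc <- NA_real_
  if (!is.null(nuclei)) {
    np <- nuclei_channel_params(params)
    pts_ref <- detect_nuclei(nuclei, np)
    dens_nuc <- estimate_density(pts_ref, area_mm2,
                                 "nuclei_channel")$density_cells_mm2
  }
  n_cells <- nrow(pts_ref)
  if (n_cells < 1000) {
    warning("only ", n_cells, " cells analyzed; report-grade morphometry ",
            "expects at least 1000")
  }
  na <- neighbor_analysis(pts_ref, px_per_cell = 20)
  areas <- voronoi_cell_areas(pts_ref, dim(img_data(calcein)))
  cov <- area_cov(areas$area_px[areas$interior] * px^2)
  dead_pct <- 0
  if (!is.null(dead)) {
    dp <- nuclei_channel_params(params)
    pts_dead <- detect_nuclei(dead, dp)
    if (nrow(pts_dead) + nrow(pts_ref) > 0) {
      dead_pct <- dead_fraction(pts_ref, pts_dead,
                                radius = params$cell_width_px / 2)
    }
  }
  tibble::tibble(n_cells = n_cells,
                 density_calcein = dens_cal$density_cells_mm2,
                 density_nuclei = dens_nuc,
                 hexagonality_pct = na$hexagonality,
                 area_cov = cov,
                 dead_pct = dead_pct)
}

#' Detection parameters for a clean nuclear counterstain channel
#'
#' Nuclei on the counterstain channels are bright dots on a dark field, so a
#' light smoothing and a high prominence floor suffice.
#' @param params Calcein-channel [detection_params()] to derive from.
#' @return A `detection_params`.
#' @export
nuclei_channel_params <- function(params) {
  detection_params(params$cell_width_px,
                   smooth_sigma = max(1, 0.07 * params$cell_width_px),
                   min_separation = params$min_separation,
                   prominence = 40)
}

# Voronoi-reconstructed per-cell pixel areas from centroids on the image
# raster; interior = region not touching the image edge
voronoi_cell_areas <- function(points, dims) {
  labels <- cpp_assign_grid(points$x, points$y, dims[1], dims[2])
  adj <- cpp_adjacency(labels, nrow(points))
  tibble::tibble(id = seq_len(nrow(points)),
                 area_px = tabulate(labels, nbins = nrow(points)),
                 interior = !adj$boundary)
}
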