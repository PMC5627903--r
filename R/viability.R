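#' Detect the graft disc in a global fluorescence image
#'
#' Two-stage localization. First the bright viable core is segmented (Otsu
#' threshold on a smoothed copy, union of substantial components — damage
#' tracks can sever the core — and a least-squares circle fit to the convex
#' hull of its boundary), which pins the graft center. Then the graft
#' radius is read off the radial mean-intensity profile about that center:
#' the outermost shelf above background (the dim dead peripheral rim is only
#' a few grey levels above the bare background) is located and the edge is
#' placed at the half-maximum crossing of the local shelf height, which is
#' unbiased whether the outermost tissue is bright or dim. The returned mask
#' is the fitted disc.
#'
#' @param image A [fluorescence_image()] or matrix.
#' @param smooth_sigma Gaussian smoothing sigma (px) for core segmentation.
#' @param shelf_min Minimum elevation (grey levels) of tissue above the
#'   background level in the radial profile.
#' @param pixel_size Pixel pitch, um/px (taken from the image if present).
#' @return A `graft_mask`: logical `mask`, fitted `center` (0-based px,
#'   `c(x, y)`), `radius` (px) and `area_mm2`.
#' @export
detect_graft_mask <- function(image, smooth_sigma = 2, shelf_min = 1.5,
                              pixel_size = NULL) {
  m <- img_data(image)
  px <- img_pixel_size(image, pixel_size)
  sm <- blur_image(m, smooth_sigma)
  rng <- range(sm)
  if (diff(rng) < 1) {
    stop("no graft found: flat image", call. = FALSE)
  }
  thr <- EBImage::otsu((sm - rng[1]) / diff(rng)) * diff(rng) + rng[1]

  bw <- label_components(sm > thr)
  sizes <- tabulate(bw[bw > 0])
  if (length(sizes) == 0 || max(sizes) < 0.01 * length(m)) {
    stop("no graft found: no component covers 1% of the image", call. = FALSE)
  }
  # keep all substantial components: damage tracks can sever the graft into
  # several bright pieces that still outline the same core
  keep <- which(sizes >= max(0.001 * length(m), 0.05 * max(sizes)))
  comp <- matrix(bw %in% keep, nrow = nrow(m))
  edge <- comp & !(erode_mat(comp, EBImage::makeBrush(3, "box")) > 0)
  idx <- which(edge, arr.ind = TRUE)
  xb <- idx[, 2] - 1; yb <- idx[, 1] - 1
  # the core outline is the convex hull of the boundary; interior damage
  # edges must not drag the circle fit inward
  hull <- grDevices::chull(xb, yb)
  xb <- xb[hull]; yb <- yb[hull]
  # Kasa algebraic circle fit: minimise ||x^2+y^2 - 2ax - 2by - c||
  A <- cbind(2 * xb, 2 * yb, 1)
  sol <- qr.solve(A, xb^2 + yb^2)
  cx <- sol[1]; cy <- sol[2]

  # radial mean profile in 1-px annuli on a lightly smoothed image
  s1 <- blur_image(m, 1)
  xg <- matrix(rep(seq_len(ncol(m)) - 1, each = nrow(m)), nrow = nrow(m))
  yg <- matrix(rep(seq_len(nrow(m)) - 1, times = ncol(m)), nrow = nrow(m))
  rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
  rmax <- floor(min(cx, cy, ncol(m) - 1 - cx, nrow(m) - 1 - cy))
  bin <- floor(rr) + 1L
  ok <- bin <= rmax
  p <- as.vector(rowsum(s1[ok], bin[ok])) / tabulate(bin[ok], nbins = rmax)
  nb <- length(p)
  bg <- mean(p[max(1, nb - 9):nb])
  on_graft <- which(p >= bg + shelf_min)
  if (length(on_graft) == 0 || max(on_graft) < 5) {
    stop("no graft found: no tissue shelf above background", call. = FALSE)
  }
  rc <- max(on_graft)
  shelf <- stats::median(p[max(1, rc - 12):max(1, rc - 4)]) - bg
  half <- bg + shelf / 2
  rc2 <- max(which(p >= half))
  r <- if (rc2 >= nb) {
    nb - 0.5
  } else {
    frac <- (p[rc2] - half) / (p[rc2] - p[rc2 + 1])
    rc2 - 0.5 + max(0, min(1, frac))
  }

  mask <- rr <= r
  covered <- sum(mask & comp) / sum(comp)
  if (covered < 0.95) {
    warning("fitted disc covers only ", round(100 * covered, 1),
            "% of the detected component; the graft may not be circular")
  }
  structure(
    list(mask = mask, center = c(x = unname(cx), y = unname(cy)),
         radius = unname(r), pixel_size = px,
         area_mm2 = sum(mask) * px^2 / 1e6, threshold = thr),
    class = "graft_mask")
}

#' @export
print.graft_mask <- function(x, ...) {
  cat("<graft_mask> center (", round(x$center[["x"]], 1), ", ",
      round(x$center[["y"]], 1), ") px, radius ", round(x$radius, 1),
      " px, area ", round(x$area_mm2, 2), " mm^2\n", sep = "")
  invisible(x)
}

default_cell_area_px <- function(pixel_size, density = 2500) {
  (1e6 / density) / pixel_size^2
}

#' Segment the viable graft area at a fixed grey-level threshold
#'
#' Pixels strictly brighter than the threshold (40 grey levels by default)
#' inside the graft mask are marked viable. Morphological cleanup then
#' removes viable specks smaller than `min_object_px` and fills non-viable
#' holes smaller than `min_hole_px` (defaults: 5 and 1 nominal cell areas —
#' noise speckle is sub-cellular; set both to 0 to disable). The viable-area
#' fraction is computed over graft-mask pixels, and `damage_fraction` is its
#' complement.
#'
#' When the generating ground truth is supplied, the truth raster is compared
#' pixelwise and sensitivity, specificity and the Dice coefficient of the
#' viable class are reported.
#'
#' @param image A [fluorescence_image()] or matrix.
#' @param mask A `graft_mask` (or logical matrix) delimiting the graft.
#' @param threshold Viability cutoff in grey levels (0--255).
#' @param min_object_px,min_hole_px Cleanup areas in pixels; `NULL` uses the
#'   nominal-cell-area defaults.
#' @param truth Optional `endomosaic` ground truth for pixelwise validation.
#' @param pixel_size Pixel pitch override, um/px.
#' @return A `viability_report`.
#' @export
segment_viable <- function(image, mask, threshold = 40,
                           min_object_px = NULL, min_hole_px = NULL,
                           truth = NULL, pixel_size = NULL) {
  m <- img_data(image)
  px <- img_pixel_size(image, pixel_size)
  if (threshold < 0 || threshold > 255) {
    stop("threshold must lie in [0, 255]", call. = FALSE)
  }
  gm <- if (inherits(mask, "graft_mask")) mask$mask else mask
  stopifnot(identical(dim(gm), dim(m)))
  cell_px <- default_cell_area_px(px)
  if (is.null(min_object_px)) min_object_px <- 5 * cell_px
  if (is.null(min_hole_px)) min_hole_px <- 1 * cell_px

  viable <- m > threshold & gm
  if (min_object_px > 0 && any(viable)) {
    lab <- label_components(viable)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_object_px)
    if (length(drop)) viable[matrix(lab %in% drop, nrow = nrow(m))] <- FALSE
  }
  if (min_hole_px > 0) {
    holes <- gm & !viable
    if (any(holes)) {
      lab <- label_components(holes)
      sizes <- tabulate(lab[lab > 0])
      fill <- which(sizes < min_hole_px)
      if (length(fill)) viable[matrix(lab %in% fill, nrow = nrow(m))] <- TRUE
    }
  }
  vf <- sum(viable) / sum(gm)

  metrics <- NULL
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "endomosaic"))
    if (!identical(dim(truth$labels), dim(m))) {
      stop("image and ground-truth geometry disagree", call. = FALSE)
    }
    tv <- mosaic_state_raster(truth) == 1L
    tp <- sum(viable & tv & gm); fp <- sum(viable & !tv & gm)
    fn <- sum(!viable & tv & gm); tn <- sum(!viable & !tv & gm)
    metrics <- tibble::tibble(
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      dice = 2 * tp / (2 * tp + fp + fn))
  }
  structure(
    list(viable = viable, mask = gm, threshold = threshold,
         viable_area_fraction = vf, damage_fraction = 1 - vf,
         pixel_size = px, metrics = metrics,
         min_object_px = min_object_px, min_hole_px = min_hole_px),
    class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat("<viability_report> threshold ", x$threshold, ": viable area ",
      round(100 * x$viable_area_fraction, 1), "%, damage ",
      round(100 * x$damage_fraction, 1), "%\n", sep = "")
  if (!is.null(x$metrics)) {
    cat("  vs truth: sensitivity ", round(x$metrics$sensitivity, 3),
        ", specificity ", round(x$metrics$specificity, 3), ", Dice ",
        round(x$metrics$dice, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname segment_viable
#' @param x A `viability_report`.
#' @param ... Unused.
#' @method glance viability_report
#' @export
glance.viability_report <- function(x, ...) {
  out <- tibble::tibble(threshold = x$threshold,
                        viable_area_fraction = x$viable_area_fraction,
                        damage_fraction = x$damage_fraction)
  if (!is.null(x$metrics)) out <- dplyr::bind_cols(out, x$metrics)
  out
}

#' @rdname segment_viable
#' @param object A `viability_report`.
#' @method autoplot viability_report
#' @export
autoplot.viability_report <- function(object, ...) {
  cls <- matrix("background", nrow(object$viable), ncol(object$viable))
  cls[object$mask] <- "non-viable"
  cls[object$viable] <- "viable"
  ds <- max(1L, floor(max(dim(object$viable)) / 600))
  ri <- seq(1, nrow(cls), by = ds); ci <- seq(1, ncol(cls), by = ds)
  df <- tidyr::expand_grid(y = ri - 1, x = ci - 1)
  df$class <- as.vector(t(cls[ri, ci]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "black",
                                          `non-viable` = "red3",
                                          viable = "green3")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Attribute detected damage to ground-truth damage footprints
#'
#' For each damage primitive applied to the ground truth, rasterizes its
#' footprint at image resolution and reports how much of it the segmentation
#' recovered as non-viable (recall), together with the leakage: non-viable
#' area detected outside every footprint. Where footprints overlap, the
#' overlapping area is credited to each primitive and flagged.
#'
#' @param report A `viability_report` from [segment_viable()].
#' @param truth The `endomosaic` the image was rendered from (with damage).
#' @return A tibble with one row per primitive (`type`, `mode`,
#'   `footprint_px`, `footprint_mm2`, `detected_px`, `recall`,
#'   `overlaps_other`), with the leakage area (px) as attribute
#'   `leakage_px`.
#' @export
attribute_damage <- function(report, truth) {
  stopifnot(inherits(report, "viability_report"),
            inherits(truth, "endomosaic"))
  if (!identical(dim(truth$labels), dim(report$viable))) {
    stop("report and ground-truth geometry disagree", call. = FALSE)
  }
  nonviable <- report$mask & !report$viable
  co <- mosaic_coord_um(truth)
  xg <- matrix(rep(co$x, each = length(co$y)), nrow = length(co$y))
  yg <- matrix(rep(co$y, times = length(co$x)), nrow = length(co$y))
  radius_um <- truth$radius_px * truth$pixel_size
  fps <- purrr::map(truth$damage, function(prim) {
    matrix(primitive_member(prim, as.vector(xg), as.vector(yg), radius_um),
           nrow = nrow(xg))
  })
  any_fp <- Reduce(`|`, fps, matrix(FALSE, nrow(xg), ncol(xg)))
  px2 <- truth$pixel_size^2 / 1e6
  rows <- purrr::imap(fps, function(fp, i) {
    others <- purrr::imap(fps, function(o, j) if (j != i) o else NULL)
    others <- purrr::compact(others)
    ov <- length(others) > 0 &&
      any(fp & Reduce(`|`, others, matrix(FALSE, nrow(xg), ncol(xg))))
    tibble::tibble(
      primitive = i,
      type = truth$damage[[i]]$type,
      mode = truth$damage[[i]]$mode,
      footprint_px = sum(fp),
      footprint_mm2 = sum(fp) * px2,
      detected_px = sum(fp & nonviable),
      recall = if (sum(fp) > 0) sum(fp & nonviable) / sum(fp) else NA_real_,
      overlaps_other = ov)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "leakage_px") <- sum(nonviable & !any_fp)
  out
}
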