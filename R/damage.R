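#' Surgical damage primitives
#'
#' Each primitive describes a footprint on the graft together with a mode:
#' `"bare_dm"` (cells scraped off, bare Descemet membrane remains) or
#' `"dead_attached"` (cells remain attached but die). Coordinates and sizes
#' are in micrometres in the graft frame (origin at the graft center, x to the
#' right, y downward); angles are in degrees, measured from the +x axis toward
#' +y. Footprints are clipped to the graft disc when applied.
#'
#' * `damage_rim()` — peripheral annulus of the given radial width; models
#'   trephination/handling damage at the graft edge.
#' * `damage_wedge()` — angular sector of the periphery, extending
#'   `radial_depth` inward; models tissue incarcerated in the surgical wound.
#' * `damage_streaks()` — `count` parallel bands of the given width, centred
#'   on the graft and spaced `spacing` apart; models the linear cell-loss
#'   tracks of an ejected graft.
#' * `damage_polygon()` — arbitrary polygonal patch.
#' * `damage_tear()` — polyline buffered to `gape` width; models a torn edge.
#' * `damage_mark()` — small peripheral triangle cut for orientation
#'   marking (tissue removed, so mode is `"bare_dm"`).
#'
#' @param width_um Radial width (rim) or band width (streaks) in um.
#' @param mode `"bare_dm"` or `"dead_attached"`.
#' @param center_angle Wedge bisector angle, degrees.
#' @param angular_width Wedge angular width, degrees.
#' @param radial_depth_um How far the wedge extends inward from the edge, um.
#' @param count Number of parallel streaks.
#' @param orientation Streak direction, degrees.
#' @param spacing_um Distance between adjacent streak centrelines, um.
#' @param vertices A two-column matrix (x, y in um) of polygon vertices.
#' @param path A two-column matrix (x, y in um) of polyline vertices.
#' @param gape_um Full width of the tear opening, um.
#' @return A `damage_primitive` object.
#' @seealso [damage_spec()], [apply_damage()]
#' @name damage_primitives
NULL

new_primitive <- function(type, mode, ...) {
  mode <- match.arg(mode, c("bare_dm", "dead_attached"))
  structure(list(type = type, mode = mode, ...), class = "damage_primitive")
}

#' @rdname damage_primitives
#' @export
damage_rim <- function(width_um = 200, mode = "dead_attached") {
  stopifnot(width_um > 0)
  new_primitive("rim", mode, width_um = width_um)
}

#' @rdname damage_primitives
#' @export
damage_wedge <- function(center_angle = 0, angular_width = 40,
                         radial_depth_um = 1200, mode = "bare_dm") {
  stopifnot(angular_width > 0, radial_depth_um > 0)
  new_primitive("wedge", mode, center_angle = center_angle,
                angular_width = angular_width, radial_depth_um = radial_depth_um)
}

#' @rdname damage_primitives
#' @export
damage_streaks <- function(count = 6, width_um = 200, orientation = 65,
                           spacing_um = 500, mode = "bare_dm") {
  stopifnot(count >= 1, width_um > 0, spacing_um > 0)
  new_primitive("streaks", mode, count = as.integer(count),
                width_um = width_um, orientation = orientation,
                spacing_um = spacing_um)
}

#' @rdname damage_primitives
#' @export
damage_polygon <- function(vertices, mode = "bare_dm") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  new_primitive("polygon_patch", mode, vertices = vertices)
}

#' @rdname damage_primitives
#' @export
damage_tear <- function(path, gape_um = 150, mode = "bare_dm") {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2, gape_um > 0)
  new_primitive("tear", mode, path = path, gape_um = gape_um)
}

#' @rdname damage_primitives
#' @export
damage_mark <- function(vertices = NULL, mode = "bare_dm") {
  if (is.null(vertices)) {
    # default: small triangle notched into the periphery at 12 o'clock
    vertices <- cbind(c(-150, 150, 0), c(-3950, -3950, -3550))
  }
  p <- damage_polygon(vertices, mode = mode)
  p$type <- "orientation_mark"
  p
}

#' @export
print.damage_primitive <- function(x, ...) {
  cat("<damage_primitive> ", x$type, " [", x$mode, "]\n", sep = "")
  invisible(x)
}

#' Collect damage primitives into an ordered damage specification
#'
#' Primitives are applied in order; a later primitive overrides the state set
#' by an earlier one where their footprints overlap. An empty specification is
#' the identity.
#'
#' @param ... `damage_primitive` objects (or lists of them).
#' @return A `damage_spec` (ordered list of primitives).
#' @export
#' @examples
#' damage_spec(damage_rim(200), damage_wedge(center_angle = 120))
damage_spec <- function(...) {
  prims <- purrr::list_flatten(list(...))
  ok <- purrr::map_lgl(prims, inherits, "damage_primitive")
  if (!all(ok)) stop("all arguments must be damage primitives", call. = FALSE)
  structure(prims, class = "damage_spec")
}

#' @export
print.damage_spec <- function(x, ...) {
  cat("<damage_spec> with", length(x), "primitive(s)\n")
  for (p in x) cat("  -", p$type, "[", p$mode, "]\n")
  invisible(x)
}

# vectorized even-odd point-in-polygon (crossing number)
point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to a polyline (minimum over segments)
dist_to_polyline <- function(px, py, path) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(path) - 1)) {
    ax <- path[i, 1]; ay <- path[i, 2]
    bx <- path[i + 1, 1]; by <- path[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}

# footprint membership of points (um, graft frame) for one primitive;
# radius_um is the graft radius used to clip/anchor peripheral primitives
primitive_member <- function(prim, x_um, y_um, radius_um) {
  r <- sqrt(x_um^2 + y_um^2)
  inside_disc <- r <= radius_um
  m <- switch(
    prim$type,
    rim = r >= radius_um - prim$width_um,
    wedge = {
      ang <- atan2(y_um, x_um) * 180 / pi
      d <- ((ang - prim$center_angle + 180) %% 360) - 180
      abs(d) <= prim$angular_width / 2 & r >= radius_um - prim$radial_depth_um
    },
    streaks = {
      th <- prim$orientation * pi / 180
      # signed distance along the normal of the streak direction
      s <- -x_um * sin(th) + y_um * cos(th)
      offs <- (seq_len(prim$count) - (prim$count + 1) / 2) * prim$spacing_um
      hit <- rep(FALSE, length(s))
      for (o in offs) hit <- hit | abs(s - o) <= prim$width_um / 2
      hit
    },
    polygon_patch = point_in_poly(x_um, y_um, prim$vertices[, 1], prim$vertices[, 2]),
    orientation_mark = point_in_poly(x_um, y_um, prim$vertices[, 1], prim$vertices[, 2]),
    tear = dist_to_polyline(x_um, y_um, prim$path) <= prim$gape_um / 2,
    stop("unknown primitive type: ", prim$type)
  )
  m & inside_disc
}

#' Apply damage primitives to a ground-truth mosaic
#'
#' Cells whose centroid falls inside a primitive's footprint switch to the
#' primitive's mode (`bare_dm` footprints leave cells `absent`,
#' `dead_attached` footprints leave them attached but dead). Primitives are
#' applied in order and compose; applying an empty specification is the
#' identity. Applied primitives are retained on the mosaic for later
#' per-region damage attribution.
#'
#' @param gt An `endomosaic`.
#' @param damage A [damage_spec()] or a single damage primitive.
#' @return The damaged `endomosaic` (derived summaries recomputable via
#'   [true_viable_fraction()] etc.).
#' @export
#' @examples
#' gt <- generate_mosaic(mosaic_spec(graft_diameter = 1, rng_seed = 2))
#' gt <- apply_damage(gt, damage_rim(width_um = 50))
#' true_viable_fraction(gt)
apply_damage <- function(gt, damage) {
  stopifnot(inherits(gt, "endomosaic"))
  if (inherits(damage, "damage_primitive")) damage <- damage_spec(damage)
  stopifnot(inherits(damage, "damage_spec"))
  radius_um <- gt$radius_px * gt$pixel_size
  state_for <- c(bare_dm = "absent", dead_attached = "dead_attached")
  for (prim in damage) {
    hit <- primitive_member(prim, gt$cells$x_um, gt$cells$y_um, radius_um)
    if (!any(hit)) {
      warning("damage primitive '", prim$type,
              "' affects no cells (footprint outside the graft?); skipped")
      next
    }
    gt$cells$state[hit] <- state_for[[prim$mode]]
    gt$damage <- c(gt$damage, list(prim))
  }
  gt
}

#' Calibrate streak damage to a target viable fraction
#'
#' Searches the streak band width so that, applied on top of the mosaic's
#' existing damage, the ground-truth viable-area fraction lands on `target`.
#' Used to recreate the linear cell-loss pattern of an ejected graft at a
#' prescribed residual viability (e.g. 73%).
#'
#' @param gt An `endomosaic` (with any prior damage already applied).
#' @param target Target viable-area fraction in (0, 1).
#' @param count,orientation,spacing_um,mode Passed to [damage_streaks()].
#' @param tol Acceptable |achieved - target|; the bisection also stops at 40
#'   iterations.
#' @return A list with `gt` (the damaged mosaic), `primitive` (the calibrated
#'   streak primitive) and `achieved` (the achieved viable fraction).
#' @export
calibrate_streak_damage <- function(gt, target = 0.73, count = 6,
                                    orientation = 65, spacing_um = 500,
                                    mode = "bare_dm", tol = 0.005) {
  stopifnot(target > 0, target < 1)
  base_vf <- true_viable_fraction(gt)
  if (base_vf <= target) {
    stop("mosaic is already at or below the target viable fraction",
         call. = FALSE)
  }
  vf_for <- function(w) {
    prim <- damage_streaks(count = count, width_um = w,
                           orientation = orientation, spacing_um = spacing_um,
                           mode = mode)
    true_viable_fraction(suppressWarnings(apply_damage(gt, prim)))
  }
  lo <- 1e-3
  hi <- spacing_um * 0.999  # streaks merge into a solid band at full spacing
  if (vf_for(hi) > target) {
    stop("streak set cannot remove enough area to reach the target; ",
         "increase count or spacing", call. = FALSE)
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    v <- vf_for(mid)
    if (abs(v - target) <= tol / 2) { lo <- hi <- mid; break }
    if (v > target) lo <- mid else hi <- mid
  }
  w <- (lo + hi) / 2
  prim <- damage_streaks(count = count, width_um = w, orientation = orientation,
                         spacing_um = spacing_um, mode = mode)
  out <- suppressWarnings(apply_damage(gt, prim))
  list(gt = out, primitive = prim, achieved = true_viable_fraction(out))
}

#' Default peripheral damage of a freshly prepared graft
#'
#' A 200-um rim of attached dead cells, modelling trephination and edge
#' handling; removes about 10% of the graft area from the viable pool, at the
#' low end of the damage range seen after preparation and insertion.
#' @param width_um Rim width in um.
#' @return A `damage_spec`.
#' @export
default_damage <- function(width_um = 200) {
  damage_spec(damage_rim(width_um = width_um, mode = "dead_attached"))
}
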