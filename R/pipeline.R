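#' Analysis run configuration
#'
#' Collects every tunable the whole-graft analysis uses, so a run is fully
#' described by its configuration and seed. Round-trips losslessly through
#' JSON via [config_write()]/[config_read()].
#'
#' @param pixel_size Pixel pitch, um/px.
#' @param threshold Viability cutoff, grey levels.
#' @param patch_side Photometry patch side, px.
#' @param rim_width_um Width of the peripheral non-viable reference annulus.
#' @param n_patches Patches per region for the photometry summary.
#' @param seed Master seed; per-image seeds derive from it.
#' @param out_dir Optional output directory for JSON/CSV reports.
#' @param verbose Log parameters and stage progress.
#' @return A `run_config`.
#' @export
run_config <- function(pixel_size = 5, threshold = 40, patch_side = 25,
                       rim_width_um = 200, n_patches = 50, seed = 1,
                       out_dir = NULL, verbose = FALSE) {
  stopifnot(pixel_size > 0, threshold >= 0, threshold <= 255,
            patch_side >= 3, rim_width_um > 0, n_patches >= 1)
  structure(
    list(pixel_size = pixel_size, threshold = threshold,
         patch_side = patch_side, rim_width_um = rim_width_um,
         n_patches = n_patches, seed = as.integer(seed),
         out_dir = out_dir, verbose = isTRUE(verbose)),
    class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
config_write <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
config_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!purrr::map_lgl(x, is.null)])
}

log_msg <- function(config, ...) {
  if (config$verbose) message("[endomosaic] ", ...)
}

#' Run the whole-graft viability pipeline over a series of images
#'
#' For each image (e.g. the pre-preparation, post-preparation and in-situ
#' time points of one graft): detect the graft disc, segment the viable area
#' at the configured threshold, and summarize patch photometry (viable and
#' peripheral reference patches, contrast, mean SNR). Returns the per-image
#' reports plus a longitudinal table of viable fraction across the series.
#' All randomness derives from `config$seed`, so a configuration reproduces
#' its report bundle exactly.
#'
#' @param config A [run_config()].
#' @param images A named list of [fluorescence_image()] objects or file
#'   paths (names become time-point labels).
#' @return A `viability_bundle`: `reports` (per-image), `photometry`
#'   (per-image tibble), `summary` (longitudinal tibble), `config`.
#' @export
run_pipeline <- function(config, images) {
  stopifnot(inherits(config, "run_config"))
  if (length(images) == 0) stop("no images supplied", call. = FALSE)
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- paste0("t", seq_along(images))
  }
  reports <- list()
  photo <- list()
  for (i in seq_along(images)) {
    nm <- names(images)[i]
    res <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) img <- read_image(img, config$pixel_size)
      log_msg(config, "image '", nm, "': detecting graft")
      mask <- detect_graft_mask(img)
      log_msg(config, "image '", nm, "': segmenting at threshold ",
              config$threshold)
      rep <- segment_viable(img, mask, threshold = config$threshold)
      regions <- patch_regions(dim(img_data(img)), mask$center, mask$radius,
                               config$rim_width_um / config$pixel_size)
      # fall back to overlapping patches when a region is too small to pack
      # the requested number of disjoint arrays
      draw <- function(mask, label, min_cov, seed) {
        tryCatch(
          sample_patches(img, mask = mask, n = config$n_patches,
                         side = config$patch_side, label = label,
                         min_coverage = min_cov, seed = seed),
          error = function(e) {
            log_msg(config, "image '", nm, "': ", label,
                    " region too small for disjoint patches; allowing overlap")
            sample_patches(img, mask = mask, n = config$n_patches,
                           side = config$patch_side, label = label,
                           min_coverage = min_cov, overlap = TRUE, seed = seed)
          })
      }
      pv <- draw(regions$viable & rep$viable, "viable", 0.9,
                 config$seed + 100 * i)
      pn <- draw(regions$non_viable, "non_viable", 1,
                 config$seed + 100 * i + 1)
      ctr <- patch_contrast(dplyr::bind_rows(pv, pn),
                            seed = config$seed + 100 * i + 2)
      list(report = rep, mask = mask,
           photometry = tibble::tibble(
             timepoint = nm,
             viable_patch_mean = ctr$viable_mean,
             nonviable_patch_mean = ctr$nonviable_mean,
             contrast = ctr$contrast,
             contrast_ci_low = ctr$ci[1], contrast_ci_high = ctr$ci[2],
             mean_snr = mean(pv$snr, na.rm = TRUE)))
    }, error = function(e) {
      stop("pipeline failed at image '", nm, "': ", conditionMessage(e),
           call. = FALSE)
    })
    reports[[nm]] <- res$report
    photo[[nm]] <- res$photometry
  }
  photometry <- dplyr::bind_rows(photo)
  summary <- dplyr::bind_cols(
    tibble::tibble(timepoint = names(reports)),
    dplyr::bind_rows(purrr::map(reports, glance)))
  bundle <- structure(
    list(reports = reports, photometry = photometry, summary = summary,
         config = config),
    class = "viability_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.viability_bundle <- function(x, ...) {
  cat("<viability_bundle> ", length(x$reports), " image(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a pipeline report bundle as JSON + CSV
#'
#' @param bundle A `viability_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$photometry, file.path(dir, "photometry.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         summary = bundle$summary,
         photometry = bundle$photometry),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", dataframe = "rows")
  invisible(dir)
}

#' Export / import ground truth as JSON
#'
#' The record carries the schema version, graft geometry, per-cell records
#' (centroid, area, nucleus, state; 0-based pixel coordinates alongside
#' physical um coordinates), the applied damage primitives and the derived
#' summaries. Cell boundary polygons (traced from the label raster) are
#' included on request; the label raster itself is not serialized.
#'
#' @param gt An `endomosaic`.
#' @param path JSON output path.
#' @param polygons Include traced cell boundary polygons (slower, larger).
#' @return `path`, invisibly.
#' @export
gt_write <- function(gt, path, polygons = FALSE) {
  px <- gt$pixel_size
  cells <- gt$cells
  cells$centroid_x_px <- gt$center_px[["x"]] + cells$x_um / px
  cells$centroid_y_px <- gt$center_px[["y"]] + cells$y_um / px
  cells$nucleus_x_px <- gt$center_px[["x"]] + cells$nucleus_x_um / px
  cells$nucleus_y_px <- gt$center_px[["y"]] + cells$nucleus_y_um / px
  obj <- list(
    schema_version = "1.0",
    graft = list(center_px = as.list(gt$center_px), radius_px = gt$radius_px,
                 pixel_size_um = px,
                 diameter_mm = gt$spec$graft_diameter,
                 image_size = gt$spec$image_size),
    summary = as.list(glance(gt)),
    damage = purrr::map(gt$damage, function(p) {
      out <- unclass(p)
      out$vertices <- if (!is.null(out$vertices)) apply(out$vertices, 1, as.list)
      out$path <- if (!is.null(out$path)) apply(out$path, 1, as.list)
      out[!purrr::map_lgl(out, is.null)]
    }),
    cells = cells)
  if (polygons) {
    oc <- EBImage::ocontour(gt$labels)
    obj$polygons <- purrr::map(oc, function(m) {
      # ocontour returns 0-based (dim1, dim2) = (row, col) = (y, x)
      list(x = as.numeric(m[, 2]), y = as.numeric(m[, 1]))
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname gt_write
#' @export
gt_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$cells <- tibble::as_tibble(obj$cells)
  obj
}

#' Hash the analytic content of a report bundle
#'
#' Stable digest of the segmentation rasters, summaries and photometry table;
#' identical configurations produce identical hashes.
#' @param bundle A `viability_bundle`.
#' @return A character hash.
#' @export
bundle_hash <- function(bundle) {
  rlang::hash(list(
    purrr::map(bundle$reports, function(r) list(r$viable, r$threshold)),
    bundle$summary, bundle$photometry))
}
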