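# summed-area table; rect_sum queries #TRUE in [y0,y1] x [x0,x1] (1-based)
integral_image <- function(mask) {
  apply(apply(mask, 2, cumsum), 1, cumsum) |> t()
}

rect_sum <- function(sat, y0, y1, x0, x1) {
  s <- sat[y1, x1]
  if (y0 > 1) s <- s - sat[y0 - 1, x1]
  if (x0 > 1) s <- s - sat[y1, x0 - 1]
  if (y0 > 1 && x0 > 1) s <- s + sat[y0 - 1, x0 - 1]
  s
}

#' Measure square fluorescence patches
#'
#' Computes the mean, SD and signal-to-noise ratio (mean/SD) of pixel
#' intensities over `side` x `side` patches, the unit of measurement used for
#' contrast and ROC photometry. Patches are either placed explicitly
#' (`locations`) or drawn by rejection sampling uniformly within a region
#' mask, requiring at least `min_coverage` of the patch area inside the mask
#' and (by default) no overlap between accepted patches.
#'
#' @param image A [fluorescence_image()] or numeric matrix.
#' @param locations Optional data frame with 0-based top-left corners `x`,
#'   `y`; when supplied, sampling parameters are ignored.
#' @param side Patch side in pixels (default 25).
#' @param label Label attached to the patches (`"viable"`, `"non_viable"`, or
#'   `"unlabeled"`).
#' @param mask Logical matrix (same size as the image) to sample within.
#' @param n Number of patches to draw when sampling.
#' @param min_coverage Minimum fraction of patch area inside `mask`.
#' @param overlap Allow sampled patches to overlap (default FALSE).
#' @param seed Seed for the sampling.
#' @return A tibble with one row per patch: `x`, `y`, `side`, `label`,
#'   `mean`, `sd`, `snr` (`NA` when the SD is 0).
#' @export
sample_patches <- function(image, locations = NULL, side = 25,
                           label = "unlabeled", mask = NULL, n = NULL,
                           min_coverage = 0.9, overlap = FALSE, seed = 1) {
  m <- img_data(image)
  stopifnot(side >= 3)
  if (side > min(dim(m))) stop("patch side exceeds image size", call. = FALSE)
  if (is.null(locations)) {
    if (is.null(mask) || is.null(n)) {
      stop("supply either explicit locations or a mask and n", call. = FALSE)
    }
    stopifnot(identical(dim(mask), dim(m)))
    sat <- integral_image(mask)
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
    ylim <- range(idx[, 1]); xlim <- range(idx[, 2])
    ylo <- max(1, ylim[1] - side + 1); xlo <- max(1, xlim[1] - side + 1)
    yhi <- min(nrow(m) - side + 1, ylim[2]); xhi <- min(ncol(m) - side + 1, xlim[2])
    acc_x <- integer(0); acc_y <- integer(0)
    withr::with_seed(seed, {
      tries <- 0
      while (length(acc_x) < n && tries < 1000 * n) {
        tries <- tries + 1
        x0 <- sample(xlo:xhi, 1); y0 <- sample(ylo:yhi, 1)
        cov <- rect_sum(sat, y0, y0 + side - 1, x0, x0 + side - 1) / side^2
        if (cov < min_coverage) next
        if (!overlap && length(acc_x) > 0 &&
            any(abs(acc_x - x0) < side & abs(acc_y - y0) < side)) next
        acc_x <- c(acc_x, x0); acc_y <- c(acc_y, y0)
      }
    })
    if (length(acc_x) < n) {
      stop("could only place ", length(acc_x), " of ", n,
           " patches in the mask (region too small?)", call. = FALSE)
    }
    locations <- tibble::tibble(x = acc_x - 1, y = acc_y - 1)
  }
  locations <- tibble::as_tibble(locations)
  bad <- locations$x < 0 | locations$y < 0 |
    locations$x + side > ncol(m) | locations$y + side > nrow(m)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("patch at (x = ", locations$x[i], ", y = ", locations$y[i],
         ") extends outside the image", call. = FALSE)
  }
  stats <- purrr::map2(locations$x, locations$y, function(x0, y0) {
    p <- m[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)]
    mu <- mean(p)
    # population SD over the patch's side^2 pixels
    s <- sqrt(mean((p - mu)^2))
    c(mu, s)
  })
  mu <- purrr::map_dbl(stats, 1)
  s <- purrr::map_dbl(stats, 2)
  tibble::tibble(x = locations$x, y = locations$y, side = side,
                 label = label, mean = mu, sd = s,
                 snr = ifelse(s > 0, mu / s, NA_real_))
}

#' Viable/non-viable fluorescence contrast from labelled patches
#'
#' Contrast is the mean of viable patch means divided by the mean of
#' non-viable patch means; a seeded bootstrap over patches gives a 95% CI for
#' the ratio.
#'
#' @param patches A patch tibble from [sample_patches()] with labels
#'   `"viable"` and `"non_viable"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @return A `contrast_result`.
#' @export
patch_contrast <- function(patches, n_boot = 2000, seed = 1) {
  v <- patches$mean[patches$label == "viable"]
  nv <- patches$mean[patches$label == "non_viable"]
  if (length(v) == 0 || length(nv) == 0) {
    stop("both viable and non_viable patches are required", call. = FALSE)
  }
  if (mean(nv) <= 0) {
    stop("non-viable mean fluorescence is zero; contrast undefined",
         call. = FALSE)
  }
  boot <- withr::with_seed(seed, {
    replicate(n_boot, {
      mean(sample(v, replace = TRUE)) / mean(sample(nv, replace = TRUE))
    })
  })
  structure(
    list(viable_mean = mean(v), nonviable_mean = mean(nv),
         contrast = mean(v) / mean(nv),
         n_viable = length(v), n_nonviable = length(nv),
         ci = unname(stats::quantile(boot, c(0.025, 0.975)))),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result> contrast ", round(x$contrast, 2), " (95% CI ",
      round(x$ci[1], 2), "-", round(x$ci[2], 2), "); viable mean ",
      round(x$viable_mean, 1), " over ", x$n_viable,
      " patches, non-viable mean ", round(x$nonviable_mean, 2), " over ",
      x$n_nonviable, "\n", sep = "")
  invisible(x)
}

#' @rdname patch_contrast
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @method glance contrast_result
#' @export
glance.contrast_result <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, ci_low = x$ci[1], ci_high = x$ci[2],
                 viable_mean = x$viable_mean, nonviable_mean = x$nonviable_mean,
                 n_viable = x$n_viable, n_nonviable = x$n_nonviable)
}

#' ROC analysis of patch mean fluorescence
#'
#' Sweeps integer thresholds 0--255 over patch mean intensities with viable
#' as the positive class: a patch is called viable when its mean is strictly
#' greater than the threshold. Reports the full sensitivity/specificity
#' curve, the trapezoidal AUC, and the operating point at a chosen cutoff
#' (fixed grey level, 40 by default, or the Youden-optimal threshold with
#' ties broken toward the lower threshold).
#'
#' @param patches Labelled patch tibble (labels `"viable"`/`"non_viable"`).
#' @param cutoff Fixed threshold used for the reported operating point.
#' @param youden If `TRUE`, choose the Youden-optimal cutoff instead.
#' @param positive_label Label of the positive class.
#' @return A `roc_result`; `tidy()` returns the threshold curve, `glance()`
#'   the AUC and operating point.
#' @export
patch_roc <- function(patches, cutoff = 40, youden = FALSE,
                      positive_label = "viable") {
  pos <- patches$mean[patches$label == positive_label]
  neg <- patches$mean[patches$label != positive_label]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  thresholds <- 0:255
  sens <- vapply(thresholds, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg <= t), numeric(1))
  # trapezoid over the swept curve in (FPR, TPR), plus the all-positive corner
  fpr <- c(1, 1 - spec)
  tpr <- c(1, sens)
  auc <- sum(-diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (youden) {
    j <- sens + spec - 1
    cutoff <- thresholds[which.max(j)]  # which.max takes the first (lowest)
  }
  stopifnot(cutoff >= 0, cutoff <= 255)
  at <- match(round(cutoff), thresholds)
  structure(
    list(curve = tibble::tibble(threshold = thresholds, sensitivity = sens,
                                specificity = spec),
         auc = auc, cutoff = cutoff,
         sensitivity = sens[at], specificity = spec[at],
         n_positive = length(pos), n_negative = length(neg),
         youden = youden),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", round(x$auc, 3), "; at cutoff ", x$cutoff,
      ": sensitivity ", round(100 * x$sensitivity, 1), "%, specificity ",
      round(100 * x$specificity, 1), "% (", x$n_positive, " positive / ",
      x$n_negative, " negative patches)\n", sep = "")
  invisible(x)
}

#' @rdname patch_roc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname patch_roc
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff, sensitivity = x$sensitivity,
                 specificity = x$specificity, n_positive = x$n_positive,
                 n_negative = x$n_negative)
}

#' @rdname patch_roc
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::annotate("point",
                      x = 1 - object$specificity, y = object$sensitivity,
                      colour = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f, cutoff = %g", object$auc,
                                  object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Geometric viable/peripheral sampling regions for a circular graft
#'
#' Builds the two default photometry regions on a graft disc: the peripheral
#' annulus used as the standard non-viable reference, and the interior viable
#' region. Both are eroded by `margin_px` so that patches do not touch the
#' blurred region boundaries.
#'
#' @param dims Image dimensions (rows, columns).
#' @param center Graft center, 0-based pixels `c(x, y)`.
#' @param radius Graft radius, pixels.
#' @param rim_width_px Width of the peripheral annulus, pixels.
#' @param margin_px Safety erosion of both regions, pixels.
#' @return A list of logical masks `viable` and `non_viable`.
#' @export
patch_regions <- function(dims, center, radius, rim_width_px,
                          margin_px = 4) {
  x <- matrix(rep(seq_len(dims[2]) - 1, each = dims[1]), nrow = dims[1])
  y <- matrix(rep(seq_len(dims[1]) - 1, times = dims[2]), nrow = dims[1])
  r <- sqrt((x - center[["x"]])^2 + (y - center[["y"]])^2)
  list(
    viable = r <= radius - rim_width_px - margin_px,
    non_viable = r >= radius - rim_width_px + margin_px &
      r <= radius - margin_px)
}
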