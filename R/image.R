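#' Fluorescence image objects
#'
#' A thin wrapper around a numeric intensity matrix on the 8-bit 0--255 grey
#' scale, carrying the physical pixel pitch. Matrices are stored
#' `[row, column]` with the origin at the top-left; exported pixel coordinates
#' are 0-based with x along columns and y along rows.
#'
#' @param data Numeric matrix of intensities in \[0, 255\].
#' @param pixel_size Pixel pitch, um/px.
#' @return A `fluorescence_image`.
#' @export
fluorescence_image <- function(data, pixel_size) {
  stopifnot(is.matrix(data), is.numeric(data), pixel_size > 0)
  structure(list(data = data, pixel_size = pixel_size),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat("<fluorescence_image> ", nrow(x$data), " x ", ncol(x$data), " px at ",
      x$pixel_size, " um/px; intensity range [", min(x$data), ", ",
      max(x$data), "]\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.fluorescence_image <- function(x, ...) x$data

#' @export
dim.fluorescence_image <- function(x) dim(x$data)

img_data <- function(image) {
  if (inherits(image, "fluorescence_image")) image$data
  else if (is.matrix(image)) image
  else stop("expected a fluorescence_image or a numeric matrix", call. = FALSE)
}

img_pixel_size <- function(image, pixel_size = NULL) {
  if (!is.null(pixel_size)) return(pixel_size)
  if (inherits(image, "fluorescence_image")) return(image$pixel_size)
  stop("pixel_size must be supplied for plain matrices", call. = FALSE)
}

#' Read a single-channel fluorescence image
#'
#' Reads 8- or 16-bit single-channel TIFF or PNG files onto the 0--255 grey
#' scale. 16-bit input is rescaled by 255/65535 with a message. RGB input is
#' rejected: extract the fluorescence channel first.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size Pixel pitch, um/px, attached to the returned image.
#' @return A [fluorescence_image()].
#' @export
read_image <- function(path, pixel_size = 5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(arr)) == 3) {
      stop("RGB/multi-channel TIFF: extract the fluorescence channel ",
           "before reading", call. = FALSE)
    }
    bits <- attr(arr, "bits.per.sample") %||% 8
    m <- matrix(as.numeric(arr), nrow = nrow(arr))
    if (bits > 8) {
      message("rescaling ", bits, "-bit input by 255/", 2^bits - 1)
      m <- m * 255 / (2^bits - 1)
    }
  } else if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) {
      stop("RGB/multi-channel PNG: extract the fluorescence channel ",
           "before reading", call. = FALSE)
    }
    m <- matrix(as.numeric(arr), nrow = nrow(arr)) * 255  # [0, 1] scale in
  } else {
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)",
         call. = FALSE)
  }
  fluorescence_image(m, pixel_size)
}

#' Write a fluorescence image as 8-bit TIFF or PNG
#'
#' @param image A [fluorescence_image()] or matrix on the 0--255 scale.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- pmin(pmax(round(img_data(image)), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else {
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)",
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname fluorescence_image
#' @param object A `fluorescence_image`.
#' @param downsample Keep every `downsample`-th pixel when plotting.
#' @param ... Unused.
#' @method autoplot fluorescence_image
#' @export
autoplot.fluorescence_image <- function(object, downsample = NULL, ...) {
  m <- object$data
  if (is.null(downsample)) downsample <- max(1L, floor(max(dim(m)) / 600))
  ri <- seq(1, nrow(m), by = downsample)
  ci <- seq(1, ncol(m), by = downsample)
  df <- tidyr::expand_grid(y = (ri - 1) * object$pixel_size,
                           x = (ci - 1) * object$pixel_size)
  df$intensity <- as.vector(t(m[ri, ci]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "green",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "grey level") +
    ggplot2::theme_minimal()
}

# Gaussian blur with replicated edges; sigma 0 is the identity
blur_image <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::imageData(EBImage::gblur(m, sigma = sigma,
                                           boundary = "replicate"))
  matrix(out, nrow = nrow(m))
}

# connected-component labelling on a logical matrix
label_components <- function(bin) {
  matrix(EBImage::imageData(EBImage::bwlabel(bin + 0)), nrow = nrow(bin))
}

# binary erosion as a plain matrix
erode_mat <- function(m, brush) {
  matrix(EBImage::imageData(EBImage::erode(m + 0, brush)), nrow = nrow(m))
}

# grayscale max filter
dilate_mat <- function(m, brush) {
  matrix(EBImage::imageData(EBImage::dilate(m + 0, brush)), nrow = nrow(m))
}

# grayscale min filter via the complemented max filter (grayscale dilation
# requires non-negative input)
min_filter <- function(m, brush) {
  ceil <- max(m) + 1
  ceil - dilate_mat(ceil - m, brush)
}
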