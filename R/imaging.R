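# Imaging: photograph -> scalar signal.
#
# Conventions (fixed so results are bit-exact and testable):
#  * pixel coordinates are 0-based (row, col), row-major, matching how image
#    software reports cursor positions;
#  * grayscale rounding is half-away-from-zero (values are non-negative, so
#    floor(x + 0.5)), not R's banker's rounding;
#  * ROI membership: a pixel belongs to a circular ROI when its centre lies
#    within Euclidean distance <= radius of the ROI centre.

fp_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ferropaper_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

round_half_up <- function(x) floor(x + 0.5)

#' 8-bit RGB image
#'
#' A thin wrapper around an `H x W x 3` integer array with channel values in
#' `[0, 255]`. This is the canonical in-memory form of an assay photograph.
#'
#' @param pixels numeric or integer array of dimension `H x W x 3`
#'   (rows x columns x channels R, G, B), all values in `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @seealso [read_assay_image()], [to_grayscale()]
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    fp_stop("`pixels` must be an H x W x 3 array", "fp_invalid_input")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    fp_stop("image must have at least one pixel", "fp_invalid_input")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    fp_stop("channel values must lie in [0, 255]", "fp_invalid_input")
  attributes(pixels) <- list(dim = dim(pixels))
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, height = d[1], width = d[2]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, 8-bit>\n", x$height, x$width))
  invisible(x)
}

#' 8-bit grayscale image
#'
#' @param pixels numeric or integer `H x W` matrix with values in `[0, 255]`.
#' @param inverted logical flag recording whether colour inversion
#'   (`255 - v`) has already been applied. The calibration signal is defined
#'   on *inverted* grayscale, where darker (more iron) spots score higher.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, inverted = FALSE) {
  if (!is.matrix(pixels))
    fp_stop("`pixels` must be a matrix", "fp_invalid_input")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    fp_stop("image must have at least one pixel", "fp_invalid_input")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    fp_stop("gray values must lie in [0, 255]", "fp_invalid_input")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, height = nrow(pixels),
                 width = ncol(pixels), inverted = isTRUE(inverted)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %s>\n", x$height, x$width,
              if (x$inverted) "inverted" else "not inverted"))
  invisible(x)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' The default is the unweighted channel mean `round((R + G + B) / 3)`.
#' The ITU-R BT.601 luma weighting
#' `round(0.299 R + 0.587 G + 0.114 B)` is available as an option; different
#' image-analysis programs use different conversions and the two do not give
#' identical intensities on coloured spots.
#'
#' @param image an [rgb_image()].
#' @param method `"unweighted_mean"` (default) or `"luma"`.
#' @return A [gray_image()] with `inverted = FALSE`.
#' @examples
#' px <- array(c(200, 100, 50), dim = c(1, 1, 3))
#' to_grayscale(rgb_image(px))$pixels          # round(350/3) = 117
#' to_grayscale(rgb_image(px), "luma")$pixels  # round(124.2) = 124
#' @export
to_grayscale <- function(image, method = c("unweighted_mean", "luma")) {
  if (!inherits(image, "rgb_image"))
    fp_stop("`image` must be an rgb_image", "fp_invalid_input")
  method <- match.arg(method)
  px <- image$pixels
  g <- switch(method,
    unweighted_mean = (px[, , 1] + px[, , 2] + px[, , 3]) / 3,
    luma = 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  )
  g <- round_half_up(g)
  dim(g) <- dim(px)[1:2]
  gray_image(g, inverted = FALSE)
}

#' Invert a grayscale image
#'
#' Maps every pixel `v` to `255 - v` and toggles the `inverted` flag. On the
#' inverted scale darker (iron-richer) spots give larger values, so intensity
#' increases with concentration. Inversion is an involution:
#' `invert_gray(invert_gray(g))` equals `g`.
#'
#' @param image a [gray_image()].
#' @return The inverted [gray_image()].
#' @export
invert_gray <- function(image) {
  if (!inherits(image, "gray_image"))
    fp_stop("`image` must be a gray_image", "fp_invalid_input")
  gray_image(255L - image$pixels, inverted = !image$inverted)
}

#' Circular detection-zone ROI
#'
#' @param center_row,center_col 0-based pixel coordinates of the ROI centre.
#' @param radius radius in pixels, > 0.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center_row, center_col, radius) {
  if (!is.finite(radius) || radius <= 0)
    fp_stop("`radius` must be > 0", "fp_invalid_input")
  if (!is.finite(center_row) || !is.finite(center_col))
    fp_stop("ROI centre must be finite", "fp_invalid_input")
  structure(list(center_row = as.numeric(center_row),
                 center_col = as.numeric(center_col),
                 radius = as.numeric(radius)),
            class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi centre (%g, %g), radius %g px>\n",
              x$center_row, x$center_col, x$radius))
  invisible(x)
}

roi_mask <- function(image, roi) {
  rows <- matrix(seq_len(image$height) - 1L, image$height, image$width)
  cols <- matrix(seq_len(image$width) - 1L, image$height, image$width,
                 byrow = TRUE)
  (rows - roi$center_row)^2 + (cols - roi$center_col)^2 <= roi$radius^2
}

#' Mean pixel intensity of a detection zone
#'
#' Averages the pixel values whose centres fall inside a circular ROI,
#' clipped to the image bounds. This is the assay's response variable; it is
#' meant to be computed on the *inverted* grayscale image (a warning is
#' issued otherwise).
#'
#' @param image a [gray_image()], normally with `inverted = TRUE`.
#' @param roi a [circular_roi()].
#' @return A list of class `intensity_measurement` with elements
#'   `mean_intensity`, `sd_intensity` (sample SD over ROI pixels, 0 when the
#'   ROI holds a single pixel) and `n_pixels`.
#' @export
mean_roi_intensity <- function(image, roi) {
  if (!inherits(image, "gray_image"))
    fp_stop("`image` must be a gray_image", "fp_invalid_input")
  if (!inherits(roi, "circular_roi"))
    fp_stop("`roi` must be a circular_roi", "fp_invalid_input")
  if (!image$inverted)
    warning("measuring a non-inverted image; the calibration signal is ",
            "defined on inverted grayscale", call. = FALSE)
  vals <- image$pixels[roi_mask(image, roi)]
  if (length(vals) == 0L)
    fp_stop("ROI contains no pixels inside the image", "fp_no_pixels")
  s <- if (length(vals) > 1L) sd(vals) else 0
  structure(list(mean_intensity = mean(vals), sd_intensity = s,
                 n_pixels = length(vals)),
            class = "intensity_measurement")
}

#' @export
print.intensity_measurement <- function(x, ...) {
  cat(sprintf("<intensity %0.2f +/- %0.2f over %d px>\n",
              x$mean_intensity, x$sd_intensity, x$n_pixels))
  invisible(x)
}

#' Automatic spot detection
#'
#' Convenience alternative to manual ROI selection: thresholds the inverted
#' image (Otsu by default), takes the largest connected bright component,
#' and returns a circular ROI at its centroid with the radius of the
#' equal-area circle, clamped to `expected_radius_range`.
#'
#' @param image an inverted [gray_image()] containing one bright, roughly
#'   circular spot.
#' @param expected_radius_range length-2 numeric, plausible spot radii in
#'   pixels; the fitted radius is clamped into this interval.
#' @param threshold optional intensity cut in `[0, 255]`; default is Otsu's
#'   threshold computed on the image.
#' @return A [circular_roi()].
#' @export
detect_spot <- function(image, expected_radius_range = c(5, Inf),
                        threshold = NULL) {
  if (!inherits(image, "gray_image"))
    fp_stop("`image` must be a gray_image", "fp_invalid_input")
  if (!image$inverted)
    warning("spot detection expects an inverted image", call. = FALSE)
  px <- image$pixels
  if (is.null(threshold)) {
    if (min(px) == max(px))
      fp_stop("uniform image: no spot to detect", "fp_detection_failure")
    threshold <- 255 * EBImage::otsu(EBImage::Image(t(px) / 255),
                                     range = c(0, 1), levels = 256L)
  }
  bin <- px > threshold
  if (!any(bin))
    fp_stop("no pixels above threshold", "fp_detection_failure")
  lab <- EBImage::bwlabel(EBImage::Image(t(bin) + 0))
  lab <- t(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  idx <- which(lab == best, arr.ind = TRUE)
  centre <- colMeans(idx) - 1  # back to 0-based
  r <- sqrt(sizes[best] / pi)
  r <- min(max(r, expected_radius_range[1]), expected_radius_range[2])
  circular_roi(centre[1], centre[2], r)
}

scale_to_8bit <- function(x, max_val) {
  if (max_val > 255) x %/% 257L else x
}

#' Read an assay photograph
#'
#' Reads PNG, TIFF or JPEG into an [rgb_image()]. Alpha channels are
#' dropped; single-channel (already grayscale) files are replicated across
#' R, G and B; 16-bit inputs are rescaled to 8 bits by integer division
#' by 257.
#'
#' @param path file path; format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return An [rgb_image()].
#' @export
read_assay_image <- function(path) {
  if (!file.exists(path))
    fp_stop(paste0("image file not found: ", path), "fp_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    x <- round_half_up(raw * (2^depth - 1))
    x <- scale_to_8bit(x, 2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    x <- round_half_up(raw * (2^depth - 1))
    x <- scale_to_8bit(x, 2^depth - 1)
  } else if (ext %in% c("jpg", "jpeg")) {
    raw <- EBImage::readImage(path)
    x <- round_half_up(EBImage::imageData(raw) * 255)
    # EBImage stores x (width) first; transpose back to row-major
    x <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
  } else {
    fp_stop(paste0("unsupported image format: .", ext), "fp_io_error")
  }
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(x, dim = c(dim(x)[1:2], 3L))
  rgb_image(x)
}

#' Write a grayscale image as PNG
#'
#' Used by the CLI's `--save-intermediates` option to persist the grayscale
#' or inverted intermediate.
#'
#' @param image a [gray_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  if (!inherits(image, "gray_image"))
    fp_stop("`image` must be a gray_image", "fp_invalid_input")
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
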