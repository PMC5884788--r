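#' Camera image frame
#'
#' A single fluorescence image with its camera dark level (the intensity
#' offset recorded with no light, a camera property supplied by the user,
#' never estimated from the image).
#'
#' @param pixels Numeric matrix of pixel intensities (finite).
#' @param pixel_size Optional pixel size on the sample, nm.
#' @param dark_level Camera offset in intensity units (>= 0; default 0).
#' @return An object of class `"image_frame"`.
#' @export
image_frame <- function(pixels, pixel_size = NULL, dark_level = 0) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("pixel values must be finite", call. = FALSE)
  if (!is.finite(dark_level) || dark_level < 0)
    stop("`dark_level` must be >= 0", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 dark_level = dark_level),
            class = "image_frame")
}

#' Read a TIFF image into an image frame
#'
#' Reads a single-frame or stack TIFF; integer images are returned as raw
#' camera counts (not rescaled to \[0, 1\]).  Stacks are either averaged or
#' indexed.
#'
#' @param path TIFF file path.
#' @param frame `"mean"` to average a stack, or a 1-based frame index.
#' @param pixel_size,dark_level Metadata passed to [image_frame()].
#' @return An [image_frame()].
#' @export
read_image_tiff <- function(path, frame = "mean", pixel_size = NULL,
                            dark_level = 0) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  px <- if (identical(frame, "mean")) {
    Reduce(`+`, imgs) / length(imgs)
  } else {
    frame <- as.integer(frame)
    if (is.na(frame) || frame < 1L || frame > length(imgs))
      stop("frame index out of range (stack has ", length(imgs),
           " frame(s))", call. = FALSE)
    imgs[[frame]]
  }
  if (length(dim(px)) == 3L) px <- px[, , 1]  # first channel
  image_frame(px, pixel_size = pixel_size, dark_level = dark_level)
}

.check_roi <- function(image, roi) {
  d <- dim(image$pixels)
  if (is.null(roi)) return(c(1L, d[1], 1L, d[2]))
  roi <- as.integer(roi)
  if (length(roi) != 4L || any(is.na(roi)))
    stop("`roi` must be c(row_min, row_max, col_min, col_max)",
         call. = FALSE)
  if (roi[1] < 1L || roi[3] < 1L || roi[2] > d[1] || roi[4] > d[2] ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("`roi` out of image bounds", call. = FALSE)
  roi
}

#' Crop an image to a rectangular region of interest
#'
#' Mirrors the optical "trimming" of the beam with slits: restricts analysis
#' to the illuminated part of the sensor.  Metadata (pixel size, dark level)
#' is preserved.
#'
#' @param image An [image_frame()].
#' @param roi Integer vector `c(row_min, row_max, col_min, col_max)`,
#'   1-based inclusive, within bounds.
#' @return The cropped [image_frame()].
#' @export
roi_crop <- function(image, roi) {
  stopifnot(inherits(image, "image_frame"))
  roi <- .check_roi(image, roi)
  image_frame(image$pixels[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE],
              pixel_size = image$pixel_size, dark_level = image$dark_level)
}

#' Display range of an image
#'
#' The display convention used for side-by-side uniformity figures: the lower
#' limit is the camera dark level and the upper limit is `factor` times the
#' `percentile`-th percentile of the dark-subtracted pixel values (added back
#' onto the dark level), computed with linear interpolation between order
#' statistics.  With a zero dark level this is simply `factor` times the
#' percentile of the raw pixel values.
#'
#' @param image An [image_frame()].
#' @param percentile Percentile in (0, 100\] (default 95).
#' @param factor Multiplier on the percentile (default 1.2).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
display_range <- function(image, percentile = 95, factor = 1.2) {
  stopifnot(inherits(image, "image_frame"))
  if (percentile <= 0 || percentile > 100)
    stop("`percentile` must be in (0, 100]", call. = FALSE)
  q <- stats::quantile(image$pixels - image$dark_level, percentile / 100,
                       names = FALSE, type = 7)
  lo <- image$dark_level
  hi <- image$dark_level + factor * q
  if (!(hi > lo))
    stop("degenerate display range: image does not exceed the dark level",
         call. = FALSE)
  c(lo = lo, hi = hi)
}

#' Illumination-uniformity statistics over a region of interest
#'
#' Flatness metrics for an illumination QC image (e.g. a uniform fluorophore
#' layer): the coefficient of variation of the dark-subtracted ROI, the
#' fraction of ROI pixels within `±band` of the ROI median, and a histogram
#' over the display range.  Out-of-range pixel values are clipped into the
#' edge bins so the histogram always conserves the ROI pixel count.
#'
#' @param image An [image_frame()].
#' @param roi Optional `c(row_min, row_max, col_min, col_max)`; default the
#'   full frame.
#' @param band Half-width of the flatness band, as a fraction of the ROI
#'   median (default 0.1).
#' @param n_bins Histogram bin count (default 256).
#' @param percentile,factor Passed to [display_range()] (computed on the ROI
#'   crop).
#' @return An object of class `"uniformity_report"`: a list with
#'   `display_lo`, `display_hi`, `breaks`, `counts`, `cv`, `flat_fraction`,
#'   `roi`, `n_pixels`.
#' @export
uniformity_stats <- function(image, roi = NULL, band = 0.1, n_bins = 256L,
                             percentile = 95, factor = 1.2) {
  stopifnot(inherits(image, "image_frame"))
  roi <- .check_roi(image, roi)
  sub <- roi_crop(image, roi)
  vals <- as.numeric(sub$pixels) - image$dark_level
  m <- mean(vals)
  if (m <= 0)
    stop("ROI mean does not exceed the dark level", call. = FALSE)
  cv <- stats::sd(vals) / m
  med <- stats::median(vals)
  flat_fraction <- mean(abs(vals - med) <= band * med)
  dr <- display_range(sub, percentile = percentile, factor = factor)
  breaks <- seq(dr["lo"], dr["hi"], length.out = n_bins + 1L)
  clipped <- pmin(pmax(as.numeric(sub$pixels), dr["lo"]), dr["hi"])
  bin <- findInterval(clipped, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(display_lo = unname(dr["lo"]), display_hi = unname(dr["hi"]),
                 breaks = breaks, counts = counts, cv = cv,
                 flat_fraction = flat_fraction, roi = roi,
                 n_pixels = length(vals)),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf(paste0("<uniformity_report: cv %.4f, flat fraction %.3f, ",
                     "display [%.3g, %.3g], %d pixels>\n"),
              x$cv, x$flat_fraction, x$display_lo, x$display_hi, x$n_pixels))
  invisible(x)
}

#' Relative power of two images over a region of interest
#'
#' Ratio of dark-subtracted pixel sums of `image_a` to `image_b` over the
#' same ROI: the measurement a user runs on calibration images to quantify,
#' e.g., how much power a beamshaper (or trimming aperture) loses relative
#' to the unshaped beam.
#'
#' @param image_a,image_b [image_frame()]s of identical dimensions.
#' @param roi Optional `c(row_min, row_max, col_min, col_max)`; default full
#'   frame.
#' @return The power ratio (numeric scalar).
#' @export
power_ratio <- function(image_a, image_b, roi = NULL) {
  stopifnot(inherits(image_a, "image_frame"), inherits(image_b, "image_frame"))
  if (!all(dim(image_a$pixels) == dim(image_b$pixels)))
    stop("images must have identical dimensions", call. = FALSE)
  roi <- .check_roi(image_a, roi)
  a <- image_a$pixels[roi[1]:roi[2], roi[3]:roi[4]] - image_a$dark_level
  b <- image_b$pixels[roi[1]:roi[2], roi[3]:roi[4]] - image_b$dark_level
  den <- sum(b)
  if (den <= 0)
    stop("denominator power is not positive over the ROI", call. = FALSE)
  sum(a) / den
}
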