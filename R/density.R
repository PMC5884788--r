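#' Remove localizations that persist from the previous frame
#'
#' A fluorophore that stays ON across consecutive camera frames is localized
#' once per frame, inflating apparent density where ON times are long.  This
#' filter removes every record in frame *f* that lies within `radius` of any
#' record of the *raw* (pre-filter) table in frame *f - 1*, so each blink is
#' counted once.  Because removal decisions are taken against the raw table,
#' the filter is order-independent and idempotent.  Records in the earliest
#' frame are never removed, and proximity within the *same* frame is not
#' persistence.  The distance test is inclusive (<= `radius`).
#'
#' @param table A [localization_table()] (canonical, frame-sorted).
#' @param radius Linking radius in nm (>= 0; default 100).
#' @return The filtered table (same class and metadata, survivor order
#'   preserved).
#' @export
persistence_filter <- function(table, radius = 100) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius < 0)
    stop("`radius` must be a single number >= 0", call. = FALSE)
  n <- nrow(table)
  if (n == 0L) return(table)
  idx_by_frame <- split(seq_len(n), table$frame)
  frames <- as.integer(names(idx_by_frame))
  drop <- logical(n)
  r2 <- radius^2
  for (k in seq_along(frames)) {
    prev <- match(frames[k] - 1L, frames)
    if (is.na(prev)) next
    cur_i <- idx_by_frame[[k]]
    prev_i <- idx_by_frame[[prev]]
    dx <- outer(table$x[cur_i], table$x[prev_i], `-`)
    dy <- outer(table$y[cur_i], table$y[prev_i], `-`)
    hit <- rowSums(dx * dx + dy * dy <= r2) > 0L
    drop[cur_i[hit]] <- TRUE
  }
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  # subsetting a data.frame keeps class but we restore attributes explicitly
  attributes(out)[c("fov_size", "pixel_size", "dialect")] <-
    attributes(table)[c("fov_size", "pixel_size", "dialect")]
  out
}

#' Low-resolution localization density map
#'
#' Bins localizations into a `grid_n` x `grid_n` count matrix over the square
#' field of view, the coarse "map" used to compare apparent fluorophore
#' density between illumination conditions.  Bins are half-open `[lo, hi)`
#' per axis with the final bin closed, so a record exactly on the far FOV
#' edge is kept.  Records outside the FOV are excluded from the counts and
#' tallied in `n_excluded`.
#'
#' @param table A [localization_table()].
#' @param fov_size Field of view in nm (> 0); defaults to the table's
#'   `fov_size` attribute.
#' @param grid_n Bins per axis (integer >= 1; default 64).
#' @param origin Length-2 lower-left corner of the FOV in nm (default
#'   `c(0, 0)`).
#' @return An object of class `"density_map"`: a list with `counts` (rows =
#'   y bins, columns = x bins), `fov_size`, `grid_n`, `origin`,
#'   `n_excluded`.
#' @export
density_map <- function(table, fov_size = NULL, grid_n = 64L,
                        origin = c(0, 0)) {
  if (is.null(fov_size)) fov_size <- attr(table, "fov_size")
  if (is.null(fov_size) || !is.finite(fov_size) || fov_size <= 0)
    stop("`fov_size` must be > 0 (give it or set the table attribute)",
         call. = FALSE)
  grid_n <- as.integer(grid_n)
  if (is.na(grid_n) || grid_n < 1L)
    stop("`grid_n` must be an integer >= 1", call. = FALSE)
  xr <- table$x - origin[1]
  yr <- table$y - origin[2]
  inside <- xr >= 0 & xr <= fov_size & yr >= 0 & yr <= fov_size
  bx <- pmin(floor(xr[inside] / fov_size * grid_n), grid_n - 1L) + 1L
  by <- pmin(floor(yr[inside] / fov_size * grid_n), grid_n - 1L) + 1L
  counts <- matrix(0L, grid_n, grid_n)
  if (any(inside)) {
    tab <- table(factor(by, levels = seq_len(grid_n)),
                 factor(bx, levels = seq_len(grid_n)))
    counts <- matrix(as.integer(tab), grid_n, grid_n)
  }
  structure(list(counts = counts, fov_size = fov_size, grid_n = grid_n,
                 origin = as.numeric(origin),
                 n_excluded = sum(!inside)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map: %d x %d bins, %d records (%d excluded)>\n",
              x$grid_n, x$grid_n, sum(x$counts), x$n_excluded))
  invisible(x)
}

#' Elementwise ratio of two density maps
#'
#' If illumination has no effect on localization probability, the ratio of
#' two density maps of the same structure is uniform up to counting noise.
#' Cells whose denominator count is zero are undefined and marked `NA`
#' (never infinite or zero-filled); they are excluded from all downstream
#' summaries.
#'
#' @param map_num,map_den [density_map()]s with identical `grid_n`,
#'   `fov_size` and `origin`.
#' @param num_label,den_label Provenance labels stored in the result.
#' @return An object of class `"ratio_map"`: a list with `values`
#'   (matrix, `NA` = undefined), `grid_n`, `fov_size`, `origin`,
#'   `num_label`, `den_label`.
#' @export
ratio_map <- function(map_num, map_den,
                      num_label = "numerator", den_label = "denominator") {
  stopifnot(inherits(map_num, "density_map"), inherits(map_den, "density_map"))
  if (map_num$grid_n != map_den$grid_n ||
      map_num$fov_size != map_den$fov_size ||
      !all(map_num$origin == map_den$origin))
    stop("density maps must share grid_n, fov_size and origin",
         call. = FALSE)
  values <- map_num$counts / map_den$counts
  values[map_den$counts == 0L] <- NA_real_
  structure(list(values = values, grid_n = map_num$grid_n,
                 fov_size = map_num$fov_size, origin = map_num$origin,
                 num_label = num_label, den_label = den_label),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<ratio_map (%s / %s): %d x %d bins, %d defined, median %.3f>\n",
    x$num_label, x$den_label, x$grid_n, x$grid_n, length(v),
    if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

# Bin-center coordinates of a density map, in nm FOV coordinates.
.bin_centers <- function(map) {
  cen <- map$origin[1] + (seq_len(map$grid_n) - 0.5) / map$grid_n *
    map$fov_size
  ceny <- map$origin[2] + (seq_len(map$grid_n) - 0.5) / map$grid_n *
    map$fov_size
  list(x = cen, y = ceny)
}

#' Illumination-bias (undercount) statistic
#'
#' Quantifies intensity-dependent loss of localizations under Gaussian
#' illumination.  Bins are partitioned by the Gaussian intensity evaluated at
#' their centers into a high-intensity region (intensity above its
#' `high_quantile` across bins; the beam center) and a low-intensity region
#' (below `low_quantile`; the field edges).  Within each region the median of
#' the Gaussian/flat count ratio is taken over defined cells whose flat-field
#' (denominator) count is at least `min_bin_count`, and the undercount factor
#' is the low-region median divided by the high-region median.  A factor
#' above 1 means the beam center recovered proportionally fewer
#' localizations than the edges.
#'
#' @param map_gauss Density map acquired under Gaussian illumination
#'   (numerator).
#' @param map_flat Density map acquired under flat (top-hat) illumination
#'   (denominator), same geometry.
#' @param illumination The [gaussian_beam()] used for the Gaussian
#'   acquisition, in nm FOV coordinates.
#' @param high_quantile,low_quantile Quantiles of the bin-center intensity
#'   distribution delimiting the regions (defaults 0.8 and 0.2;
#'   `0 < low < high < 1`).
#' @param min_bin_count Minimum flat-field count for a bin to enter the
#'   medians (default 5).
#' @return An object of class `"bias_report"`: a list with `high_median`,
#'   `low_median`, `undercount_factor`, logical region masks `high_region`
#'   and `low_region`, and the number of qualifying bins per region.
#' @export
illumination_bias_statistic <- function(map_gauss, map_flat, illumination,
                                        high_quantile = 0.8,
                                        low_quantile = 0.2,
                                        min_bin_count = 5L) {
  stopifnot(inherits(map_gauss, "density_map"),
            inherits(map_flat, "density_map"),
            inherits(illumination, "gaussian_beam"))
  if (!(low_quantile > 0 && high_quantile < 1 &&
        low_quantile < high_quantile))
    stop("need 0 < low_quantile < high_quantile < 1", call. = FALSE)
  rm_ <- ratio_map(map_gauss, map_flat)
  cen <- .bin_centers(map_gauss)
  intens <- outer(cen$y, cen$x,
                  function(y, x) beam_intensity(illumination, x, y))
  hi_thr <- stats::quantile(intens, high_quantile, names = FALSE)
  lo_thr <- stats::quantile(intens, low_quantile, names = FALSE)
  qualifying <- !is.na(rm_$values) & map_flat$counts >= min_bin_count
  high_region <- intens >= hi_thr
  low_region <- intens <= lo_thr
  hi_vals <- rm_$values[high_region & qualifying]
  lo_vals <- rm_$values[low_region & qualifying]
  if (!length(hi_vals))
    stop("insufficient data: no qualifying bins in the high-intensity region",
         call. = FALSE)
  if (!length(lo_vals))
    stop("insufficient data: no qualifying bins in the low-intensity region",
         call. = FALSE)
  high_median <- stats::median(hi_vals)
  low_median <- stats::median(lo_vals)
  structure(list(high_median = high_median, low_median = low_median,
                 undercount_factor = low_median / high_median,
                 high_region = high_region, low_region = low_region,
                 n_high = length(hi_vals), n_low = length(lo_vals),
                 min_bin_count = min_bin_count),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<bias_report: undercount factor %.3f ",
    "(low-I median %.3f / high-I median %.3f; %d / %d bins)>\n"),
    x$undercount_factor, x$low_median, x$high_median, x$n_low, x$n_high))
  invisible(x)
}

#' Write a density or ratio map as delimited text
#'
#' Writes the matrix as tab-separated values preceded by `#` comment lines
#' recording the geometry; undefined ratio cells are written as `NA`.
#'
#' @param map A [density_map()] or [ratio_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_txt <- function(map, path) {
  m <- if (inherits(map, "density_map")) map$counts
       else if (inherits(map, "ratio_map")) map$values
       else stop("`map` must be a density_map or ratio_map", call. = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s %d x %d, fov_size %g nm, origin (%g, %g)",
                     class(map)[1], nrow(m), ncol(m), map$fov_size,
                     map$origin[1], map$origin[2]), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
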