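#' Canonical localization table
#'
#' The in-memory container all analysis functions operate on: one row per
#' localization, with 0-based frame indices and coordinates in nanometres.
#' Records are stably sorted by frame (within-frame order preserved), so that
#' downstream persistence filtering is deterministic.  Metadata (source
#' dialect, field of view, camera pixel size) travels in attributes.
#'
#' @param frame Integer vector of frame indices (>= 0; 0-based).
#' @param x,y Numeric coordinates in nm (finite).
#' @param photons Optional numeric photon counts (>= 0).
#' @param uncertainty Optional numeric localization precision in nm.
#' @param fov_size,pixel_size Optional metadata in nm.
#' @param dialect Optional source-dialect label.
#' @return A data.frame of class `"localization_table"` with columns
#'   `frame`, `x`, `y` and optionally `photons`, `uncertainty`.
#' @export
localization_table <- function(frame, x, y, photons = NULL,
                               uncertainty = NULL, fov_size = NULL,
                               pixel_size = NULL, dialect = NA_character_) {
  n <- length(frame)
  if (length(x) != n || length(y) != n)
    stop("`frame`, `x`, `y` must have equal length", call. = FALSE)
  frame <- as.integer(frame)
  if (n > 0 && (any(is.na(frame)) || any(frame < 0L)))
    stop("`frame` must be integer and >= 0", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("`x` and `y` must be finite", call. = FALSE)
  df <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y))
  if (!is.null(photons)) {
    if (length(photons) != n)
      stop("`photons` must match the number of records", call. = FALSE)
    if (any(photons[!is.na(photons)] < 0))
      stop("`photons` must be >= 0", call. = FALSE)
    df$photons <- as.numeric(photons)
  }
  if (!is.null(uncertainty)) {
    if (length(uncertainty) != n)
      stop("`uncertainty` must match the number of records", call. = FALSE)
    df$uncertainty <- as.numeric(uncertainty)
  }
  # stable (radix) sort by frame only: within-frame order is preserved
  df <- df[order(df$frame, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("localization_table", "data.frame"),
            fov_size = fov_size, pixel_size = pixel_size, dialect = dialect)
}

#' Coerce a data.frame to a canonical localization table
#'
#' @param df A data.frame with columns `frame`, `x`, `y` and optionally
#'   `photons`, `uncertainty`.
#' @inheritParams localization_table
#' @return A `"localization_table"`; see [localization_table()].
#' @export
as_localization_table <- function(df, fov_size = NULL, pixel_size = NULL,
                                  dialect = NA_character_) {
  req <- c("frame", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  localization_table(df$frame, df$x, df$y,
                     photons = df[["photons"]],
                     uncertainty = df[["uncertainty"]],
                     fov_size = fov_size, pixel_size = pixel_size,
                     dialect = dialect)
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table: %d records, %s frames>\n",
              nrow(x),
              if (nrow(x)) length(unique(x$frame)) else 0L))
  if (!is.null(attr(x, "fov_size")))
    cat(sprintf("  fov_size: %g nm\n", attr(x, "fov_size")))
  NextMethod()
  invisible(x)
}

#' Validate a localization table against basic sanity rules
#'
#' Report-only check (never mutates): flags non-finite coordinates, negative
#' photon counts, and records outside the field of view.
#'
#' @param table A [localization_table()] (or plain data.frame with the same
#'   columns).
#' @param fov_size Optional field of view in nm; when given, records with
#'   `x` or `y` outside `[0, fov_size]` are flagged.
#' @return A data.frame of issues with columns `row`, `field`, `issue`;
#'   zero rows when the table is clean.
#' @export
validate_table <- function(table, fov_size = NULL) {
  issues <- list()
  flag <- function(rows, field, issue) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(row = rows, field = field,
                                                   issue = issue)
  }
  flag(which(!is.finite(table$x)), "x", "non-finite")
  flag(which(!is.finite(table$y)), "y", "non-finite")
  if (!is.null(table$photons)) {
    flag(which(!is.na(table$photons) & table$photons < 0), "photons",
         "negative")
    flag(which(is.nan(table$photons) | is.infinite(table$photons)),
         "photons", "non-finite")
  }
  if (!is.null(fov_size)) {
    flag(which(is.finite(table$x) & (table$x < 0 | table$x > fov_size)),
         "x", "outside field of view")
    flag(which(is.finite(table$y) & (table$y < 0 | table$y > fov_size)),
         "y", "outside field of view")
  }
  if (!length(issues))
    return(data.frame(row = integer(), field = character(),
                      issue = character()))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
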