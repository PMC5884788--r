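# Column-name aliases accepted across dialects (all compared lower-case,
# units stripped).  rapidSTORM writes identifiers like "Position-0-0";
# ThunderSTORM writes "x [nm]".
.col_aliases <- list(
  frame       = c("frame", "imagenumber-0-0", "frame_ix", "t"),
  x           = c("x", "position-0-0"),
  y           = c("y", "position-1-0"),
  photons     = c("photons", "intensity", "amplitude-0-0", "amp-0-0"),
  uncertainty = c("uncertainty", "precision", "sigma")
)

# Strip a trailing bracketed unit ("x [nm]" -> "x") and return both the bare
# name and the unit (NA when absent).
.split_unit <- function(nm) {
  unit <- rep(NA_character_, length(nm))
  has <- grepl("\\[.+\\]\\s*$", nm)
  unit[has] <- sub("^.*\\[(.+)\\]\\s*$", "\\1", nm[has])
  bare <- trimws(sub("\\s*\\[.+\\]\\s*$", "", nm))
  list(bare = tolower(bare), unit = unit)
}

.match_columns <- function(raw_names) {
  su <- .split_unit(raw_names)
  out <- list()
  for (field in names(.col_aliases)) {
    hit <- which(su$bare %in% .col_aliases[[field]])
    if (length(hit)) out[[field]] <- list(index = hit[1], unit = su$unit[hit[1]])
  }
  out
}

.length_factor <- function(unit, default = 1) {
  if (is.na(unit)) return(default)
  switch(tolower(unit),
         "nm" = 1, "um" = 1000, "µm" = 1000, "micron" = 1000,
         "px" = NA_real_,  # needs pixel_size; handled by caller
         stop("unsupported length unit: ", unit, call. = FALSE))
}

# Convert character columns to numeric, failing loudly with the 1-based data
# line number of the first offending cell (or dropping bad lines on request).
.numeric_or_die <- function(chr, field, path, header_lines, skip_bad_lines) {
  suppressWarnings(num <- as.numeric(chr))
  bad <- which(is.na(num) & !is.na(chr) & nzchar(trimws(chr)))
  if (length(bad) && !skip_bad_lines)
    stop(sprintf("%s: non-numeric value %s in column '%s' at line %d",
                 path, dQuote(chr[bad[1]]), field, bad[1] + header_lines),
         call. = FALSE)
  list(values = num, bad_rows = bad)
}

#' Read a localization table from delimited text
#'
#' Parses the two dialects common in SMLM work plus a caller-mapped generic
#' CSV, and returns one canonical in-memory table (nm coordinates, 0-based
#' frames, stably sorted by frame):
#'
#' * `"rapidstorm"`: whitespace-separated values with a leading comment line
#'   naming the columns (either plain names or rapidSTORM identifiers such as
#'   `Position-0-0`); frame indices are 0-based in the file.
#' * `"thunderstorm"`: comma-separated with a quoted header such as
#'   `"frame","x [nm]","y [nm]","intensity [photon]"`; frame indices are
#'   1-based in the file and converted on read.
#' * `"generic"`: delimited text with a caller-supplied `column_map` naming
#'   which file column holds each canonical field.
#'
#' `"auto"` sniffs the dialect from the first line: a `#` comment means
#' rapidSTORM style, a comma-separated header containing `frame` means
#' ThunderSTORM style.
#'
#' @param path Path to an existing, non-empty file.
#' @param dialect One of `"auto"`, `"rapidstorm"`, `"thunderstorm"`,
#'   `"generic"`.
#' @param xy_unit Unit of the coordinate columns when the header does not
#'   declare one: `"nm"` (default) or `"um"`.
#' @param column_map Named character vector for `dialect = "generic"`, e.g.
#'   `c(frame = "t", x = "xpos", y = "ypos")`; `photons` and `uncertainty`
#'   entries are optional.
#' @param sep Field separator for `dialect = "generic"` (default `","`).
#' @param frame_base Frame index origin in a generic file (0 or 1;
#'   default 0).
#' @param skip_bad_lines Drop lines with non-numeric cells (with a warning)
#'   instead of failing; off by default because silent drops bias density
#'   maps.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path,
                               dialect = c("auto", "rapidstorm",
                                           "thunderstorm", "generic"),
                               xy_unit = c("nm", "um"),
                               column_map = NULL, sep = ",",
                               frame_base = 0L,
                               skip_bad_lines = FALSE) {
  dialect <- match.arg(dialect)
  xy_unit <- match.arg(xy_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    stop("empty file: ", path, call. = FALSE)

  if (dialect == "auto") {
    dialect <- if (startsWith(trimws(first), "#")) "rapidstorm"
               else if (grepl(",", first) &&
                        grepl("frame", tolower(first), fixed = TRUE))
                 "thunderstorm"
               else if (!is.null(column_map)) "generic"
               else stop("could not sniff dialect of ", path,
                         "; pass `dialect` (and `column_map` for generic ",
                         "files)", call. = FALSE)
  }

  if (dialect == "rapidstorm") {
    raw_names <- strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]
    n_lines <- length(readLines(path))
    df <- if (n_lines < 2L) {
      as.data.frame(matrix(character(), ncol = length(raw_names), nrow = 0L))
    } else {
      utils::read.table(path, skip = 1L, header = FALSE,
                        colClasses = "character",
                        col.names = paste0("V", seq_along(raw_names)),
                        fill = FALSE)
    }
    .assemble_table(df, raw_names, path, header_lines = 1L,
                    xy_unit = xy_unit, frame_base = 0L,
                    skip_bad_lines = skip_bad_lines, dialect = "rapidstorm")
  } else if (dialect == "thunderstorm") {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
    .assemble_table(df, names(df), path, header_lines = 1L,
                    xy_unit = xy_unit, frame_base = 1L,
                    skip_bad_lines = skip_bad_lines, dialect = "thunderstorm")
  } else {  # generic
    if (is.null(column_map) || !all(c("frame", "x", "y") %in%
                                    names(column_map)))
      stop("generic dialect needs `column_map` with at least frame, x, y",
           call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE)
    miss <- setdiff(unname(column_map), names(df))
    if (length(miss))
      stop(path, ": mapped column(s) not in file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    # rename mapped columns to canonical names, drop the rest
    df <- df[, unname(column_map), drop = FALSE]
    names(df) <- names(column_map)
    .assemble_table(df, names(df), path, header_lines = 1L,
                    xy_unit = xy_unit, frame_base = as.integer(frame_base),
                    skip_bad_lines = skip_bad_lines, dialect = "generic")
  }
}

.assemble_table <- function(df, raw_names, path, header_lines, xy_unit,
                            frame_base, skip_bad_lines, dialect) {
  cols <- .match_columns(raw_names)
  miss <- setdiff(c("frame", "x", "y"), names(cols))
  if (length(miss))
    stop(path, ": required column(s) missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  default_fac <- if (xy_unit == "um") 1000 else 1
  get_num <- function(field) {
    .numeric_or_die(df[[cols[[field]]$index]], field, path, header_lines,
                    skip_bad_lines)
  }
  fr <- get_num("frame"); xx <- get_num("x"); yy <- get_num("y")
  ph <- if ("photons" %in% names(cols)) get_num("photons") else NULL
  un <- if ("uncertainty" %in% names(cols)) get_num("uncertainty") else NULL
  bad <- sort(unique(c(fr$bad_rows, xx$bad_rows, yy$bad_rows,
                       ph$bad_rows, un$bad_rows)))
  keep <- if (length(bad)) setdiff(seq_len(nrow(df)), bad) else
    seq_len(nrow(df))
  if (length(bad))
    warning(sprintf("%s: dropped %d malformed line(s)", path, length(bad)),
            call. = FALSE)
  fx <- .length_factor(cols$x$unit, default_fac)
  fy <- .length_factor(cols$y$unit, default_fac)
  fu <- if (!is.null(un)) .length_factor(cols$uncertainty$unit, default_fac)
        else 1
  localization_table(
    frame = fr$values[keep] - frame_base,
    x = xx$values[keep] * fx,
    y = yy$values[keep] * fy,
    photons = if (!is.null(ph)) ph$values[keep],
    uncertainty = if (!is.null(un)) un$values[keep] * fu,
    dialect = dialect)
}

#' Write a localization table to delimited text
#'
#' Inverse of [read_localizations()]: coordinates are written in nm with six
#' decimal places, so a read-after-write round trip agrees to better than
#' 1e-6 nm; frame indices are restored to each dialect's convention (1-based
#' for ThunderSTORM, 0-based for rapidSTORM).  Optional columns (`photons`,
#' `uncertainty`) are written only when present.
#'
#' @param table A [localization_table()].
#' @param path Output path.
#' @param dialect `"thunderstorm"` (CSV, quoted headers) or `"rapidstorm"`
#'   (whitespace table with a `#` header line).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("thunderstorm", "rapidstorm")) {
  dialect <- match.arg(dialect)
  has_ph <- !is.null(table$photons)
  has_un <- !is.null(table$uncertainty)
  fmt <- function(v) sprintf("%.6f", v)
  if (dialect == "thunderstorm") {
    hdr <- c("\"frame\"", "\"x [nm]\"", "\"y [nm]\"",
             if (has_ph) "\"intensity [photon]\"",
             if (has_un) "\"uncertainty [nm]\"")
    body <- cbind(format(table$frame + 1L, trim = TRUE, scientific = FALSE),
                  fmt(table$x), fmt(table$y),
                  if (has_ph) fmt(table$photons),
                  if (has_un) fmt(table$uncertainty))
    lines <- c(paste(hdr, collapse = ","),
               if (nrow(table)) apply(body, 1L, paste, collapse = ","))
  } else {
    hdr <- paste("#", paste(c("x", "y", "frame",
                              if (has_ph) "photons",
                              if (has_un) "uncertainty"), collapse = " "))
    body <- cbind(fmt(table$x), fmt(table$y),
                  format(table$frame, trim = TRUE, scientific = FALSE),
                  if (has_ph) fmt(table$photons),
                  if (has_un) fmt(table$uncertainty))
    lines <- c(hdr,
               if (nrow(table)) apply(body, 1L, paste, collapse = " "))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
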