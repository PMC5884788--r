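# Shared fixtures and independent oracles used across test files.

# Quadratic-time reference implementation of the persistence filter: for
# every record, scan all raw records of the immediately preceding frame.
persistence_oracle <- function(table, radius) {
  keep <- rep(TRUE, nrow(table))
  for (i in seq_len(nrow(table))) {
    prev <- which(table$frame == table$frame[i] - 1L)
    if (length(prev)) {
      d2 <- (table$x[prev] - table$x[i])^2 + (table$y[prev] - table$y[i])^2
      if (any(d2 <= radius^2)) keep[i] <- FALSE
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random canonical localization table over a square FOV.
random_loc_table <- function(n, n_frames = 50L, fov = 10000,
                             photons = TRUE) {
  localization_table(
    frame = sample.int(n_frames, n, replace = TRUE) - 1L,
    x = stats::runif(n, 0, fov), y = stats::runif(n, 0, fov),
    photons = if (photons) stats::runif(n, 100, 2000),
    fov_size = fov)
}

# A unit-level top-hat and a centered Gaussian over the default FOV, in nm.
fov_beams <- function(fov = 60400, peak = 3, sigma_frac = 0.5) {
  list(tophat = tophat_beam(side = fov, intensity = 1,
                            center = c(fov / 2, fov / 2)),
       gaussian = gaussian_beam(amplitude = peak, sigma = sigma_frac * fov,
                                center = c(fov / 2, fov / 2)))
}

# Write delimited-text fixture lines to a temp file and return the path.
write_fixture_lines <- function(lines, fileext = ".csv") {
  path <- tempfile(fileext = fileext)
  writeLines(lines, path)
  path
}
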