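# Emitter state codes used throughout the simulator.
STATE_OFF <- 0L
STATE_ON <- 1L
STATE_BLEACHED <- 2L

# --- independent RNG streams -------------------------------------------------
# One root seed expands into per-stage Mersenne-Twister streams (ground
# truth, kinetics, photons, localization noise) so that, e.g., changing the
# photon model never perturbs the switching trajectories.

.derive_seed <- function(seed, stage) {
  offs <- c(ground_truth = 101L, kinetics = 211L, photons = 307L,
            noise = 401L, pair_second = 503L)
  if (!stage %in% names(offs)) stop("unknown RNG stage: ", stage)
  # keep within 32-bit signed range
  as.integer((as.double(seed) * 69069 + offs[[stage]]) %% 2147483647)
}

.new_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister")
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  e
}

.with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

# --- parameter containers ----------------------------------------------------

#' Photophysics parameters for the blinking simulator
#'
#' Per-frame photoswitching kinetics of a dSTORM fluorophore.  The switch-off,
#' bleaching and emission rates scale linearly with the local relative
#' excitation intensity \eqn{I} (1 = the top-hat level); the switch-on rate is
#' intensity-independent, modelling spontaneous recovery from the dark state
#' in a reducing imaging buffer.  Per-frame transition probabilities are
#' derived as \eqn{1 - \exp(-\mathrm{rate})}, which keeps them in \[0, 1\] for
#' any non-negative rate.
#'
#' The defaults are illustrative rather than measurements of any particular
#' dye: they are chosen so that over a default-length acquisition an emitter's
#' blinking budget is exhausted under a Gaussian peak of about three times the
#' flat-field level, but not at the field edges, producing a visible
#' center undercount in the density maps.
#'
#' @param k_on OFF to ON rate per frame (at unit activation; >= 0).
#' @param k_off_coeff ON to OFF rate per frame per unit relative excitation
#'   intensity (>= 0).
#' @param k_bleach_coeff ON to BLEACHED rate per frame per unit relative
#'   excitation intensity (>= 0).
#' @param photon_coeff Mean detected photons per frame per unit relative
#'   excitation intensity (>= 0).
#' @param activation_multiplier Optional scaling of `k_on` (uniform 1 by
#'   default; a separate activation-light profile is not modelled).
#' @return An object of class `"photophysics_params"`.
#' @export
photophysics_params <- function(k_on = 0.001, k_off_coeff = 1.0,
                                k_bleach_coeff = 0.1, photon_coeff = 1000,
                                activation_multiplier = 1) {
  vals <- c(k_on = k_on, k_off_coeff = k_off_coeff,
            k_bleach_coeff = k_bleach_coeff, photon_coeff = photon_coeff,
            activation_multiplier = activation_multiplier)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("photophysics rates must be finite and >= 0", call. = FALSE)
  structure(as.list(vals), class = "photophysics_params")
}

#' Acquisition parameters for the blinking simulator
#'
#' Camera and detection settings of a simulated dSTORM acquisition.  The
#' defaults mirror a typical large-field EMCCD acquisition: 12000 frames over
#' a 60.4 um x 60.4 um field with 118 nm camera pixels.
#'
#' @param n_frames Number of camera frames (>= 1; default 12000).
#' @param fov_size Field of view in nm (default 60400).
#' @param pixel_size Camera pixel size on the sample in nm (default 118).
#' @param detect_photon_min Minimum photons for a successful localization
#'   (default 50).
#' @param reject_radius Minimum allowed distance in nm between simultaneously
#'   ON emitters; closer pairs are mutually rejected as overlapping PSFs
#'   (default 500).
#' @param psf_sigma PSF standard deviation in nm; localization noise is
#'   isotropic Gaussian with sd `psf_sigma / sqrt(photons)` (default 130).
#' @return An object of class `"acquisition_params"`.
#' @export
acquisition_params <- function(n_frames = 12000L, fov_size = 60400,
                               pixel_size = 118, detect_photon_min = 50,
                               reject_radius = 500, psf_sigma = 130) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("`n_frames` must be an integer >= 1", call. = FALSE)
  if (!is.finite(fov_size) || fov_size <= 0)
    stop("`fov_size` must be > 0", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0", call. = FALSE)
  if (!is.finite(reject_radius) || reject_radius < 0)
    stop("`reject_radius` must be >= 0", call. = FALSE)
  if (!is.finite(detect_photon_min) || detect_photon_min < 0)
    stop("`detect_photon_min` must be >= 0", call. = FALSE)
  if (!is.finite(psf_sigma) || psf_sigma <= 0)
    stop("`psf_sigma` must be > 0", call. = FALSE)
  structure(list(n_frames = n_frames, fov_size = fov_size,
                 pixel_size = pixel_size,
                 detect_photon_min = detect_photon_min,
                 reject_radius = reject_radius, psf_sigma = psf_sigma),
            class = "acquisition_params")
}

#' Emitter ensemble (simulation ground truth)
#'
#' Fixed emitter positions plus their current photophysical states.  Allowed
#' state transitions are OFF <-> ON and ON -> BLEACHED; BLEACHED is absorbing.
#'
#' @param positions n x 2 numeric matrix of emitter positions in nm
#'   (origin at the top-left FOV corner, x rightward, y downward).
#' @param fov_size Field of view in nm; all positions must lie within
#'   `[0, fov_size]` on both axes.
#' @param states Optional integer state vector (0 = OFF, 1 = ON,
#'   2 = BLEACHED); defaults to all OFF.
#' @return An object of class `"emitter_ensemble"`.
#' @export
emitter_ensemble <- function(positions, fov_size, states = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) > 0 && ncol(positions) != 2L)
    stop("`positions` must be an n x 2 matrix", call. = FALSE)
  if (nrow(positions) == 0) positions <- matrix(numeric(), 0, 2)
  if (!is.finite(fov_size) || fov_size <= 0)
    stop("`fov_size` must be > 0", call. = FALSE)
  if (any(!is.finite(positions)))
    stop("positions must be finite", call. = FALSE)
  if (any(positions < 0) || any(positions > fov_size))
    stop("positions must lie within [0, fov_size]", call. = FALSE)
  if (is.null(states)) states <- rep(STATE_OFF, nrow(positions))
  states <- as.integer(states)
  if (length(states) != nrow(positions) ||
      any(!states %in% c(STATE_OFF, STATE_ON, STATE_BLEACHED)))
    stop("`states` must be one of 0 (OFF), 1 (ON), 2 (BLEACHED) per emitter",
         call. = FALSE)
  structure(list(positions = positions, states = states,
                 fov_size = fov_size),
            class = "emitter_ensemble")
}

#' @export
print.emitter_ensemble <- function(x, ...) {
  cat(sprintf(
    "<emitter_ensemble: %d emitters in %g nm FOV (%d OFF, %d ON, %d bleached)>\n",
    nrow(x$positions), x$fov_size, sum(x$states == STATE_OFF),
    sum(x$states == STATE_ON), sum(x$states == STATE_BLEACHED)))
  invisible(x)
}

#' Generate filament-like ground truth
#'
#' Places emitters along randomly oriented, gently curved segments (circular
#' arcs) clipped to the field of view, emulating immunostained microtubules.
#' Emitters are spaced uniformly along each filament with isotropic Gaussian
#' jitter, mimicking antibody-label positions around the filament backbone.
#'
#' @param n_filaments Number of filaments (>= 0).
#' @param emitters_per_filament Emitters per filament (>= 0).
#' @param fov_size Field of view in nm.
#' @param seed Integer seed; the same seed always yields the same ensemble.
#' @param jitter_sd Isotropic label jitter sd in nm (default 20).
#' @param length_range Filament length range in nm, drawn uniformly
#'   (default `c(0.3, 0.9) * fov_size`).
#' @param max_curvature Maximum bend, as total direction change in radians
#'   over a filament (default 1).
#' @return An [emitter_ensemble()] with all emitters OFF.
#' @export
generate_filament_ground_truth <- function(n_filaments,
                                           emitters_per_filament,
                                           fov_size = 60400, seed,
                                           jitter_sd = 20,
                                           length_range = NULL,
                                           max_curvature = 1) {
  if (n_filaments < 0 || emitters_per_filament < 0)
    stop("counts must be >= 0", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(length_range)) length_range <- c(0.3, 0.9) * fov_size
  stream <- .new_stream(.derive_seed(seed, "ground_truth"))
  pos <- .with_stream(stream, {
    out <- vector("list", n_filaments)
    for (i in seq_len(n_filaments)) {
      n <- emitters_per_filament
      if (n == 0) { out[[i]] <- matrix(numeric(), 0, 2); next }
      start <- stats::runif(2, 0.05, 0.95) * fov_size
      theta0 <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, length_range[1], length_range[2])
      bend <- stats::runif(1, -max_curvature, max_curvature)
      s <- seq(0, len, length.out = max(n, 2L))[seq_len(n)]
      theta <- theta0 + bend * s / len
      x <- start[1] + cumsum(c(0, diff(s)) * cos(theta))
      y <- start[2] + cumsum(c(0, diff(s)) * sin(theta))
      x <- x + stats::rnorm(n, 0, jitter_sd)
      y <- y + stats::rnorm(n, 0, jitter_sd)
      # clip a small margin inside the FOV so localization noise rarely
      # pushes records outside the field
      margin <- min(0.002 * fov_size, fov_size / 2)
      out[[i]] <- cbind(pmin(pmax(x, margin), fov_size - margin),
                        pmin(pmax(y, margin), fov_size - margin))
    }
    do.call(rbind, c(out, list(matrix(numeric(), 0, 2))))
  })
  emitter_ensemble(pos, fov_size = fov_size)
}

#' Advance emitter states by one frame
#'
#' Vectorized one-frame Markov transition.  From OFF, an emitter switches ON
#' with probability \eqn{1-\exp(-k_{on})}.  From ON, it first bleaches with
#' probability \eqn{1-\exp(-k_{bleach} I)}; surviving that, it switches OFF
#' with probability \eqn{1-\exp(-k_{off} I)}, where \eqn{I} is the local
#' relative excitation intensity.  BLEACHED is absorbing.
#'
#' @param states Integer vector of current states (0 = OFF, 1 = ON,
#'   2 = BLEACHED).
#' @param local_excitation Relative excitation intensity per emitter
#'   (recycled; >= 0).
#' @param params A [photophysics_params()].
#' @return Integer vector of new states.
#' @export
frame_transition <- function(states, local_excitation, params) {
  stopifnot(inherits(params, "photophysics_params"))
  if (any(local_excitation < 0) || any(!is.finite(local_excitation)))
    stop("`local_excitation` must be finite and >= 0", call. = FALSE)
  n <- length(states)
  I <- rep_len(local_excitation, n)
  new <- states
  p_on <- 1 - exp(-params$k_on * params$activation_multiplier)
  off <- which(states == STATE_OFF)
  if (length(off))
    new[off[stats::runif(length(off)) < p_on]] <- STATE_ON
  on <- which(states == STATE_ON)
  if (length(on)) {
    p_bleach <- 1 - exp(-params$k_bleach_coeff * I[on])
    bleached <- stats::runif(length(on)) < p_bleach
    new[on[bleached]] <- STATE_BLEACHED
    surv <- on[!bleached]
    if (length(surv)) {
      p_off <- 1 - exp(-params$k_off_coeff * I[surv])
      new[surv[stats::runif(length(surv)) < p_off]] <- STATE_OFF
    }
  }
  new
}

#' Simulate a dSTORM acquisition
#'
#' Runs the per-frame blinking Markov chain for every emitter under the given
#' illumination profile and emits a localization table.  Per frame, each
#' emitter's state is advanced with [frame_transition()] using the
#' illumination intensity at its (fixed) position; each ON emitter draws
#' photons from Poisson(`photon_coeff` x intensity); a localization record is
#' emitted iff the photon count reaches `detect_photon_min` and no other ON
#' emitter lies within `reject_radius` (overlapping PSFs are mutually
#' rejected).  Localized positions are the true positions plus isotropic
#' Gaussian noise with sd `psf_sigma / sqrt(photons)`.
#'
#' Illumination is expressed in relative units: the flat-field (top-hat)
#' level over the FOV defines intensity 1, and beams are specified in nm FOV
#' coordinates (e.g. a Gaussian centered at `fov_size/2` with `sigma` a
#' fraction of `fov_size`).
#'
#' @param ensemble An [emitter_ensemble()]; its states are the initial
#'   states, so a partially bleached ensemble can be re-imaged.
#' @param illumination A [gaussian_beam()] or [tophat_beam()] in nm FOV
#'   coordinates, intensity relative to the top-hat level.
#' @param photophysics A [photophysics_params()].
#' @param acquisition An [acquisition_params()].
#' @param seed Integer root seed; expands into independent streams for
#'   kinetics, photon counts, and localization noise.
#' @param keep_states Also return the full per-frame state matrix
#'   (`n_frames` x n; memory-heavy, meant for validation at small sizes).
#' @return A list of class `"smlm_acquisition"`:
#'   * `table`: the [localization_table()] (with `photons`, `uncertainty`,
#'     and metadata);
#'   * `truth`: a list with `state_counts` (`n_frames` x 3 matrix of
#'     OFF/ON/BLEACHED counts after each frame's transition), `bleach_frame`
#'     (0-based frame at which each emitter bleached, `NA` if never),
#'     `record_emitter` (emitter index of each record), and optionally
#'     `states`;
#'   * `final_states`: emitter states after the last frame;
#'   * `ensemble`, `seed`: the inputs, for provenance.
#' @export
simulate_acquisition <- function(ensemble, illumination, photophysics,
                                 acquisition, seed, keep_states = FALSE) {
  stopifnot(inherits(ensemble, "emitter_ensemble"),
            inherits(photophysics, "photophysics_params"),
            inherits(acquisition, "acquisition_params"))
  if (!(inherits(illumination, "gaussian_beam") ||
        inherits(illumination, "tophat_beam")))
    stop("`illumination` must be a gaussian_beam or tophat_beam",
         call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  n <- nrow(ensemble$positions)
  nf <- acquisition$n_frames
  pos <- ensemble$positions
  I <- if (n) beam_intensity(illumination, pos[, 1], pos[, 2]) else numeric()
  if (any(I < 0)) stop("illumination intensity must be >= 0", call. = FALSE)

  s_kin <- .new_stream(.derive_seed(seed, "kinetics"))
  s_pho <- .new_stream(.derive_seed(seed, "photons"))
  s_noi <- .new_stream(.derive_seed(seed, "noise"))

  states <- ensemble$states
  state_counts <- matrix(0L, nf, 3L,
                         dimnames = list(NULL, c("off", "on", "bleached")))
  bleach_frame <- rep(NA_integer_, n)
  states_log <- if (keep_states) matrix(NA_integer_, nf, n) else NULL

  rec_frame <- vector("list", nf); rec_x <- vector("list", nf)
  rec_y <- vector("list", nf); rec_ph <- vector("list", nf)
  rec_un <- vector("list", nf); rec_em <- vector("list", nf)

  lam <- photophysics$photon_coeff * I

  for (f in seq_len(nf)) {
    prev <- states
    states <- .with_stream(s_kin,
                           frame_transition(states, I, photophysics))
    newly_bleached <- which(prev != STATE_BLEACHED &
                              states == STATE_BLEACHED)
    bleach_frame[newly_bleached] <- f - 1L
    state_counts[f, ] <- c(sum(states == STATE_OFF),
                           sum(states == STATE_ON),
                           sum(states == STATE_BLEACHED))
    if (keep_states) states_log[f, ] <- states

    on <- which(states == STATE_ON)
    if (length(on)) {
      photons <- .with_stream(s_pho, stats::rpois(length(on), lam[on]))
      ok <- photons >= acquisition$detect_photon_min & photons > 0
      if (acquisition$reject_radius > 0 && length(on) > 1L) {
        d <- as.matrix(stats::dist(pos[on, , drop = FALSE]))
        diag(d) <- Inf
        crowded <- apply(d <= acquisition$reject_radius, 1L, any)
        ok <- ok & !crowded
      }
      if (any(ok)) {
        idx <- on[ok]
        ph <- photons[ok]
        sd_loc <- acquisition$psf_sigma / sqrt(ph)
        noise <- .with_stream(s_noi,
                              stats::rnorm(2L * length(idx)))
        rec_frame[[f]] <- rep.int(f - 1L, length(idx))
        rec_x[[f]] <- pos[idx, 1] + noise[seq_along(idx)] * sd_loc
        rec_y[[f]] <- pos[idx, 2] +
          noise[length(idx) + seq_along(idx)] * sd_loc
        rec_ph[[f]] <- as.numeric(ph)
        rec_un[[f]] <- sd_loc
        rec_em[[f]] <- idx
      }
    }
  }

  table <- localization_table(
    frame = unlist(rec_frame), x = unlist(rec_x), y = unlist(rec_y),
    photons = unlist(rec_ph), uncertainty = unlist(rec_un),
    fov_size = ensemble$fov_size, pixel_size = acquisition$pixel_size,
    dialect = "simulated")
  truth <- list(state_counts = state_counts, bleach_frame = bleach_frame,
                record_emitter = unlist(rec_em))
  if (keep_states) truth$states <- states_log
  structure(list(table = table, truth = truth, final_states = states,
                 ensemble = ensemble, seed = seed),
            class = "smlm_acquisition")
}

#' Simulate two sequential acquisitions of the same sample
#'
#' Runs two full acquisitions back to back on the same emitter ensemble,
#' carrying bleached emitters from the first run into the second (surviving
#' emitters restart OFF).  This mirrors the paired imaging protocol in which
#' each sample is imaged under both illumination profiles in turn, with the
#' order reversed across samples to separate illumination bias from
#' photobleaching carry-over.
#'
#' @param ensemble An [emitter_ensemble()].
#' @param illumination_first,illumination_second Beam specs for the two runs.
#' @param photophysics A [photophysics_params()].
#' @param acquisition An [acquisition_params()] (used for both runs).
#' @param seed Integer root seed; the two runs use independent derived
#'   streams.
#' @return A list with elements `first` and `second`, each an
#'   `"smlm_acquisition"` as returned by [simulate_acquisition()].
#' @export
simulate_sequential_pair <- function(ensemble, illumination_first,
                                     illumination_second, photophysics,
                                     acquisition, seed) {
  first <- simulate_acquisition(ensemble, illumination_first, photophysics,
                                acquisition, seed)
  carried <- ifelse(first$final_states == STATE_BLEACHED, STATE_BLEACHED,
                    STATE_OFF)
  ensemble2 <- emitter_ensemble(ensemble$positions, ensemble$fov_size,
                                states = carried)
  second <- simulate_acquisition(ensemble2, illumination_second,
                                 photophysics, acquisition,
                                 .derive_seed(seed, "pair_second"))
  list(first = first, second = second)
}

#' Expected localization count for an isolated emitter
#'
#' Closed-form expectation used as an analytic oracle: for a single emitter
#' with no bleaching under constant relative intensity \eqn{I}, the expected
#' number of localization records is `n_frames` times the stationary ON
#' probability \eqn{p_{on}/(p_{on}+p_{off})} of the two-state chain times the
#' detection probability \eqn{P(\mathrm{Poisson}(\lambda) \ge
#' \max(\mathrm{detect\_photon\_min}, 1))} with \eqn{\lambda =
#' \mathrm{photon\_coeff} \cdot I} (a record always needs at least one
#' photon).  Overlap rejection does not apply to an isolated emitter.
#'
#' @param photophysics A [photophysics_params()] (its `k_bleach_coeff` is
#'   ignored: the formula assumes no bleaching).
#' @param acquisition An [acquisition_params()].
#' @param intensity Relative excitation intensity (>= 0).
#' @return Expected record count (numeric scalar).
#' @export
expected_localizations_isolated <- function(photophysics, acquisition,
                                            intensity) {
  stopifnot(inherits(photophysics, "photophysics_params"),
            inherits(acquisition, "acquisition_params"))
  if (intensity < 0) stop("`intensity` must be >= 0", call. = FALSE)
  p_on <- 1 - exp(-photophysics$k_on * photophysics$activation_multiplier)
  p_off <- 1 - exp(-photophysics$k_off_coeff * intensity)
  if (p_on + p_off == 0) return(0)
  stationary_on <- p_on / (p_on + p_off)
  lam <- photophysics$photon_coeff * intensity
  # a record needs at least one photon even when the threshold is zero
  m <- max(acquisition$detect_photon_min, 1)
  p_detect <- stats::ppois(m - 1, lam, lower.tail = FALSE)
  acquisition$n_frames * stationary_on * p_detect
}
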