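test_that("filament ground truth respects counts, bounds and determinism", {
  empty <- generate_filament_ground_truth(0, 100, seed = 1)
  expect_identical(nrow(empty$positions), 0L)

  ens <- generate_filament_ground_truth(1, 100, fov_size = 60400, seed = 42)
  expect_identical(nrow(ens$positions), 100L)
  expect_true(all(ens$positions >= 0 & ens$positions <= 60400))
  expect_true(all(ens$states == 0L))

  again <- generate_filament_ground_truth(1, 100, fov_size = 60400, seed = 42)
  expect_identical(ens$positions, again$positions)
  other <- generate_filament_ground_truth(1, 100, fov_size = 60400, seed = 43)
  expect_false(identical(ens$positions, other$positions))

  expect_error(generate_filament_ground_truth(-1, 10, seed = 1), ">= 0")
})

test_that("emitters look filament-like, not uniformly scattered", {
  ens <- generate_filament_ground_truth(5, 200, fov_size = 60400, seed = 3)
  # mean nearest-neighbour distance along filaments is far below the
  # uniform-scatter expectation 0.5 / sqrt(density)
  d <- as.matrix(stats::dist(ens$positions))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  uniform_nn <- 0.5 / sqrt(nrow(ens$positions) / 60400^2)
  expect_lt(mean(nn), 0.25 * uniform_nn)
})

test_that("frame transitions honour the kinetic model", {
  pp <- photophysics_params(k_on = log(2), k_off_coeff = 1,
                            k_bleach_coeff = 0.1)
  # BLEACHED is absorbing at any intensity
  expect_true(all(frame_transition(rep(2L, 500), 10, pp) == 2L))
  # zero intensity: an ON emitter neither bleaches nor switches off
  expect_true(all(frame_transition(rep(1L, 500), 0, pp) == 1L))
  expect_error(frame_transition(rep(0L, 3), -1, pp), "excitation")

  # OFF -> ON with probability 1 - exp(-ln 2) = 1/2, checked by Monte Carlo
  # against a 3-sigma binomial envelope
  set.seed(99)
  n <- 1e5
  frac_on <- mean(frame_transition(rep(0L, n), 1, pp) == 1L)
  expect_lt(abs(frac_on - 0.5), 3 * sqrt(0.25 / n))
})

test_that("no photons means no localizations", {
  ens <- generate_filament_ground_truth(2, 50, fov_size = 60400, seed = 5)
  beams <- fov_beams()
  res <- simulate_acquisition(
    ens, beams$tophat,
    photophysics_params(k_on = 0.05, photon_coeff = 0),
    acquisition_params(n_frames = 200), seed = 7)
  expect_identical(nrow(res$table), 0L)
})

test_that("overlapping ON emitters are mutually rejected", {
  fov <- 60400
  pos <- rbind(c(30000, 30000), c(30100, 30000))  # 100 nm apart
  ens <- emitter_ensemble(pos, fov)
  # force both ON every frame: huge switch-on rate, no switch-off/bleach
  pp <- photophysics_params(k_on = 50, k_off_coeff = 0, k_bleach_coeff = 0,
                            photon_coeff = 1000)
  beams <- fov_beams()
  res <- simulate_acquisition(ens, beams$tophat, pp,
                              acquisition_params(n_frames = 100,
                                                 reject_radius = 500),
                              seed = 1)
  expect_identical(nrow(res$table), 0L)

  # with overlap rejection disabled the same emitters are localized
  res2 <- simulate_acquisition(ens, beams$tophat, pp,
                               acquisition_params(n_frames = 100,
                                                  reject_radius = 0),
                               seed = 1)
  expect_gt(nrow(res2$table), 150)
})

test_that("record count of an isolated emitter matches the analytic oracle", {
  # two-state chain with p_on = 0.1, p_off = 0.9 and certain detection
  pp <- photophysics_params(k_on = -log(1 - 0.1), k_off_coeff = -log(1 - 0.9),
                            k_bleach_coeff = 0, photon_coeff = 1000)
  acq <- acquisition_params(n_frames = 1000, detect_photon_min = 50,
                            reject_radius = 0)
  expected <- expected_localizations_isolated(pp, acq, intensity = 1)
  expect_equal(expected, 1000 * 0.1 / (0.1 + 0.9) *
                 stats::ppois(49, 1000, lower.tail = FALSE),
               tolerance = 1e-12)

  ens <- emitter_ensemble(matrix(c(30200, 30200), 1), 60400)
  beams <- fov_beams()
  counts <- vapply(1:20, function(s)
    nrow(simulate_acquisition(ens, beams$tophat, pp, acq, seed = s)$table),
    numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("expected_localizations_isolated handles edge cases", {
  pp <- photophysics_params(k_on = 0.1, k_off_coeff = 1)
  acq <- acquisition_params(n_frames = 500, detect_photon_min = 0)
  expect_identical(expected_localizations_isolated(pp, acq, 0), 0)
  # with a zero photon threshold only the >= 1 photon requirement remains
  p_on <- 1 - exp(-0.1); p_off <- 1 - exp(-1)
  expect_equal(expected_localizations_isolated(pp, acq, 1),
               500 * p_on / (p_on + p_off) * (1 - exp(-1000)),
               tolerance = 1e-12)
})

test_that("state bookkeeping is conserved and bleached emitters are silent", {
  ens <- generate_filament_ground_truth(3, 60, fov_size = 60400, seed = 11)
  beams <- fov_beams()
  pp <- photophysics_params(k_on = 0.02, k_off_coeff = 1,
                            k_bleach_coeff = 0.3)
  res <- simulate_acquisition(ens, beams$gaussian, pp,
                              acquisition_params(n_frames = 400),
                              seed = 13, keep_states = TRUE)
  n <- nrow(ens$positions)
  expect_true(all(rowSums(res$truth$state_counts) == n))
  expect_gt(sum(res$final_states == 2L), 0)  # bleaching happened

  # every record was emitted by an emitter that was ON in that frame
  st <- res$truth$states
  rec_states <- st[cbind(res$table$frame + 1L, res$truth$record_emitter)]
  expect_true(all(rec_states == 1L))

  # and never at or after its recorded bleaching frame
  bf <- res$truth$bleach_frame[res$truth$record_emitter]
  expect_true(all(is.na(bf) | res$table$frame < bf))
})

test_that("identical seeds give byte-identical tables; seeds differ otherwise", {
  ens <- generate_filament_ground_truth(2, 80, fov_size = 60400, seed = 2)
  beams <- fov_beams()
  pp <- photophysics_params(k_on = 0.02)
  acq <- acquisition_params(n_frames = 300)
  a <- simulate_acquisition(ens, beams$gaussian, pp, acq, seed = 5)
  b <- simulate_acquisition(ens, beams$gaussian, pp, acq, seed = 5)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$state_counts, b$truth$state_counts)
  c_ <- simulate_acquisition(ens, beams$gaussian, pp, acq, seed = 6)
  expect_false(identical(a$table, c_$table))
})

test_that("raising the bleach rate never increases the record count", {
  ens <- generate_filament_ground_truth(2, 100, fov_size = 60400, seed = 21)
  beams <- fov_beams()
  acq <- acquisition_params(n_frames = 400)
  mean_count <- function(kb) {
    pp <- photophysics_params(k_on = 0.02, k_off_coeff = 1,
                              k_bleach_coeff = kb)
    mean(vapply(1:20, function(s)
      nrow(simulate_acquisition(ens, beams$tophat, pp, acq,
                                seed = 100 + s)$table), numeric(1)))
  }
  counts <- vapply(c(0, 0.1, 0.5), mean_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sequential pairs carry bleaching and preserve exchangeability", {
  ens <- generate_filament_ground_truth(3, 80, fov_size = 60400, seed = 31)
  beams <- fov_beams()

  # a fully bleached ensemble yields an empty second table
  pp_hot <- photophysics_params(k_on = 5, k_off_coeff = 0,
                                k_bleach_coeff = 5)
  acq <- acquisition_params(n_frames = 300)
  pair <- simulate_sequential_pair(ens, beams$tophat, beams$tophat,
                                   pp_hot, acq, seed = 41)
  expect_true(all(pair$first$final_states == 2L))
  expect_identical(nrow(pair$second$table), 0L)

  # no bleaching, identical illumination: the two runs are exchangeable, so
  # a chi-square homogeneity test across coarse bins must not reject
  pp0 <- photophysics_params(k_on = 0.05, k_off_coeff = 1,
                             k_bleach_coeff = 0)
  pair0 <- simulate_sequential_pair(ens, beams$tophat, beams$tophat,
                                    pp0, acq, seed = 43)
  m1 <- density_map(pair0$first$table, 60400, grid_n = 8)
  m2 <- density_map(pair0$second$table, 60400, grid_n = 8)
  tot <- as.vector(m1$counts) + as.vector(m2$counts)
  keep <- tot >= 10
  pval <- stats::chisq.test(cbind(as.vector(m1$counts)[keep],
                                  as.vector(m2$counts)[keep]))$p.value
  expect_gt(pval, 0.001)

  # top-hat first, then Gaussian, with bleaching: the Gaussian/top-hat
  # ratio map sits below unity
  pp_b <- photophysics_params(k_on = 0.02, k_off_coeff = 1,
                              k_bleach_coeff = 0.2)
  pair_b <- simulate_sequential_pair(ens, beams$tophat, beams$gaussian,
                                     pp_b, acquisition_params(n_frames = 800),
                                     seed = 47)
  mt <- density_map(pair_b$first$table, 60400, grid_n = 16)
  mg <- density_map(pair_b$second$table, 60400, grid_n = 16)
  rm_ <- ratio_map(mg, mt)
  expect_lt(stats::median(rm_$values, na.rm = TRUE), 1)
})
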