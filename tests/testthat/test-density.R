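test_that("persistence filter implements the previous-frame rule", {
  expect_identical(nrow(persistence_filter(
    localization_table(integer(), numeric(), numeric()))), 0L)

  # identical position in consecutive frames: the later record is removed
  t <- localization_table(frame = c(1, 2), x = c(500, 500), y = c(500, 500))
  expect_identical(persistence_filter(t, 100)$frame, 1L)

  # a chain across frames 1,2,3 keeps only the first record, because both
  # later records have a raw predecessor within the radius
  chain <- localization_table(frame = 1:3, x = rep(500, 3), y = rep(500, 3))
  expect_identical(persistence_filter(chain, 100)$frame, 1L)
  expect_identical(nrow(persistence_oracle(chain, 100)), 1L)

  # same-frame proximity is not persistence
  same <- localization_table(frame = c(5, 5), x = c(0, 90), y = c(0, 0))
  expect_identical(nrow(persistence_filter(same, 100)), 2L)

  # the distance test is inclusive at exactly the radius
  edge <- localization_table(frame = c(0, 1), x = c(0, 100), y = c(0, 0))
  expect_identical(nrow(persistence_filter(edge, 100)), 1L)
  expect_identical(nrow(persistence_filter(edge, 99.999)), 2L)

  expect_error(persistence_filter(t, -1), "radius")
})

test_that("persistence filter equals the brute-force oracle and is idempotent", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(50:2000, 1)
    t <- random_loc_table(n, n_frames = sample(c(5L, 20L, 60L), 1),
                          fov = 5000)
    f <- persistence_filter(t, 300)
    o <- persistence_oracle(t, 300)
    expect_identical(f$frame, o$frame)
    expect_identical(f$x, o$x)
    # contraction and idempotence (removals depend only on the raw table)
    expect_lte(nrow(f), nrow(t))
    ff <- persistence_filter(f, 300)
    expect_identical(ff$x, f$x)
  }
})

test_that("density map bins with half-open intervals and a closed far edge", {
  # four quadrant centers on a 2x2 grid
  t <- localization_table(frame = rep(0L, 4), x = c(25, 75, 25, 75),
                          y = c(25, 25, 75, 75))
  m <- density_map(t, fov_size = 100, grid_n = 2)
  expect_identical(m$counts, matrix(1L, 2, 2))

  # a record exactly on the far corner lands in the last bin
  corner <- localization_table(0, 100, 100)
  mc <- density_map(corner, 100, 2)
  expect_identical(mc$counts[2, 2], 1L)
  expect_identical(sum(mc$counts), 1L)

  # out-of-FOV records are excluded and tallied
  out <- localization_table(frame = c(0, 0), x = c(50, 101), y = c(50, 50))
  mo <- density_map(out, 100, 2)
  expect_identical(sum(mo$counts), 1L)
  expect_identical(mo$n_excluded, 1L)

  expect_error(density_map(t, 100, grid_n = 0), "grid_n")
  expect_error(density_map(localization_table(0, 1, 1)), "fov_size")
})

test_that("density map places x along columns and y along rows", {
  t <- localization_table(0, x = 90, y = 10)  # right edge, top row
  m <- density_map(t, 100, 2)
  expect_identical(m$counts[1, 2], 1L)
})

test_that("density map conserves counts for every grid size", {
  set.seed(29)
  t <- random_loc_table(5000, fov = 60400)
  for (g in c(1L, 2L, 64L, 101L))
    expect_identical(sum(density_map(t, 60400, g)$counts), 5000L)
})

test_that("uniform records pass a goodness-of-fit test against uniformity", {
  set.seed(31)
  t <- random_loc_table(10000, fov = 60400)
  m <- density_map(t, 60400, grid_n = 8)
  pval <- stats::chisq.test(as.vector(m$counts))$p.value
  expect_gt(pval, 0.001)
})

test_that("density map is equivariant under joint translation", {
  set.seed(37)
  t <- random_loc_table(1000, fov = 10000)
  shift <- c(12345, -678)
  t2 <- localization_table(t$frame, t$x + shift[1], t$y + shift[2])
  m1 <- density_map(t, 10000, 16)
  m2 <- density_map(t2, 10000, 16, origin = shift)
  expect_identical(m1$counts, m2$counts)
})

test_that("ratio maps mark zero-denominator cells undefined", {
  set.seed(41)
  t <- random_loc_table(3000, fov = 1000)
  m <- density_map(t, 1000, 8)
  self <- ratio_map(m, m)
  expect_true(all(self$values[!is.na(self$values)] == 1))
  expect_identical(is.na(self$values), m$counts == 0L)

  num <- density_map(localization_table(0, 500, 500), 1000, 2)
  den <- density_map(localization_table(integer(), numeric(), numeric()),
                     1000, 2)
  r <- ratio_map(num, den)
  expect_true(all(is.na(r$values)))

  zero_num <- ratio_map(den0 <- density_map(
    localization_table(integer(), numeric(), numeric()), 1000, 2), num)
  vals <- zero_num$values[num$counts > 0]
  expect_true(all(vals == 0))

  other <- density_map(localization_table(0, 1, 1), 1000, 4)
  expect_error(ratio_map(num, other), "share")
})

test_that("bias statistic recovers constructed region ratios", {
  fov <- 1000
  g <- 16L
  beam <- gaussian_beam(amplitude = 3, sigma = 0.5 * fov,
                        center = c(fov / 2, fov / 2))
  flat_counts <- matrix(100L, g, g)
  flat <- structure(list(counts = flat_counts, fov_size = fov, grid_n = g,
                         origin = c(0, 0), n_excluded = 0L),
                    class = "density_map")
  # identical maps: factor exactly 1
  b0 <- illumination_bias_statistic(flat, flat, beam)
  expect_identical(b0$undercount_factor, 1)

  # construct a numerator whose high-intensity cells hold half the ratio of
  # the low-intensity cells; the factor must be exactly 2
  cen <- (seq_len(g) - 0.5) / g * fov
  intens <- outer(cen, cen, function(y, x) beam_intensity(beam, x, y))
  hi <- intens >= stats::quantile(intens, 0.8)
  num_counts <- matrix(80L, g, g)
  num_counts[hi] <- 40L
  num <- structure(list(counts = num_counts, fov_size = fov, grid_n = g,
                        origin = c(0, 0), n_excluded = 0L),
                   class = "density_map")
  b2 <- illumination_bias_statistic(num, flat, beam)
  expect_equal(b2$undercount_factor, 2)
  expect_equal(b2$high_median, 0.4)
  expect_equal(b2$low_median, 0.8)

  # the high-intensity region contains the FOV center, not the corners
  expect_true(b2$high_region[g / 2, g / 2])
  expect_false(b2$high_region[1, 1])
  expect_true(b2$low_region[1, 1])

  # empty regions raise an explicit error rather than returning NaN
  sparse <- structure(list(counts = matrix(0L, g, g), fov_size = fov,
                           grid_n = g, origin = c(0, 0), n_excluded = 0L),
                      class = "density_map")
  expect_error(illumination_bias_statistic(num, sparse, beam),
               "insufficient data")
  expect_error(illumination_bias_statistic(num, flat, beam,
                                           high_quantile = 0.2,
                                           low_quantile = 0.8),
               "quantile")
})

test_that("maps serialize to delimited text", {
  t <- localization_table(frame = rep(0L, 4), x = c(25, 75, 25, 75),
                          y = c(25, 25, 75, 75))
  m <- density_map(t, 100, 2)
  path <- tempfile(fileext = ".tsv")
  write_map_txt(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# density_map 2 x 2")
  re <- as.matrix(utils::read.table(path, skip = 1, sep = "\t"))
  expect_identical(unname(re), matrix(c(1L, 1L, 1L, 1L), 2, 2))
})
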