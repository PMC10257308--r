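test_that("satellite filter keeps fixes with at least min_sat satellites", {
  f <- fix_series(1:3, rep(-36, 3), rep(137, 3), nsat = c(4, 5, 6))
  kept <- filter_satellites(f, 5)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$nsat, c(5, 6))
  expect_equal(nrow(filter_satellites(fix_series(1:3, rep(-36, 3),
                                                 rep(137, 3), rep(4, 3)))), 0)
  empty <- fix_series(numeric(), numeric(), numeric(), numeric())
  expect_equal(nrow(filter_satellites(empty)), 0)
})

test_that("speed filter drops fixes implying speeds over the threshold", {
  lat0 <- -36
  # second fix 400 m north after 60 s: 6.67 m/s by the haversine oracle
  f <- fix_series(c(0, 60), c(lat0, lat0 + 400 / M_DEG), c(137, 137), c(8, 8))
  v <- haversine_oracle(137, lat0, 137, lat0 + 400 / M_DEG) / 60
  expect_gt(v, 6)
  expect_equal(nrow(speed_filter(f, 6)), 1)
  # 300 m in 60 s = 5 m/s: both kept
  f2 <- fix_series(c(0, 60), c(lat0, lat0 + 300 / M_DEG), c(137, 137), c(8, 8))
  expect_equal(nrow(speed_filter(f2, 6)), 2)
  one <- fix_series(0, lat0, 137, 8)
  expect_equal(speed_filter(one, 6), one)
})

test_that("speed filter is idempotent and bounds every retained pair", {
  set.seed(11)
  n <- 120
  t <- cumsum(sample(30:120, n, replace = TRUE))
  lat <- -36 + cumsum(rnorm(n, 0, 300)) / M_DEG
  lon <- 137 + cumsum(rnorm(n, 0, 300)) / M_DEG
  f <- fix_series(t, lat, lon, rep(8, n))
  g <- speed_filter(f, 6)
  expect_identical(speed_filter(g, 6), g)
  if (nrow(g) > 1) {
    v <- haversine_oracle(g$lon[-nrow(g)], g$lat[-nrow(g)],
                          g$lon[-1], g$lat[-1]) / diff(g$t)
    expect_true(all(v <= 6 + 1e-9))
  }
})

test_that("zero-offset correction recovers surface baselines", {
  base <- trapezoid_depth(depth = 40, plateau = 200, surface = 300)
  # constant transducer offset
  off <- depth_series(base$t, base$depth + 1.5)
  cor1 <- zero_offset_correct(off, window = 600, surface = 3)
  surf <- base$depth < 0.01
  expect_lt(abs(median(cor1$depth[surf])), 0.1)
  # already-zeroed record barely changes
  cor2 <- zero_offset_correct(base, window = 600, surface = 3)
  expect_lt(max(abs(cor2$depth - base$depth)), 0.05)
  # linear drift 0 -> 2 m across a 12 h record of repeated dives
  one <- trapezoid_depth(depth = 40, plateau = 200, surface = 300)
  reps <- ceiling(43200 / nrow(one))
  long <- depth_series(seq_len(reps * nrow(one)) - 1, rep(one$depth, reps))
  drift <- depth_series(long$t, long$depth +
                          seq(0, 2, length.out = nrow(long)))
  cor3 <- zero_offset_correct(drift, window = 3600, surface = 3)
  lsurf <- long$depth < 0.01
  expect_lt(abs(median(cor3$depth[lsurf])), 0.1)
  expect_true(all(abs(cor3$depth[lsurf]) < 0.35))
})

test_that("zero-offset correction preserves within-dive shape and warns when all-submerged", {
  base <- trapezoid_depth(depth = 40, plateau = 200, surface = 300)
  off <- depth_series(base$t, base$depth + 1.2)
  cor1 <- zero_offset_correct(off, window = 600, surface = 3)
  dive <- which(base$depth > 5)
  d0 <- diff(base$depth[dive])
  d1 <- diff(cor1$depth[dive])
  expect_lt(max(abs(d1 - d0)), 0.05)
  deep <- depth_series(1:100, rep(30, 100))
  expect_warning(out <- zero_offset_correct(deep), "surface")
  expect_equal(out$depth, deep$depth)
})

test_that("align_streams puts one row per depth second and conserves samples", {
  n <- 600
  acc <- accel_series(seq(0, n - 1 + 0.96, by = 0.04),
                      surge = rep(0.25, n * 25), sway = rep(0, n * 25),
                      heave = rep(1, n * 25))
  mag <- mag_series(seq(0, n - 1 + 0.5, by = 0.5),
                    mx = seq_len(2 * n), my = rep(0, 2 * n),
                    mz = rep(-50, 2 * n))
  dep <- depth_series(0:(n - 1), rep(10, n))
  b <- sensor_bundle(acc, mag, dep, fix_series(numeric(), numeric(),
                                               numeric(), numeric()))
  m <- align_streams(b)
  expect_equal(nrow(m), n)
  expect_equal(m$surge, rep(0.25, n))         # constant accel -> same mean
  # mag is linear in time, so interpolation reproduces the line
  expect_equal(m$mx[2:(n - 1)], seq(1, 2 * n, by = 2)[2:(n - 1)],
               tolerance = 1e-12)
  expect_true(all(m$complete))
})

test_that("reading a written synthetic trip round-trips and validates", {
  dir <- withr::local_tempdir()
  trip <- simulate_trip(trip_config(duration_h = 1, seed = 3))
  write_synthetic_trip(trip, dir)
  paths <- list(accel = file.path(dir, "accel.csv"),
                mag = file.path(dir, "mag.csv"),
                depth = file.path(dir, "depth.csv"),
                fixes = file.path(dir, "fixes.csv"))
  b <- suppressMessages(read_sensor_bundle(paths))
  expect_equal(nrow(b$depth), nrow(trip$bundle$depth))
  expect_equal(b$fixes$lat, trip$bundle$fixes$lat, tolerance = 1e-9)
  # missing column is a format error naming the stream
  bad <- read.csv(paths$depth)
  names(bad)[2] <- "pressure"
  write.csv(bad, paths$depth, row.names = FALSE)
  expect_error(suppressMessages(read_sensor_bundle(paths)), "depth")
})

test_that("disjoint stream time ranges are rejected", {
  acc <- accel_series(seq(0, 99.96, by = 0.04), rep(0, 2500), rep(0, 2500),
                      rep(1, 2500))
  mag <- mag_series(seq(500, 599.5, by = 0.5), rep(30, 200), rep(0, 200),
                    rep(-50, 200))
  dep <- depth_series(0:99, rep(0, 100))
  expect_error(sensor_bundle(acc, mag, dep,
                             fix_series(numeric(), numeric(), numeric(),
                                        numeric())),
               "common time range")
})

test_that("non-monotonic timestamps are rejected naming the offending row", {
  expect_error(depth_series(c(0, 1, 1, 2), rep(0, 4)), "row 3")
})
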