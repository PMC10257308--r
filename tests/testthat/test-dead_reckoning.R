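test_that("static/dynamic split is an exact decomposition", {
  t <- seq(0, 60, by = 0.04)
  const <- accel_series(t, rep(0.3, length(t)), rep(-0.2, length(t)),
                        rep(0.9, length(t)))
  parts <- split_static_dynamic(const, 3)
  expect_true(all(abs(unlist(parts$dynamic[, -1])) < 1e-12))
  set.seed(4)
  noisy <- accel_series(t, rnorm(length(t)), rnorm(length(t)),
                        rnorm(length(t)), range = 10)
  p2 <- split_static_dynamic(noisy, 3)
  expect_equal(p2$static$surge + p2$dynamic$surge, noisy$surge,
               tolerance = 1e-12)
  expect_equal(p2$static$heave + p2$dynamic$heave, noisy$heave,
               tolerance = 1e-12)
  expect_error(split_static_dynamic(accel_series(0:1 / 25, 0:1, 0:1, 0:1),
                                    3), "shorter")
})

test_that("running mean attenuates a 5 Hz ripple riding on 1 G", {
  t <- seq(0, 30, by = 0.04)
  x <- 1 + 0.5 * sin(2 * pi * 5 * t)
  s <- split_static_dynamic(accel_series(t, x, x * 0, x * 0 + 1), 3)$static
  interior <- t > 2 & t < 28
  expect_lt(max(abs(s$surge[interior] - 1)), 0.02)
})

test_that("attitude recovers pitch and roll from rotated gravity", {
  flat <- attitude_from_static(data.frame(t = 1, surge = 0, sway = 0,
                                          heave = 1))
  expect_equal(flat$pitch, 0)
  expect_equal(flat$roll, 0)
  nose_up <- attitude_from_static(data.frame(t = 1, surge = -1, sway = 0,
                                             heave = 0))
  expect_equal(nose_up$pitch, pi / 2)
  set.seed(7)
  pitch <- runif(200, -1.4, 1.4)
  roll <- runif(200, -2.8, 2.8)
  g <- t(vapply(seq_along(pitch), function(i)
    to_device_oracle(c(0, 0, 1), 0, pitch[i], roll[i]), numeric(3)))
  att <- attitude_from_static(data.frame(t = seq_along(pitch),
                                         surge = g[, 1], sway = g[, 2],
                                         heave = g[, 3]))
  expect_lt(max(abs(att$pitch - pitch)), 1e-9)
  expect_lt(max(abs(att$roll - roll)), 1e-9)
})

test_that("weak gravity samples are flagged and interpolated", {
  g <- data.frame(t = 1:5, surge = c(0, 0, 0.001, 0, 0),
                  sway = 0, heave = c(1, 1, 0.001, 1, 1))
  att <- attitude_from_static(g)
  expect_true(att$flagged[3])
  expect_lt(abs(att$pitch[3]), 1e-6)
})

test_that("tilt-compensated heading inverts the forward field model", {
  model <- list(declination = 7.698, inclination = -68.012)
  # level tag, field aligned with magnetic north, no declination
  lev <- tilt_compensated_heading(
    data.frame(t = 1, mx = 30, my = 0, mz = -55), 0, 0,
    list(declination = 0, inclination = -61))
  expect_equal(lev$heading, 0)
  # random attitude and true heading, field synthesised with the study
  # area's declination/inclination via an independent rotation oracle
  set.seed(9)
  n <- 400
  yaw_true <- runif(n, 0, 2 * pi)
  pitch <- runif(n, -75, 75) * pi / 180
  roll <- runif(n, -60, 60) * pi / 180
  D <- model$declination * pi / 180
  I <- model$inclination * pi / 180
  f_ned <- 60 * c(cos(I) * cos(D), cos(I) * sin(D), sin(I))
  m <- t(vapply(seq_len(n), function(i)
    to_device_oracle(f_ned, yaw_true[i], pitch[i], roll[i]), numeric(3)))
  h <- tilt_compensated_heading(data.frame(t = seq_len(n), mx = m[, 1],
                                           my = m[, 2], mz = m[, 3]),
                                pitch, roll, model)
  err <- abs(((h$heading - yaw_true + pi) %% (2 * pi)) - pi)
  expect_lt(max(err), 1e-6)
})

test_that("speed from depth rate and pitch follows the geometry", {
  expect_equal(estimate_speed(1, -45 * pi / 180, 1), sqrt(2),
               tolerance = 1e-9)
  expect_equal(estimate_speed(0.5, 0, fallback = 1.3), 1.3)
  expect_equal(estimate_speed(0, 30 * pi / 180, 1), 0)
  expect_equal(estimate_speed(c(1, 1), c(-0.5, 0.5), 1,
                              method = "constant"), c(1, 1))
  # clipped at v_clip for implausible geometry
  expect_equal(estimate_speed(10, 6 * pi / 180, 1, v_clip = 12), 12)
})

test_that("pseudo-track integration follows heading and speed", {
  east <- integrate_pseudo_track(0:60, rep(pi / 2, 61), rep(1, 61),
                                 rep(0, 61))
  expect_equal(east$x_east[61], 60, tolerance = 1e-9)
  expect_equal(east$y_north[61], 0, tolerance = 1e-9)
  still <- integrate_pseudo_track(0:60, rep(1, 61), rep(0, 61), rep(0, 61))
  expect_true(all(abs(still$x_east) < 1e-12))
  out_back <- integrate_pseudo_track(0:60, c(rep(0, 30), rep(pi, 31)),
                                     rep(1, 61), rep(0, 61))
  expect_lt(abs(out_back$y_north[61]), 1e-9)
  # pitch shortens the horizontal component
  steep <- integrate_pseudo_track(0:60, rep(0, 61), rep(1, 61),
                                  rep(pi / 3, 61))
  expect_equal(steep$y_north[61], 60 * cos(pi / 3), tolerance = 1e-9)
})

test_that("georeferencing passes through fixes and spreads drift linearly", {
  n <- 601
  lat0 <- -36; lon0 <- 137
  # pseudo-track drifting east at 1 m/s; fixes say the animal went north
  pseudo <- data.frame(t = 0:(n - 1), x_east = 0:(n - 1),
                       y_north = rep(0, n), depth = 0)
  fixes <- fix_series(c(0, 600), c(lat0, lat0 + 600 / M_DEG),
                      c(lon0, lon0), c(8, 8))
  g <- georeference(pseudo, fixes)
  expect_lt(haversine_oracle(g$lon[1], g$lat[1], lon0, lat0), 1)
  expect_lt(haversine_oracle(g$lon[n], g$lat[n], lon0, lat0 + 600 / M_DEG), 1)
  # at the segment midpoint the correction is half the end drift
  mid <- which(g$t == 300)
  expect_equal((g$lat[mid] - lat0) * M_DEG, 300, tolerance = 1)
  expect_equal((g$lon[mid] - lon0) * M_DEG * cos(lat0 * pi / 180),
               300 - 300, tolerance = 1)
  # already-exact pseudo-track is returned unchanged
  py <- data.frame(t = 0:600, x_east = rep(0, 601), y_north = 0:600,
                   depth = 0)
  g2 <- georeference(py, fixes)
  expect_lt(max(haversine_oracle(g2$lon, g2$lat, lon0,
                                 lat0 + (0:600) / M_DEG)), 1e-3)
  expect_error(georeference(pseudo, fixes[1, ]), "two fixes")
  expect_warning(georeference(pseudo,
                              fix_series(c(0, 300, 1e6),
                                         c(lat0, lat0, lat0),
                                         c(lon0, lon0, lon0), rep(8, 3))),
                 "trimmed")
})

test_that("georeferenced track length dominates the straight-line fix path", {
  trip <- simulate_trip(trip_config(duration_h = 1.5, seed = 21))
  an <- suppressWarnings(suppressMessages(
    run_trip_analysis(trip$bundle, bottomuse_config(seed = 21),
                      trip$calibration, min_dives = Inf)))
  fx <- an$fixes
  straight <- sum(haversine_oracle(fx$lon[-nrow(fx)], fx$lat[-nrow(fx)],
                                   fx$lon[-1], fx$lat[-1]))
  expect_gte(sum(an$track$step_dist), straight)
})
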