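#' Configuration for the synthetic-trip simulator
#'
#' Describes a central-place benthic foraging trip: surface transit away
#' from the colony, a sequence of benthic dives drawn from two archetypes,
#' and a return leg. Archetype 1 emulates lower-effort bottom use (short,
#' straight, flat bottom phases); archetype 2 higher effort (long bottom
#' time, longer bottom distance, rugose substrate, tortuous movement), with
#' contrasts of at least two pooled standard deviations so the two modes
#' are recoverable by clustering. Sampling regimes mirror the real
#' deployment: 25 Hz tri-axial acceleration within +/- 4 G, 2 Hz tri-axial
#' magnetic field, 1 Hz depth, and surface GPS fixes at a 120 s cadence.
#'
#' @param colony_lat,colony_lon Colony position (decimal degrees).
#' @param duration_h Trip duration in hours.
#' @param transit_speed Surface transit speed (m/s).
#' @param dive_speed Descent/ascent swim speed (m/s).
#' @param bottom_speed_mean,bottom_speed_sd Per-dive bottom swim speed
#'   distribution (m/s), shared by both archetypes so mean bottom speed
#'   carries no archetype signal; the spread decorrelates bottom distance
#'   from bottom time the way individual swimming variation does.
#' @param depth_range Per-dive bottom depth drawn uniformly from this range
#'   (m), independent of archetype; the wide spread decorrelates the
#'   time-at-depth index from bottom time.
#' @param archetypes List of two lists with fields \code{bottom_dur_mean},
#'   \code{bottom_dur_sd}, \code{bottom_dur_range} (s; the ranges of the
#'   two behavioural modes are disjoint), \code{rel_rugosity_mean},
#'   \code{rel_rugosity_sd} (substrate relief as a fraction of bottom
#'   depth, the target of the depth-variability index), and
#'   \code{tortuosity} (rad s^-1/2 heading volatility during the bottom
#'   phase).
#' @param mixture_weight Probability that a dive is archetype 2.
#' @param surface_mean,surface_sd Surface-interval duration (s).
#' @param accel_noise,mag_noise,depth_noise Sensor noise sd (G, microtesla,
#'   m).
#' @param depth_offset Constant transducer offset added to emitted depth
#'   (m), exercising zero-offset correction.
#' @param gps_noise GPS position noise sd (m).
#' @param fix_interval GPS cadence while at the surface (s).
#' @param declination,inclination,field_intensity Local geomagnetic model
#'   (degrees, degrees, microtesla).
#' @param seed Mandatory integer seed; the whole trip is a deterministic
#'   function of it.
#' @return A list of class \code{trip_config}.
#' @export
trip_config <- function(colony_lat = -35.994, colony_lon = 137.317,
                        duration_h = 8, transit_speed = 1.5,
                        dive_speed = 1.8,
                        bottom_speed_mean = 1.0, bottom_speed_sd = 0.7,
                        depth_range = c(25, 100),
                        archetypes = list(
                          list(bottom_dur_mean = 70, bottom_dur_sd = 20,
                               bottom_dur_range = c(35, 115),
                               rel_rugosity_mean = 0.005,
                               rel_rugosity_sd = 0.004, tortuosity = 0.10),
                          list(bottom_dur_mean = 240, bottom_dur_sd = 40,
                               bottom_dur_range = c(175, 330),
                               rel_rugosity_mean = 0.085,
                               rel_rugosity_sd = 0.025, tortuosity = 0.45)),
                        mixture_weight = 0.5,
                        surface_mean = 150, surface_sd = 30,
                        accel_noise = 0.05, mag_noise = 0.3,
                        depth_noise = 0.1, depth_offset = 0.3,
                        gps_noise = 10, fix_interval = 120,
                        declination = 7.698, inclination = -68.012,
                        field_intensity = 60,
                        seed) {
  stop_if(missing(seed), "trip_config: seed is mandatory")
  stop_if(duration_h <= 0, "duration must be positive")
  stop_if(mixture_weight <= 0 || mixture_weight >= 1,
          "mixture_weight must lie in (0, 1)")
  stop_if(depth_range[1] <= 0 || depth_range[2] <= depth_range[1],
          "depth_range must be increasing and positive")
  for (a in archetypes)
    stop_if(a$bottom_dur_mean <= 0 || a$rel_rugosity_mean <= 0,
            "archetype durations/rugosities must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "trip_config"
  cfg
}

# Ornstein-Uhlenbeck increments at 1 Hz: reversion kappa toward mu,
# volatility sigma per sqrt(s).
ou_path <- function(n, x0, mu, kappa, sigma) {
  x <- numeric(n)
  x[1] <- x0
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sigma)
    for (i in 2:n) x[i] <- x[i - 1] + kappa * (mu - x[i - 1]) + eps[i - 1]
  }
  x
}

#' Simulate a foraging trip with known ground truth
#'
#' Generates a 1 Hz true path (position, depth, attitude, heading) by the
#' same kinematics the dead-reckoner assumes (horizontal step
#' \eqn{v\cos(pitch)} along the heading, vertical rate \eqn{-v\sin(pitch)}),
#' then emits mutually consistent raw sensor streams: 25 Hz acceleration as
#' gravity rotated into the device frame plus dynamic noise, 2 Hz magnetic
#' field as the local geomagnetic vector rotated into the device frame plus
#' noise, 1 Hz depth with noise and a constant transducer offset, and
#' surface-only GPS fixes with positional noise and a satellite count.
#' Sensor values are emitted in raw counts together with the affine
#' calibrations that map them back to physical units.
#'
#' @param config A \code{trip_config}.
#' @return List of class \code{synthetic_trip} with \code{bundle} (a raw
#'   \code{sensor_bundle}), \code{calibration} (per-axis calibrations for
#'   \code{\link{apply_calibration}}), and \code{truth} (true 1 Hz path,
#'   attitude/heading, and the dive table with archetype labels).
#' @export
simulate_trip <- function(config) {
  stop_if(!inherits(config, "trip_config"), "config must be a trip_config")
  set.seed(config$seed)
  n_total <- round(config$duration_h * 3600)
  # --- assemble the 1 Hz truth profile segment by segment ---------------
  depth <- numeric(0); speed <- numeric(0); state <- character(0)
  dive_id <- integer(0)
  h_vol <- numeric(0); h_base_mode <- character(0)
  dives <- list()
  t_len <- 0L
  add <- function(n, d, v, st, id, vol, mode) {
    depth <<- c(depth, d); speed <<- c(speed, v)
    state <<- c(state, rep(st, n)); dive_id <<- c(dive_id, rep(id, n))
    h_vol <<- c(h_vol, rep(vol, n)); h_base_mode <<- c(h_base_mode, rep(mode, n))
    t_len <<- t_len + n
  }
  next_dive <- 0L
  while (t_len < n_total) {
    frac <- t_len / n_total
    if (frac < 0.15) {          # outbound transit, no diving
      add(60L, rep(0, 60), rep(config$transit_speed, 60), "surface", 0L,
          0.02, "out")
      next
    }
    if (frac > 0.85) {          # homebound transit
      add(60L, rep(0, 60), rep(config$transit_speed, 60), "surface", 0L,
          0.02, "home")
      next
    }
    # surface interval inside the foraging patch (heading wanders)
    ns <- max(60L, round(stats::rnorm(1, config$surface_mean, config$surface_sd)))
    add(ns, rep(0, ns), rep(config$transit_speed, ns), "surface", 0L, 0.05, "patch")
    if (t_len >= n_total * 0.85) next
    # dive drawn from the archetype mixture
    next_dive <- next_dive + 1L
    type <- 1L + stats::rbinom(1, 1, config$mixture_weight)
    a <- config$archetypes[[type]]
    bdepth <- stats::runif(1, config$depth_range[1], config$depth_range[2])
    bdur <- round(min(max(stats::rnorm(1, a$bottom_dur_mean, a$bottom_dur_sd),
                          a$bottom_dur_range[1]), a$bottom_dur_range[2]))
    vbot <- min(max(stats::rnorm(1, config$bottom_speed_mean,
                                 config$bottom_speed_sd), 0.1), 2.8)
    vmax_z <- config$dive_speed * sin(deg2rad(60))
    vh_dive <- config$dive_speed * cos(deg2rad(60))
    nd <- ceiling(bdepth / vmax_z)
    t0 <- t_len
    add(nd, seq(bdepth / nd, bdepth, length.out = nd),
        rep(vh_dive, nd), "descent", next_dive, 0.02, "hold")
    # bottom relief: ridge-like oscillatory substrate (amplitude a fraction
    # of depth, period long enough that the swim speed can track it and the
    # 20 s smoother preserves it) plus OU texture, plus a 10 s swimming
    # undulation that keeps pitch informative for speed inference
    # relief must stay within ~10 % of bottom depth: beyond that the plateau
    # itself drops out of the > 80 %-of-max band and the bottom phase would
    # no longer cover the substrate the animal is working
    rel <- max(stats::rnorm(1, a$rel_rugosity_mean, a$rel_rugosity_sd), 0.001)
    amp <- max(min(rel * bdepth, 0.11 * bdepth - 0.5 * vbot), 0)
    period <- max(60, 2 * pi * amp / (0.7 * vbot))
    ridge <- amp * sin(2 * pi * seq_len(bdur) / period + stats::runif(1, 0, 2 * pi))
    rug <- ridge + ou_path(bdur, 0, 0, 0.03, 0.1 * vbot)
    rug <- pmax(pmin(rug, 0.12 * bdepth), -0.12 * bdepth)
    # 20 s undulation: nulled by the 20 s metric smoother, barely attenuated
    # by the 3 s attitude filter, so it feeds speed inference without
    # contaminating the depth-variability index
    wig <- 1.2 * vbot * sin(2 * pi * seq_len(bdur) / 20)
    add(bdur, pmax(bdepth + rug + wig, 0.4 * bdepth), rep(vbot, bdur),
        "bottom", next_dive,
        a$tortuosity * exp(stats::rnorm(1, 0, 0.3)), "hold")
    d_end <- depth[t_len]
    na <- ceiling(d_end / vmax_z)
    add(na, seq(d_end - d_end / na, 0, length.out = na),
        rep(vh_dive, na), "ascent", next_dive, 0.02, "hold")
    dives[[next_dive]] <- data.frame(
      dive_id = next_dive, archetype = type,
      t_start = t0, t_end = t_len - 1L,
      bottom_start = t0 + nd, bottom_end = t0 + nd + bdur - 1L,
      bottom_depth = bdepth, bottom_dur = bdur,
      bottom_speed = vbot, rel_rugosity = rel)
  }
  n <- t_len
  t <- seq_len(n) - 1                    # epoch seconds from trip start
  # `speed` holds the nominal horizontal ground speed of each segment; the
  # vertical rate comes from the depth profile, the swim vector is their
  # resultant, and pitch follows exactly: tan(pitch) = -dz / h. This keeps
  # horizontal bottom speed identically the drawn per-dive value, whatever
  # the relief demands vertically.
  dz <- c(diff(depth), 0)
  pitch <- -atan2(dz, speed)
  roll <- rep(0, n)
  # heading: outbound bearing for the first half, then home; tortuous on
  # the bottom
  heading <- numeric(n)
  heading[1] <- deg2rad(150)
  x <- y <- numeric(n)
  for (i in 2:n) {
    mode <- h_base_mode[i - 1]
    base <- switch(mode,
                   out = deg2rad(150),
                   home = wrap_2pi(atan2(-x[i - 1], -y[i - 1])),
                   heading[i - 1])
    kappa <- if (mode %in% c("out", "home")) 0.1 else 0
    delta <- ((base - heading[i - 1] + pi) %% (2 * pi)) - pi
    heading[i] <- heading[i - 1] + kappa * delta +
      stats::rnorm(1, 0, h_vol[i - 1])
    d <- speed[i - 1]                    # horizontal ground speed, dt = 1 s
    x[i] <- x[i - 1] + d * sin(heading[i - 1])
    y[i] <- y[i - 1] + d * cos(heading[i - 1])
  }
  lat <- config$colony_lat + y / M_PER_DEG
  lon <- config$colony_lon + x / (M_PER_DEG * cos(deg2rad(config$colony_lat)))
  # --- emit sensors ------------------------------------------------------
  # accel, 25 Hz: gravity in the device frame plus dynamic noise
  ta <- seq(0, t[n], by = 1 / 25)
  pa <- stats::approx(t, pitch, xout = ta)$y
  ga <- cbind(-sin(pa), 0, cos(pa))            # roll = 0
  acc <- ga + matrix(stats::rnorm(3 * length(ta), 0, config$accel_noise),
                     ncol = 3)
  acc <- pmax(pmin(acc, 4), -4)
  # mag, 2 Hz: geomagnetic vector rotated into the device frame
  tm <- seq(0, t[n], by = 1 / 2)
  pm <- stats::approx(t, pitch, xout = tm)$y
  hm <- stats::approx(t, heading, xout = tm)$y  # heading is unwrapped
  field <- earth_field_ned(config$declination, config$inclination,
                           config$field_intensity)
  mag <- ned_to_device(field, hm, pm, rep(0, length(tm))) +
    matrix(stats::rnorm(3 * length(tm), 0, config$mag_noise), ncol = 3)
  # depth, 1 Hz, with transducer offset
  dep <- depth + config$depth_offset + stats::rnorm(n, 0, config$depth_noise)
  # GPS: surface samples on the fix cadence
  at_surface <- depth < 1
  fix_idx <- which(at_surface & (t %% config$fix_interval) == 0)
  nsat <- sample(4:10, length(fix_idx), replace = TRUE,
                 prob = c(.1, .2, .2, .2, .15, .1, .05))
  fixes <- fix_series(t[fix_idx],
                      lat[fix_idx] + stats::rnorm(length(fix_idx), 0,
                                                  config$gps_noise / M_PER_DEG),
                      lon[fix_idx] + stats::rnorm(length(fix_idx), 0,
                        config$gps_noise / (M_PER_DEG * cos(deg2rad(config$colony_lat)))),
                      nsat)
  # raw counts through the inverse calibration maps
  cal_a <- fit_axis_calibration(0, 255, -4, 4)
  cal_m <- fit_axis_calibration(0, 1023, -100, 100)
  to_raw <- function(v, cal) (v - cal$intercept) / cal$slope
  bundle <- sensor_bundle(
    accel_series(ta, to_raw(acc[, 1], cal_a), to_raw(acc[, 2], cal_a),
                 to_raw(acc[, 3], cal_a), range = 256),
    mag_series(tm, to_raw(mag[, 1], cal_m), to_raw(mag[, 2], cal_m),
               to_raw(mag[, 3], cal_m)),
    depth_series(t, dep),
    fixes)
  truth <- list(
    path = data.frame(t = t, lat = lat, lon = lon, depth = depth,
                      x_east = x, y_north = y, state = state,
                      dive_id = dive_id),
    attitude = data.frame(t = t, pitch = pitch, roll = roll,
                          heading = wrap_2pi(heading)),
    dives = if (length(dives)) do.call(rbind, dives) else data.frame())
  structure(list(bundle = bundle,
                 calibration = list(
                   surge = cal_a, sway = cal_a, heave = cal_a,
                   mx = cal_m, my = cal_m, mz = cal_m),
                 truth = truth, config = config),
            class = "synthetic_trip")
}

#' Write a synthetic trip to the CSV dialects the reader ingests
#'
#' @param trip A \code{synthetic_trip}.
#' @param dir Output directory (created if needed).
#' @return Named vector of the file paths written (\code{accel, mag, depth,
#'   fixes, calibration, truth_dives, truth_path}).
#' @export
write_synthetic_trip <- function(trip, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- trip$bundle
  paths <- c(accel = file.path(dir, "accel.csv"),
             mag = file.path(dir, "mag.csv"),
             depth = file.path(dir, "depth.csv"),
             fixes = file.path(dir, "fixes.csv"),
             calibration = file.path(dir, "calibration.csv"),
             truth_dives = file.path(dir, "truth_dives.csv"),
             truth_path = file.path(dir, "truth_path.csv"))
  utils::write.csv(data.frame(time = b$accel$t, ax = b$accel$surge,
                              ay = b$accel$sway, az = b$accel$heave),
                   paths["accel"], row.names = FALSE)
  utils::write.csv(data.frame(time = b$mag$t, mx = b$mag$mx, my = b$mag$my,
                              mz = b$mag$mz), paths["mag"], row.names = FALSE)
  utils::write.csv(data.frame(time = b$depth$t, depth = b$depth$depth),
                   paths["depth"], row.names = FALSE)
  utils::write.csv(data.frame(time = b$fixes$t, lat = b$fixes$lat,
                              lon = b$fixes$lon, nsat = b$fixes$nsat),
                   paths["fixes"], row.names = FALSE)
  cal <- trip$calibration
  utils::write.csv(data.frame(
    axis = names(cal),
    raw_min = vapply(cal, `[[`, 0, "raw_min"),
    raw_max = vapply(cal, `[[`, 0, "raw_max"),
    target_min = vapply(cal, `[[`, 0, "target_min"),
    target_max = vapply(cal, `[[`, 0, "target_max")),
    paths["calibration"], row.names = FALSE)
  utils::write.csv(trip$truth$dives, paths["truth_dives"], row.names = FALSE)
  utils::write.csv(trip$truth$path, paths["truth_path"], row.names = FALSE)
  paths
}

#' Score pipeline outputs against simulator ground truth
#'
#' @param analysis Output of \code{\link{run_trip_analysis}} on the
#'   simulated bundle.
#' @param truth The \code{truth} element of a \code{synthetic_trip}.
#' @return List with \code{dive_precision}, \code{dive_recall},
#'   \code{cluster_ari} (adjusted Rand index between final cluster
#'   assignments and true archetypes of the matched dives, NA when no
#'   clustering was run), \code{track_rmse} and \code{interp_rmse} (RMS
#'   position error of the dead-reckoned track and of straight-line
#'   interpolation between the same GPS fixes, metres).
#' @export
truth_score <- function(analysis, truth) {
  # match detected dives to true dives by bottom-midpoint containment
  det <- analysis$segments$dives
  tru <- truth$dives
  match_true <- function(tmid)
    which(tru$t_start <= tmid & tru$t_end >= tmid)[1]
  mid <- (det$bottom_start + det$bottom_end) / 2
  hits <- vapply(mid, match_true, 0L)
  dive_recall <- length(unique(stats::na.omit(hits))) / nrow(tru)
  dive_precision <- mean(!is.na(hits))
  ari <- NA_real_
  if (!is.null(analysis$cluster$solution) &&
      !is.null(analysis$metrics$dive_id)) {
    m <- analysis$metrics
    mm <- match(m$dive_id, det$dive_id)
    archetype <- tru$archetype[hits[mm]]
    ok <- !is.na(archetype)
    ari <- mclust::adjustedRandIndex(analysis$cluster$solution$assignments[ok],
                                     archetype[ok])
  }
  # position errors on the truth grid
  tr <- analysis$track
  glat <- stats::approx(tr$t, tr$lat, xout = truth$path$t, rule = 2)$y
  glon <- stats::approx(tr$t, tr$lon, xout = truth$path$t, rule = 2)$y
  err <- gc_dist(glon, glat, truth$path$lon, truth$path$lat)
  fx <- analysis$fixes
  ilat <- stats::approx(fx$t, fx$lat, xout = truth$path$t, rule = 2)$y
  ilon <- stats::approx(fx$t, fx$lon, xout = truth$path$t, rule = 2)$y
  ierr <- gc_dist(ilon, ilat, truth$path$lon, truth$path$lat)
  list(dive_precision = dive_precision,
       dive_recall = dive_recall,
       cluster_ari = ari,
       track_rmse = sqrt(mean(err^2)),
       interp_rmse = sqrt(mean(ierr^2)))
}
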