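#' Split acceleration into static (gravity) and dynamic components
#'
#' A centred running mean (high-pass filter complement) separates the
#' low-frequency gravity signal, which encodes body orientation, from the
#' high-frequency dynamic acceleration of head/body movement. The
#' decomposition is exact: static + dynamic reproduces the input
#' elementwise, including at the edges where the window shrinks.
#'
#' @param accel An \code{accel_series}.
#' @param window Running-mean length in seconds (default 3 s).
#' @return List with \code{static} and \code{dynamic} data frames sharing
#'   the input timestamps.
#' @export
split_static_dynamic <- function(accel, window = 3) {
  stop_if(window <= 0, "window must be positive")
  n <- nrow(accel)
  dt <- stats::median(diff(accel$t))
  k <- max(1L, round(window / dt))
  stop_if(n <= k, "series shorter than the smoothing window")
  static <- data.frame(t = accel$t,
                       surge = runmean_centred(accel$surge, k),
                       sway  = runmean_centred(accel$sway, k),
                       heave = runmean_centred(accel$heave, k))
  dynamic <- data.frame(t = accel$t,
                        surge = accel$surge - static$surge,
                        sway  = accel$sway - static$sway,
                        heave = accel$heave - static$heave)
  list(static = static, dynamic = dynamic)
}

#' Derive pitch and roll from the static gravity vector
#'
#' Device convention: surge (x) forward, sway (y) right, heave (z) down, so
#' a level, motionless tag reads (0, 0, 1) G. Pitch is positive nose-up,
#' roll positive right-side-down:
#' \deqn{pitch = atan2(-g_x, \sqrt{g_y^2 + g_z^2}), \quad roll = atan2(g_y, g_z)}
#' Samples whose static vector norm falls below \code{min_norm} (sensor
#' glitch or violent manoeuvre) are flagged and their gravity direction
#' linearly interpolated from neighbouring good samples before the angles
#' are computed.
#'
#' @param static Data frame \code{t, surge, sway, heave} of static
#'   acceleration (G).
#' @param min_norm Minimum static-vector norm treated as trustworthy (G).
#' @return Data frame \code{t, pitch, roll, flagged} (radians).
#' @export
attitude_from_static <- function(static, min_norm = 0.2) {
  g <- cbind(static$surge, static$sway, static$heave)
  nrm <- sqrt(rowSums(g^2))
  bad <- !is.finite(nrm) | nrm < min_norm
  stop_if(all(bad), "no static samples with usable gravity norm")
  u <- g / nrm
  if (any(bad)) {
    good <- which(!bad)
    for (j in 1:3)
      u[bad, j] <- stats::approx(static$t[good], u[good, j],
                                 xout = static$t[bad], rule = 2)$y
    nb <- sqrt(rowSums(u[bad, , drop = FALSE]^2))
    u[bad, ] <- u[bad, , drop = FALSE] / nb
  }
  data.frame(t = static$t,
             pitch = atan2(-u[, 1], sqrt(u[, 2]^2 + u[, 3]^2)),
             roll = atan2(u[, 2], u[, 3]),
             flagged = bad)
}

# Geomagnetic field vector in local NED coordinates (relative to TRUE
# north), unit intensity unless given. Declination rotates the horizontal
# component east of true north; negative inclination (southern hemisphere)
# points the field upward.
earth_field_ned <- function(declination, inclination, intensity = 1) {
  D <- deg2rad(declination); I <- deg2rad(inclination)
  intensity * c(cos(I) * cos(D), cos(I) * sin(D), sin(I))
}

# Rotate a vector from local NED into the device frame for yaw/pitch/roll
# (aerospace z-y-x sequence; yaw measured from true north). Vectorised over
# attitude; v is length 3.
ned_to_device <- function(v, yaw, pitch, roll) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  # rows of R^T where R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)
  x <- v[1] * (cy * cp) + v[2] * (sy * cp) + v[3] * (-sp)
  y <- v[1] * (cy * sp * sr - sy * cr) + v[2] * (sy * sp * sr + cy * cr) + v[3] * (cp * sr)
  z <- v[1] * (cy * sp * cr + sy * sr) + v[2] * (sy * sp * cr - cy * sr) + v[3] * (cp * cr)
  cbind(x, y, z)
}

#' Tilt-compensated compass heading
#'
#' De-rotates the calibrated magnetometer vector by roll and then pitch so
#' its horizontal components can be read as a compass, then applies the
#' local magnetic declination to express the heading relative to true
#' north:
#' \deqn{m_{xh} = m_x \cos P + m_y \sin R \sin P + m_z \cos R \sin P}
#' \deqn{m_{yh} = m_y \cos R - m_z \sin R}
#' \deqn{heading = wrap(atan2(-m_{yh}, m_{xh}) + D)}
#' Samples whose de-rotated horizontal field is weaker than \code{h_min}
#' times the total field (tag pointing along the field; heading
#' unobservable) are flagged and interpolated from neighbours.
#'
#' @param mag Data frame \code{t, mx, my, mz} of calibrated field values.
#' @param pitch,roll Attitude in radians, same length as \code{mag} rows.
#' @param model List with \code{declination} and \code{inclination}
#'   (degrees).
#' @param h_min Minimum horizontal-to-total field ratio.
#' @return Data frame \code{t, heading, flagged}; heading in radians
#'   clockwise from true north in [0, 2pi).
#' @export
tilt_compensated_heading <- function(mag, pitch, roll, model, h_min = 0.05) {
  stop_if(length(pitch) != nrow(mag) || length(roll) != nrow(mag),
          "attitude and mag lengths differ")
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  mxh <- mag$mx * cp + mag$my * sr * sp + mag$mz * cr * sp
  myh <- mag$my * cr - mag$mz * sr
  total <- sqrt(mag$mx^2 + mag$my^2 + mag$mz^2)
  horiz <- sqrt(mxh^2 + myh^2)
  bad <- !is.finite(horiz) | horiz < h_min * total
  heading <- wrap_2pi(atan2(-myh, mxh) + deg2rad(model$declination))
  if (any(bad) && any(!bad)) {
    good <- which(!bad)
    ch <- stats::approx(mag$t[good], cos(heading[good]), xout = mag$t[bad], rule = 2)$y
    sh <- stats::approx(mag$t[good], sin(heading[good]), xout = mag$t[bad], rule = 2)$y
    heading[bad] <- wrap_2pi(atan2(sh, ch))
  }
  data.frame(t = mag$t, heading = heading, flagged = bad)
}

#' Estimate swim speed from vertical velocity and pitch
#'
#' When the animal is meaningfully pitched, the along-body speed follows
#' from the depth rate: \eqn{v = |dz/dt| / |\sin(pitch)|}. At shallow pitch
#' the geometry degenerates and a fallback cruising speed is used instead.
#' Because the georeferencing step rescales each inter-fix segment through
#' the GPS positions, a multiplicative speed error largely cancels.
#'
#' @param depth_rate Vertical speed (m/s, positive down).
#' @param pitch Pitch in radians.
#' @param fallback Speed assumed when |pitch| < \code{pitch_min} (m/s).
#' @param pitch_min Minimum usable |pitch| (degrees).
#' @param v_clip Ceiling on inferred speed (m/s); default twice the GPS
#'   speed-filter threshold.
#' @param method \code{"pitch"} (depth-rate inference) or
#'   \code{"constant"} (always the fallback).
#' @return Speed vector (m/s).
#' @export
estimate_speed <- function(depth_rate, pitch, fallback = 1.0, pitch_min = 5,
                           v_clip = 12, method = c("pitch", "constant")) {
  method <- match.arg(method)
  stop_if(fallback <= 0, "fallback speed must be positive")
  if (method == "constant") return(rep(fallback, length(depth_rate)))
  usable <- abs(pitch) >= deg2rad(pitch_min)
  v <- rep(fallback, length(depth_rate))
  v[usable] <- pmin(abs(depth_rate[usable]) / abs(sin(pitch[usable])), v_clip)
  v
}

#' Integrate heading, speed and pitch into a dead-reckoned pseudo-track
#'
#' Each one-second step advances the track by the horizontal component of
#' the swim vector, \eqn{d = v \, dt \, \cos(pitch)}, along the heading:
#' east displacement \eqn{d \sin h}, north displacement \eqn{d \cos h},
#' accumulated from the origin. The result is the uncorrected
#' "pseudo-track" in local metres; georeferencing pins it to the GPS fixes.
#'
#' @param t Timestamps (s).
#' @param heading Heading (radians from true north).
#' @param speed Speed (m/s).
#' @param pitch Pitch (radians).
#' @param depth Depth (m), carried through.
#' @param origin Length-2 origin \code{c(x_east, y_north)} in metres.
#' @param active Logical; steps where FALSE contribute no displacement
#'   (flagged gaps).
#' @return Data frame \code{t, x_east, y_north, depth}.
#' @export
integrate_pseudo_track <- function(t, heading, speed, pitch, depth = NULL,
                                   origin = c(0, 0), active = NULL) {
  n <- length(t)
  stop_if(n < 2, "need at least two samples")
  if (is.null(active)) active <- rep(TRUE, n)
  dt <- c(diff(t), 0)            # step taken from sample i to i+1
  d <- speed * dt * cos(pitch)
  d[!active] <- 0
  dx <- d * sin(heading)
  dy <- d * cos(heading)
  data.frame(t = t,
             x_east = origin[1] + c(0, cumsum(dx)[-n]),
             y_north = origin[2] + c(0, cumsum(dy)[-n]),
             depth = if (is.null(depth)) 0 else depth)
}

# Metres per degree of latitude on the sphere used for haversine distances.
M_PER_DEG <- pi / 180 * 6378137

#' Georeference a pseudo-track through GPS fixes
#'
#' Pins the dead-reckoned pseudo-track to geography by forcing it through
#' every retained GPS fix. For each inter-fix segment the track is anchored
#' at the opening fix, the mismatch at the closing fix (accumulated
#' dead-reckoning drift) is measured, and the correction is distributed
#' linearly in time across the segment, so the output passes through every
#' fix exactly while keeping the fine-scale shape of the reconstruction.
#' Samples before the first or after the last fix are anchored to the
#' nearest fix with no drift correction. Metres/degrees conversion is local
#' equirectangular at the segment latitude.
#'
#' @param pseudo Data frame from \code{\link{integrate_pseudo_track}}.
#' @param fixes A \code{fix_series} with at least two rows inside the
#'   pseudo-track time range (fixes outside are trimmed with a warning).
#' @return A \code{geo_track} data frame \code{t, lat, lon, depth,
#'   step_dist} (metres between consecutive samples).
#' @export
georeference <- function(pseudo, fixes) {
  inside <- fixes$t >= pseudo$t[1] & fixes$t <= pseudo$t[nrow(pseudo)]
  if (any(!inside)) {
    warning(sprintf("%d fix(es) outside pseudo-track range trimmed", sum(!inside)))
    fixes <- fixes[inside, , drop = FALSE]
  }
  stop_if(nrow(fixes) < 2, "georeference needs at least two fixes in range")
  # pseudo position interpolated at fix times
  fx <- stats::approx(pseudo$t, pseudo$x_east, xout = fixes$t)$y
  fy <- stats::approx(pseudo$t, pseudo$y_north, xout = fixes$t)$y
  nf <- nrow(fixes)
  seg <- findInterval(pseudo$t, fixes$t)     # 0 before first fix, nf after last
  seg_anchor <- pmin(pmax(seg, 1L), nf - 1L) # anchor fix index per sample
  i <- seg_anchor
  mlat <- M_PER_DEG
  mlon <- M_PER_DEG * cos(deg2rad(fixes$lat[i]))
  # anchored provisional position
  lat0 <- fixes$lat[i] + (pseudo$y_north - fy[i]) / mlat
  lon0 <- fixes$lon[i] + (pseudo$x_east - fx[i]) / mlon
  # drift at the closing fix of each segment, in degrees
  dlat_end <- fixes$lat[i + 1L] - (fixes$lat[i] + (fy[i + 1L] - fy[i]) / mlat)
  dlon_end <- fixes$lon[i + 1L] - (fixes$lon[i] + (fx[i + 1L] - fx[i]) / mlon)
  frac <- (pseudo$t - fixes$t[i]) / (fixes$t[i + 1L] - fixes$t[i])
  frac <- pmin(pmax(frac, 0), 1)            # no extrapolated correction
  lat <- lat0 + frac * dlat_end
  lon <- lon0 + frac * dlon_end
  n <- nrow(pseudo)
  step <- c(0, gc_dist(lon[-n], lat[-n], lon[-1], lat[-1]))
  structure(data.frame(t = pseudo$t, lat = lat, lon = lon,
                       depth = pseudo$depth, step_dist = step),
            class = c("geo_track", "data.frame"))
}

#' Dead-reckon a full sensor bundle into a georeferenced track
#'
#' Convenience orchestration of the reconstruction chain: static/dynamic
#' split of the raw acceleration, alignment onto the 1 Hz depth clock,
#' attitude from per-second mean static acceleration, tilt-compensated
#' heading, depth-rate speed, pseudo-track integration, and georeferencing
#' through the satellite- and speed-filtered GPS fixes.
#'
#' @param bundle A calibrated \code{sensor_bundle} (depth already
#'   zero-offset corrected).
#' @param config A \code{bottomuse_config}.
#' @return List with \code{track} (a \code{geo_track}), \code{pseudo},
#'   \code{attitude}, \code{heading}, \code{merged} (the aligned frame) and
#'   \code{fixes} (the retained fixes).
#' @export
dead_reckon <- function(bundle, config = bottomuse_config()) {
  parts <- split_static_dynamic(bundle$accel, window = config$hp_window)
  static_bundle <- bundle
  static_bundle$accel <- accel_series(parts$static$t, parts$static$surge,
                                      parts$static$sway, parts$static$heave,
                                      range = Inf)
  merged <- align_streams(static_bundle)
  ok <- merged$complete
  att <- attitude_from_static(merged[ok, c("t", "surge", "sway", "heave")])
  pitch <- roll <- rep(0, nrow(merged))
  pitch[ok] <- att$pitch; roll[ok] <- att$roll
  hdg <- rep(0, nrow(merged))
  h <- tilt_compensated_heading(merged[ok, c("t", "mx", "my", "mz")],
                                pitch[ok], roll[ok],
                                list(declination = config$declination,
                                     inclination = config$inclination))
  hdg[ok] <- h$heading
  # forward difference: sample i's attitude and speed drive the step to
  # i + 1, matching the integrator's left-endpoint convention
  dz <- c(diff(merged$depth) / diff(merged$t), 0)
  speed <- estimate_speed(dz, pitch, fallback = config$fallback_speed,
                          pitch_min = config$pitch_min,
                          v_clip = 2 * config$vmax,
                          method = config$speed_method)
  pseudo <- integrate_pseudo_track(merged$t, hdg, speed, pitch,
                                   depth = merged$depth, active = ok)
  fixes <- speed_filter(filter_satellites(bundle$fixes, config$min_sat),
                        config$vmax)
  track <- georeference(pseudo, fixes)
  list(track = track, pseudo = pseudo,
       attitude = data.frame(t = merged$t, pitch = pitch, roll = roll),
       heading = data.frame(t = merged$t, heading = hdg),
       merged = merged, fixes = fixes)
}
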