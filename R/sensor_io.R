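#' Sensor stream constructors
#'
#' Light validating constructors for the four raw streams of a biologging
#' deployment: tri-axial head acceleration (nominal 25 Hz, G), tri-axial
#' magnetic field (nominal 2 Hz, microtesla), depth from a time-depth
#' recorder (1 Hz, metres positive down), and GPS surface fixes. Timestamps
#' are UTC epoch seconds and must be strictly increasing; gaps are allowed
#' and flagged downstream.
#'
#' @param t Numeric vector of UTC epoch seconds.
#' @param surge,sway,heave Acceleration along the anterior-posterior,
#'   lateral and dorsal-ventral axes (G).
#' @param range Absolute sensor range in G (values outside it are an error).
#' @return A data frame with a series subclass.
#' @export
accel_series <- function(t, surge, sway, heave, range = 4) {
  n <- length(t)
  stop_if(length(surge) != n || length(sway) != n || length(heave) != n,
          "accel_series: column lengths differ")
  check_monotonic(t, "accel")
  amax <- suppressWarnings(max(abs(c(surge, sway, heave)), na.rm = TRUE))
  stop_if(is.finite(amax) && amax > range + 1e-9,
          sprintf("accel_series: |value| %.3f exceeds sensor range %.1f G", amax, range))
  structure(data.frame(t = t, surge = surge, sway = sway, heave = heave),
            class = c("accel_series", "data.frame"))
}

#' @rdname accel_series
#' @param mx,my,mz Magnetic field along the roll (north), pitch (east) and
#'   yaw (down) device axes (microtesla).
#' @export
mag_series <- function(t, mx, my, mz) {
  n <- length(t)
  stop_if(length(mx) != n || length(my) != n || length(mz) != n,
          "mag_series: column lengths differ")
  check_monotonic(t, "mag")
  stop_if(!all(is.finite(c(mx, my, mz))), "mag_series: non-finite values")
  structure(data.frame(t = t, mx = mx, my = my, mz = mz),
            class = c("mag_series", "data.frame"))
}

#' @rdname accel_series
#' @param depth Depth in metres, positive down.
#' @export
depth_series <- function(t, depth) {
  stop_if(length(depth) != length(t), "depth_series: column lengths differ")
  check_monotonic(t, "depth")
  structure(data.frame(t = t, depth = depth),
            class = c("depth_series", "data.frame"))
}

#' @rdname accel_series
#' @param lat,lon WGS84 decimal degrees.
#' @param nsat Number of satellites used in the fix.
#' @export
fix_series <- function(t, lat, lon, nsat) {
  n <- length(t)
  stop_if(length(lat) != n || length(lon) != n || length(nsat) != n,
          "fix_series: column lengths differ")
  if (n > 0) check_monotonic(t, "fixes")
  stop_if(n > 0 && (any(abs(lat) > 90) || any(abs(lon) > 180)),
          "fix_series: coordinates out of range")
  structure(data.frame(t = t, lat = lat, lon = lon, nsat = nsat),
            class = c("fix_series", "data.frame"))
}

#' Bundle time-cropped sensor streams for one foraging trip
#'
#' Crops all four streams to \code{trip_window} (data collected before the
#' start or after the end of the trip are omitted). The window defaults to
#' the intersection of the stream time ranges; an empty intersection is a
#' validation error.
#'
#' @param accel,mag,depth,fixes Series built by the constructors above.
#' @param trip_window Length-2 numeric \code{c(t_start, t_end)}, or NULL.
#' @return A list of class \code{sensor_bundle}.
#' @export
sensor_bundle <- function(accel, mag, depth, fixes, trip_window = NULL) {
  if (is.null(trip_window)) {
    trip_window <- c(max(min(accel$t), min(mag$t), min(depth$t)),
                     min(max(accel$t), max(mag$t), max(depth$t)))
  }
  stop_if(trip_window[2] <= trip_window[1],
          "sensor_bundle: streams have no common time range")
  crop <- function(s) s[s$t >= trip_window[1] & s$t <= trip_window[2], , drop = FALSE]
  out <- list(accel = crop(accel), mag = crop(mag), depth = crop(depth),
              fixes = crop(fixes), trip_window = trip_window)
  stop_if(nrow(out$depth) == 0, "sensor_bundle: no depth samples inside trip window")
  class(out) <- "sensor_bundle"
  out
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat(sprintf("sensor_bundle: %.1f h trip\n",
              diff(x$trip_window) / 3600))
  cat(sprintf("  accel %d rows | mag %d rows | depth %d rows | fixes %d\n",
              nrow(x$accel), nrow(x$mag), nrow(x$depth), nrow(x$fixes)))
  invisible(x)
}

#' Read the four sensor streams from delimited text files
#'
#' @param paths Named list or character vector with elements \code{accel},
#'   \code{mag}, \code{depth}, \code{fixes}, each a CSV path. Default column
#'   names are \code{time,ax,ay,az}, \code{time,mx,my,mz},
#'   \code{time,depth} and \code{time,lat,lon,nsat}; remap with
#'   \code{columns}.
#' @param config A \code{bottomuse_config} (currently unused for parsing but
#'   carried for provenance).
#' @param columns Optional named list overriding the column map per stream,
#'   e.g. \code{list(depth = c(time = "secs", depth = "press_m"))}.
#' @param trip_window Optional explicit trip window (epoch seconds).
#' @param accel_range Acceleration validity range. Files holding raw
#'   counts have no physical bound until calibrated, so the reader default
#'   is \code{Inf}; pass 4 for files already in G.
#' @return A \code{sensor_bundle}. Gaps larger than twice the nominal
#'   sampling interval are reported with a message.
#' @export
read_sensor_bundle <- function(paths, config = bottomuse_config(),
                               columns = list(), trip_window = NULL,
                               accel_range = Inf) {
  need <- c("accel", "mag", "depth", "fixes")
  stop_if(!all(need %in% names(paths)),
          sprintf("paths must name %s", paste(need, collapse = ", ")))
  defaults <- list(
    accel = c(time = "time", surge = "ax", sway = "ay", heave = "az"),
    mag   = c(time = "time", mx = "mx", my = "my", mz = "mz"),
    depth = c(time = "time", depth = "depth"),
    fixes = c(time = "time", lat = "lat", lon = "lon", nsat = "nsat"))
  grab <- function(stream) {
    map <- defaults[[stream]]
    if (!is.null(columns[[stream]])) map[names(columns[[stream]])] <- columns[[stream]]
    df <- utils::read.csv(paths[[stream]], stringsAsFactors = FALSE)
    missing <- setdiff(unname(map), names(df))
    stop_if(length(missing) > 0,
            sprintf("%s file %s: missing column(s) %s", stream, paths[[stream]],
                    paste(missing, collapse = ", ")))
    out <- df[, unname(map), drop = FALSE]
    names(out) <- names(map)
    out
  }
  a <- grab("accel"); m <- grab("mag"); d <- grab("depth"); f <- grab("fixes")
  report_gaps <- function(t, nominal, what) {
    gaps <- which(diff(t) > 2 * nominal)
    if (length(gaps) > 0)
      message(sprintf("%s: %d gap(s) > %.2f s (first at t = %.1f)",
                      what, length(gaps), 2 * nominal, t[gaps[1]]))
  }
  report_gaps(a$time, 1 / 25, "accel")
  report_gaps(m$time, 1 / 2, "mag")
  report_gaps(d$time, 1, "depth")
  bundle <- sensor_bundle(
    accel_series(a$time, a$surge, a$sway, a$heave, range = accel_range),
    mag_series(m$time, m$mx, m$my, m$mz),
    depth_series(d$time, d$depth),
    fix_series(f$time, f$lat, f$lon, f$nsat),
    trip_window = trip_window)
  message(sprintf("read %d accel, %d mag, %d depth rows, %d fixes",
                  nrow(bundle$accel), nrow(bundle$mag), nrow(bundle$depth),
                  nrow(bundle$fixes)))
  bundle
}

#' Discard GPS fixes with too few satellites
#'
#' Fastloc positions solved from four or fewer satellites are unreliable and
#' are discarded; the default keeps fixes with at least five.
#'
#' @param fixes A \code{fix_series}.
#' @param min_sat Minimum satellite count retained.
#' @return The filtered \code{fix_series} (possibly empty), order preserved.
#' @export
filter_satellites <- function(fixes, min_sat = 5) {
  stop_if(min_sat < 0, "min_sat must be >= 0")
  keep <- fixes$nsat >= min_sat
  fixes[keep, , drop = FALSE]
}

#' Remove fixes implying unrealistic swim speeds
#'
#' Forward-sequential filter: walking the series in time order, a fix whose
#' great-circle speed from the last retained fix exceeds \code{vmax} is
#' dropped. Every consecutive retained pair therefore satisfies the speed
#' bound, and re-applying the filter changes nothing.
#'
#' @param fixes A \code{fix_series} with at least one row.
#' @param vmax Speed threshold (m/s); the default 6 m/s is the ceiling of
#'   plausible sea lion swim speed.
#' @return The filtered \code{fix_series}.
#' @export
speed_filter <- function(fixes, vmax = 6) {
  stop_if(vmax <= 0, "vmax must be positive")
  n <- nrow(fixes)
  if (n <= 1L) return(fixes)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    dt <- fixes$t[i] - fixes$t[last]
    dd <- gc_dist(fixes$lon[last], fixes$lat[last], fixes$lon[i], fixes$lat[i])
    if (dd / dt <= vmax) {
      keep[i] <- TRUE
      last <- i
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Zero-offset correct a time-depth record
#'
#' Pressure transducers drift over a deployment, so raw "surface" readings
#' wander away from zero. The correction estimates a surface baseline as a
#' rolling low quantile of near-surface samples (depth < \code{surface})
#' inside a sliding window, interpolates that baseline over the whole
#' record, and subtracts it. Within-dive depth differences are preserved for
#' offsets that are constant on the scale of a dive.
#'
#' @param depth A \code{depth_series}.
#' @param window Baseline window (s); drift is assumed smooth on this scale.
#' @param quantile Quantile of near-surface depths taken as true surface.
#' @param surface Depth below which a raw sample can be a surface candidate (m).
#' @param clip Clip corrected depths at zero.
#' @return Corrected \code{depth_series}. If the record never comes near the
#'   surface the input is returned unchanged with a warning.
#' @export
zero_offset_correct <- function(depth, window = 7200, quantile = 0.10,
                                surface = 3, clip = FALSE) {
  stop_if(nrow(depth) == 0, "empty depth series")
  stop_if(window <= 0, "window must be positive")
  cand <- which(depth$depth < surface)
  if (length(cand) == 0) {
    warning("no surface candidates; zero-offset correction skipped")
    return(depth)
  }
  ct <- depth$t[cand]
  cd <- depth$depth[cand]
  # Baseline evaluated at regular knots, each the low quantile of surface
  # candidates within +/- window/2; interpolated to every sample.
  knots <- seq(min(depth$t), max(depth$t), by = max(60, window / 20))
  base <- vapply(knots, function(k) {
    w <- cd[ct >= k - window / 2 & ct <= k + window / 2]
    if (length(w) == 0) NA_real_ else unname(stats::quantile(w, quantile))
  }, 0)
  ok <- is.finite(base)
  stop_if(sum(ok) == 0, "zero-offset correction: no usable baseline knots")
  baseline <- stats::approx(knots[ok], base[ok], xout = depth$t, rule = 2)$y
  corrected <- depth$depth - baseline
  if (clip) corrected <- pmax(corrected, 0)
  depth_series(depth$t, corrected)
}

#' Time-align the sensor streams onto the 1 Hz depth clock
#'
#' The depth record is the master grid: one output row per depth sample.
#' Acceleration is averaged within each one-second bin centred on the depth
#' timestamp; the slower magnetometer is linearly interpolated to the grid.
#' Rows missing any channel (gaps in a stream) are retained but flagged
#' \code{complete = FALSE} and excluded from dead-reckoning.
#'
#' @param bundle A \code{sensor_bundle}.
#' @return Data frame \code{t, surge, sway, heave, mx, my, mz, depth,
#'   complete} with one row per second of overlap.
#' @export
align_streams <- function(bundle) {
  d <- bundle$depth; a <- bundle$accel; m <- bundle$mag
  t0 <- max(min(d$t), min(a$t), min(m$t))
  t1 <- min(max(d$t), max(a$t), max(m$t))
  stop_if(t1 <= t0, "align_streams: streams do not overlap")
  d <- d[d$t >= t0 & d$t <= t1, , drop = FALSE]
  grid <- d$t
  # accel samples binned to nearest grid second
  bin <- findInterval(a$t, grid - 0.5)
  inside <- bin >= 1L & bin <= length(grid)
  agg <- function(v) {
    s <- rowsum(v[inside], bin[inside])
    cnt <- rowsum(rep(1, sum(inside)), bin[inside])
    out <- rep(NA_real_, length(grid))
    out[as.integer(rownames(s))] <- s / cnt
    out
  }
  interp <- function(v) {
    out <- stats::approx(m$t, v, xout = grid, rule = 1)$y
    # do not bridge gaps wider than 4x the nominal 0.5 s spacing
    gap_after <- which(diff(m$t) > 2)
    for (g in gap_after) out[grid > m$t[g] & grid < m$t[g + 1]] <- NA_real_
    out
  }
  out <- data.frame(t = grid,
                    surge = agg(a$surge), sway = agg(a$sway), heave = agg(a$heave),
                    mx = interp(m$mx), my = interp(m$my), mz = interp(m$mz),
                    depth = d$depth)
  out$complete <- stats::complete.cases(out)
  if (any(!out$complete))
    message(sprintf("align_streams: %d of %d rows incomplete (stream gaps)",
                    sum(!out$complete), nrow(out)))
  out
}
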