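#' Per-axis linear sensor calibration
#'
#' Before deployment the tag is physically rotated through all attitudes and
#' the raw minimum/maximum recorded on each accelerometer and magnetometer
#' axis. Each axis is then standardised with the affine map that sends the
#' observed raw extrema exactly onto the physical-unit extrema (slope and
#' intercept of a linear model through the two endpoints).
#'
#' @param raw_min,raw_max Raw extrema recorded during the rotation
#'   calibration (raw counts).
#' @param target_min,target_max Physical-unit extrema (G or microtesla).
#' @return An \code{axis_calibration} with \code{slope} and
#'   \code{intercept}.
#' @export
fit_axis_calibration <- function(raw_min, raw_max, target_min, target_max) {
  stop_if(raw_max <= raw_min,
          "degenerate calibration: raw_max must exceed raw_min")
  stop_if(target_max <= target_min,
          "degenerate calibration: target_max must exceed target_min")
  slope <- (target_max - target_min) / (raw_max - raw_min)
  structure(list(raw_min = raw_min, raw_max = raw_max,
                 target_min = target_min, target_max = target_max,
                 slope = slope, intercept = target_min - slope * raw_min),
            class = "axis_calibration")
}

#' Apply per-axis calibrations to a raw series
#'
#' @param series An \code{accel_series} or \code{mag_series} in raw units.
#' @param calibrations Named list of \code{axis_calibration}, one per value
#'   column of \code{series} (e.g. \code{surge}, \code{sway}, \code{heave}).
#' @return The series with each axis mapped to physical units; timestamps
#'   unchanged.
#' @export
apply_calibration <- function(series, calibrations) {
  axes <- setdiff(names(series), "t")
  stop_if(!all(axes %in% names(calibrations)),
          sprintf("calibrations must name axes %s", paste(axes, collapse = ", ")))
  out <- series
  for (ax in axes) {
    cal <- calibrations[[ax]]
    stop_if(!inherits(cal, "axis_calibration"),
            sprintf("calibrations$%s is not an axis_calibration", ax))
    out[[ax]] <- cal$slope * series[[ax]] + cal$intercept
  }
  # re-validate through the constructor the series came from
  if (inherits(series, "accel_series"))
    out <- accel_series(out$t, out$surge, out$sway, out$heave,
                        range = max(4, max(abs(c(out$surge, out$sway, out$heave)))))
  if (inherits(series, "mag_series"))
    out <- mag_series(out$t, out$mx, out$my, out$mz)
  out
}

#' Read a calibration file
#'
#' Six CSV rows (three accelerometer, three magnetometer axes) with columns
#' \code{axis, raw_min, raw_max, target_min, target_max}; axis names are
#' \code{surge, sway, heave, mx, my, mz}.
#'
#' @param path CSV path.
#' @return Named list of \code{axis_calibration}.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("axis", "raw_min", "raw_max", "target_min", "target_max")
  stop_if(!all(need %in% names(df)),
          sprintf("calibration file: need columns %s", paste(need, collapse = ", ")))
  cals <- lapply(seq_len(nrow(df)), function(i)
    fit_axis_calibration(df$raw_min[i], df$raw_max[i],
                         df$target_min[i], df$target_max[i]))
  names(cals) <- df$axis
  cals
}
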