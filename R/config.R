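#' Pipeline run configuration
#'
#' Collects every tunable parameter of the processing chain in one place.
#' Defaults follow the deployment described for adult female Australian sea
#' lions at Seal Bay, Kangaroo Island: Fastloc GPS fixes filtered at 6 m/s and
#' at least five satellites, a 3 s running mean to split static from dynamic
#' acceleration, a 20 s smoothing window for the time-depth record, bottom
#' phases at > 80 % of maximum dive depth, a Pearson collinearity ceiling of
#' 0.750, stepwise removal at p > 0.05, and the local geomagnetic field
#' (declination 7.698 deg, inclination -68.012 deg).
#'
#' @param colony_lat,colony_lon Colony (central place) in WGS84 decimal
#'   degrees. Defaults: Seal Bay Conservation Park.
#' @param vmax Maximum plausible swim speed for the GPS speed filter (m/s).
#' @param min_sat Minimum satellite count for a fix to be retained.
#' @param hp_window Running-mean length separating static from dynamic
#'   acceleration (s).
#' @param smooth_window Depth smoothing window for dive segmentation (s).
#' @param dive_threshold Minimum smoothed depth for a dive (m).
#' @param bottom_frac Fraction of maximum dive depth defining the bottom
#'   phase.
#' @param r_max Pairwise Pearson correlation above which a predictor is
#'   dropped (strict inequality).
#' @param alpha Stepwise removal threshold on per-term p-values.
#' @param declination,inclination Local geomagnetic declination and
#'   inclination (degrees).
#' @param zoc_window Window for the rolling surface baseline of the
#'   zero-offset correction (s).
#' @param zoc_quantile Quantile of near-surface depths used as the baseline.
#' @param zoc_surface Depth below which a sample is a surface candidate (m).
#' @param zoc_clip Clip corrected depths at zero.
#' @param fallback_speed Swim speed assumed when pitch is too shallow to
#'   infer speed from the depth rate (m/s).
#' @param pitch_min Minimum absolute pitch for depth-rate speed inference
#'   (degrees).
#' @param speed_method Speed strategy for dead-reckoning: depth-rate over
#'   sine of pitch with fallback (\code{"pitch"}) or a constant
#'   (\code{"constant"}).
#' @param sinuosity_cap Value assigned when the bottom path returns to its
#'   start and the straight-line denominator degenerates.
#' @param k_min,k_max Search range for the number of clusters.
#' @param n_restarts Random restarts per k-means fit.
#' @param seed Integer seed driving every stochastic step.
#' @return A list of class \code{bottomuse_config}.
#' @export
bottomuse_config <- function(colony_lat = -35.994, colony_lon = 137.317,
                             vmax = 6, min_sat = 5,
                             hp_window = 3, smooth_window = 20,
                             dive_threshold = 5, bottom_frac = 0.8,
                             r_max = 0.750, alpha = 0.05,
                             declination = 7.698, inclination = -68.012,
                             zoc_window = 7200, zoc_quantile = 0.10,
                             zoc_surface = 3, zoc_clip = FALSE,
                             fallback_speed = 1.0, pitch_min = 5,
                             speed_method = c("pitch", "constant"),
                             sinuosity_cap = 50,
                             k_min = 2, k_max = 8, n_restarts = 25,
                             seed = 1L) {
  cfg <- list(colony_lat = colony_lat, colony_lon = colony_lon,
              vmax = vmax, min_sat = min_sat,
              hp_window = hp_window, smooth_window = smooth_window,
              dive_threshold = dive_threshold, bottom_frac = bottom_frac,
              r_max = r_max, alpha = alpha,
              declination = declination, inclination = inclination,
              zoc_window = zoc_window, zoc_quantile = zoc_quantile,
              zoc_surface = zoc_surface, zoc_clip = zoc_clip,
              fallback_speed = fallback_speed, pitch_min = pitch_min,
              speed_method = match.arg(speed_method),
              sinuosity_cap = sinuosity_cap,
              k_min = k_min, k_max = k_max, n_restarts = n_restarts,
              seed = as.integer(seed))
  stop_if(cfg$vmax <= 0, "vmax must be positive")
  stop_if(cfg$bottom_frac <= 0 || cfg$bottom_frac >= 1,
          "bottom_frac must lie in (0, 1)")
  stop_if(cfg$declination <= -180 || cfg$declination > 180,
          "declination out of range")
  stop_if(abs(cfg$inclination) > 90, "inclination out of range")
  class(cfg) <- "bottomuse_config"
  cfg
}

#' Read a run configuration from a plain key=value file
#'
#' Lines look like \code{vmax = 6}; blank lines and lines starting with
#' \code{#} are ignored. Unknown keys are an error so that typos do not
#' silently fall back to defaults.
#'
#' @param path Path to the configuration file.
#' @return A \code{bottomuse_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  stop_if(any(bad), sprintf("config: cannot parse line '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- names(formals(bottomuse_config))
  unknown <- setdiff(keys, known)
  stop_if(length(unknown) > 0,
          sprintf("config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "speed_method") vals[i]
    else if (vals[i] %in% c("TRUE", "FALSE")) as.logical(vals[i])
    else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(bottomuse_config, args)
}

#' Write a run configuration as key=value text
#'
#' @param config A \code{bottomuse_config}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) format(v, digits = 15), "")
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}
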