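#' Smooth a time-depth record
#'
#' Centred rolling mean over \code{window} seconds (shrinking symmetric
#' windows at the record edges) applied before dive detection, suppressing
#' transducer noise so phase boundaries are stable.
#'
#' @param depth A \code{depth_series} (1 Hz).
#' @param window Smoothing window in seconds (default 20 s).
#' @return A \code{depth_series} of the same length.
#' @export
smooth_depth <- function(depth, window = 20) {
  stop_if(window <= 0, "window must be positive")
  dt <- if (nrow(depth) > 1) stats::median(diff(depth$t)) else 1
  k <- max(1L, round(window / dt))
  depth_series(depth$t, runmean_centred(depth$depth, k))
}

#' Detect dives in a corrected depth record
#'
#' A dive is a maximal run of samples whose (smoothed) depth is at or above
#' the dive threshold; everything else is surface. Depth must already be
#' zero-offset corrected.
#'
#' @param depth A smoothed \code{depth_series}.
#' @param dive_threshold Minimum depth for a sample to belong to a dive (m).
#' @return Data frame with one row per dive: \code{dive_id, t_start, t_end,
#'   max_depth, i_start, i_end} (row indices into \code{depth}).
#' @export
detect_dives <- function(depth, dive_threshold = 5) {
  stop_if(dive_threshold <= 0, "dive_threshold must be positive")
  sub <- depth$depth >= dive_threshold
  if (!any(sub)) {
    return(data.frame(dive_id = integer(), t_start = numeric(),
                      t_end = numeric(), max_depth = numeric(),
                      i_start = integer(), i_end = integer()))
  }
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  i_start <- starts[keep]; i_end <- ends[keep]
  data.frame(dive_id = seq_along(i_start),
             t_start = depth$t[i_start],
             t_end = depth$t[i_end],
             max_depth = vapply(seq_along(i_start), function(j)
               max(depth$depth[i_start[j]:i_end[j]]), 0),
             i_start = i_start, i_end = i_end)
}

#' Label descent, bottom and ascent phases of a dive
#'
#' The bottom phase is the contiguous span from the first to the last
#' sample deeper than \code{bottom_frac} of the dive's maximum depth (the
#' benthic operative definition: > 80 % of maximum dive depth). Brief
#' excursions above the line inside that span stay "bottom", matching a
#' benthic forager tracking rugose substrate. Descent is everything before
#' the span, ascent everything after; the three phases partition the dive's
#' samples.
#'
#' @param dive One row of the \code{\link{detect_dives}} table.
#' @param depth The same \code{depth_series} the dive indices refer to.
#' @param bottom_frac Bottom threshold as a fraction of maximum dive depth.
#' @return List with \code{phases} (character vector over the dive's
#'   samples) and \code{bottom} (data frame \code{dive_id, i, t, depth} of
#'   bottom samples, indices into \code{depth}).
#' @export
label_phases <- function(dive, depth, bottom_frac = 0.8) {
  idx <- dive$i_start:dive$i_end
  stop_if(length(idx) < 3, "dive has fewer than 3 samples")
  d <- depth$depth[idx]
  line <- bottom_frac * dive$max_depth
  over <- which(d > line)
  # the max-depth sample always qualifies (max_depth > frac * max_depth)
  b0 <- min(over); b1 <- max(over)
  phases <- rep("ascent", length(idx))
  phases[seq_len(b0 - 1L)] <- "descent"
  phases[b0:b1] <- "bottom"
  bi <- idx[b0:b1]
  list(phases = phases,
       bottom = data.frame(dive_id = dive$dive_id, i = bi,
                           t = depth$t[bi], depth = depth$depth[bi]))
}

#' Segment a depth record into dives with labelled bottom phases
#'
#' Smooths the record, detects dives, and labels each dive's phases.
#'
#' @param depth A zero-offset-corrected \code{depth_series}.
#' @param config A \code{bottomuse_config}.
#' @return List with \code{dives} (the dive table, plus bottom-span
#'   columns), \code{bottoms} (row-bound bottom-sample frame) and
#'   \code{smoothed} (the smoothed series used).
#' @export
segment_dives <- function(depth, config = bottomuse_config()) {
  sm <- smooth_depth(depth, config$smooth_window)
  dives <- detect_dives(sm, config$dive_threshold)
  # spans too short to carry phases (sub-threshold noise blips) are dropped
  dives <- dives[dives$i_end - dives$i_start >= 2, , drop = FALSE]
  dives$dive_id <- seq_len(nrow(dives))
  if (nrow(dives) == 0)
    return(list(dives = cbind(dives, bottom_start = numeric(),
                              bottom_end = numeric(), bottom_n = integer()),
                bottoms = data.frame(dive_id = integer(), i = integer(),
                                     t = numeric(), depth = numeric()),
                smoothed = sm))
  lab <- lapply(seq_len(nrow(dives)), function(j)
    label_phases(dives[j, ], sm, config$bottom_frac))
  bottoms <- do.call(rbind, lapply(lab, `[[`, "bottom"))
  dives$bottom_start <- vapply(lab, function(l) l$bottom$t[1], 0)
  dives$bottom_end <- vapply(lab, function(l) l$bottom$t[nrow(l$bottom)], 0)
  dives$bottom_n <- vapply(lab, function(l) nrow(l$bottom), 0L)
  list(dives = dives, bottoms = bottoms, smoothed = sm)
}
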