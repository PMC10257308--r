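#' Per-dive bottom-use metrics
#'
#' Computes the seven benthic foraging-effort predictors for one dive's
#' bottom phase from the georeferenced track:
#' \itemize{
#'   \item \code{bottom_time}: total bottom time (s);
#'   \item \code{tad_index}: time-at-depth index, bottom time / maximum
#'     dive depth (s/m);
#'   \item \code{bottom_distance}: distance travelled along the track
#'     within the bottom phase (m);
#'   \item \code{depth_var_index}: depth-variability index, sd of bottom
#'     depths / mean bottom depth (substrate-rugosity proxy);
#'   \item \code{bottom_speed}: mean horizontal bottom speed,
#'     distance/time (m/s);
#'   \item \code{sinuosity}: bottom distance / straight-line distance
#'     between the first and last bottom positions (>= 1; capped when the
#'     path closes on itself);
#'   \item \code{colony_distance}: mean great-circle distance from the
#'     colony over the bottom samples (km).
#' }
#'
#' @param bottom Bottom-sample frame for one dive (\code{dive_id, i, t,
#'   depth}) as produced by \code{\link{segment_dives}}, indices into the
#'   track rows.
#' @param track A \code{geo_track} on the same 1 Hz grid as the depth
#'   record.
#' @param max_depth The dive's maximum depth (m).
#' @param colony \code{c(lat, lon)} of the colony.
#' @param sinuosity_cap Value used when start and end coincide.
#' @return One-row data frame of metrics.
#' @export
compute_dive_metrics <- function(bottom, track, max_depth, colony,
                                 sinuosity_cap = 50) {
  stop_if(nrow(bottom) < 2, "bottom phase needs at least 2 samples")
  idx <- bottom$i
  bottom_time <- bottom$t[nrow(bottom)] - bottom$t[1]
  # step_dist[i] is the distance from sample i-1 to i
  bottom_distance <- sum(track$step_dist[idx[-1]])
  mu <- mean(bottom$depth)
  dvi <- stats::sd(bottom$depth) / mu
  chord <- gc_dist(track$lon[idx[1]], track$lat[idx[1]],
                   track$lon[idx[length(idx)]], track$lat[idx[length(idx)]])
  if (chord < 1e-6) {
    warning(sprintf("dive %d: degenerate bottom chord; sinuosity capped",
                    bottom$dive_id[1]))
    sinuosity <- sinuosity_cap
  } else {
    sinuosity <- min(bottom_distance / chord, sinuosity_cap)
  }
  colony_km <- mean(gc_dist(track$lon[idx], track$lat[idx],
                            colony[2], colony[1])) / 1000
  data.frame(dive_id = bottom$dive_id[1],
             bottom_time = bottom_time,
             tad_index = bottom_time / max_depth,
             bottom_distance = bottom_distance,
             depth_var_index = dvi,
             bottom_speed = bottom_distance / bottom_time,
             sinuosity = sinuosity,
             colony_distance = colony_km)
}

#' Metrics table for all dives of a trip
#'
#' @param segments Output of \code{\link{segment_dives}}.
#' @param track A \code{geo_track} aligned with the segmented depth record.
#' @param config A \code{bottomuse_config} (colony position, sinuosity
#'   cap).
#' @return Data frame, one row per dive with a bottom phase of at least two
#'   samples.
#' @export
dive_metrics_table <- function(segments, track, config = bottomuse_config()) {
  dives <- segments$dives
  rows <- lapply(seq_len(nrow(dives)), function(j) {
    b <- segments$bottoms[segments$bottoms$dive_id == dives$dive_id[j], ,
                          drop = FALSE]
    if (nrow(b) < 2) return(NULL)
    compute_dive_metrics(b, track, dives$max_depth[j],
                         c(config$colony_lat, config$colony_lon),
                         config$sinuosity_cap)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Screen predictors for collinearity
#'
#' Pairwise Pearson correlations are computed; while any pair exceeds
#' \code{r_max} in absolute value (strictly), the member of the
#' worst-offending pair with the larger mean absolute correlation to all
#' other predictors is dropped. Constant columns (undefined correlation)
#' are dropped first with a warning. The rule is deterministic so runs are
#' reproducible.
#'
#' @param metrics Metrics data frame (a \code{dive_id} column, if present,
#'   is ignored).
#' @param r_max Absolute-correlation ceiling (default 0.750, strict
#'   inequality: a pair at exactly \code{r_max} is retained).
#' @return List with \code{retained} (column names), \code{dropped},
#'   and \code{correlation} (the full initial correlation matrix).
#' @export
collinearity_screen <- function(metrics, r_max = 0.750) {
  X <- metrics[, setdiff(names(metrics), "dive_id"), drop = FALSE]
  stop_if(nrow(X) < 3, "need at least 3 rows to estimate correlations")
  stop_if(ncol(X) < 2, "need at least 2 predictor columns")
  const <- vapply(X, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)),
                  TRUE)
  if (any(const)) {
    warning(sprintf("constant column(s) dropped: %s",
                    paste(names(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  full_cor <- stats::cor(X)
  keep <- names(X)
  repeat {
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= r_max) break
    worst <- which(C == max(C), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- colMeans(C)[pair]
    drop_col <- pair[which.max(mean_abs)]        # ties: first of the pair
    keep <- setdiff(keep, drop_col)
    if (length(keep) < 2) break
  }
  list(retained = keep,
       dropped = setdiff(names(const), keep),
       correlation = full_cor)
}
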