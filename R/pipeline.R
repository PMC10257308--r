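#' Run the full bottom-use analysis in memory
#'
#' Executes the processing chain on one trip: per-axis calibration,
#' zero-offset correction of depth, dead-reckoning and georeferencing,
#' dive segmentation with bottom-phase labelling, per-dive metrics, and the
#' iterated clustering / stepwise predictor-selection loop. Clustering is
#' skipped (with a message) when fewer than \code{min_dives} bottom phases
#' are available.
#'
#' @param bundle A \code{sensor_bundle} (raw units if \code{calibration}
#'   is supplied, physical units otherwise).
#' @param config A \code{bottomuse_config}.
#' @param calibration Optional named list of \code{axis_calibration}
#'   (\code{surge, sway, heave, mx, my, mz}).
#' @param min_dives Minimum bottom phases required to attempt clustering.
#' @return List with \code{track}, \code{dr} (dead-reckoning internals),
#'   \code{segments}, \code{metrics}, \code{cluster}, \code{summary},
#'   \code{fixes} and \code{config}.
#' @export
run_trip_analysis <- function(bundle, config = bottomuse_config(),
                              calibration = NULL, min_dives = 10) {
  if (!is.null(calibration)) {
    bundle$accel <- apply_calibration(bundle$accel,
                                      calibration[c("surge", "sway", "heave")])
    bundle$mag <- apply_calibration(bundle$mag,
                                    calibration[c("mx", "my", "mz")])
  }
  bundle$depth <- zero_offset_correct(bundle$depth,
                                      window = config$zoc_window,
                                      quantile = config$zoc_quantile,
                                      surface = config$zoc_surface,
                                      clip = config$zoc_clip)
  dr <- dead_reckon(bundle, config)
  segments <- segment_dives(depth_series(dr$merged$t, dr$merged$depth), config)
  metrics <- dive_metrics_table(segments, dr$track, config)
  cluster <- NULL
  if (nrow(metrics) >= min_dives) {
    cluster <- iterate_cluster_selection(metrics, config)
  } else {
    message(sprintf("only %d bottom phases; clustering skipped", nrow(metrics)))
  }
  summary <- trip_summary(dr$fixes, segments, metrics,
                          solution = cluster$solution,
                          trip_window = bundle$trip_window)
  list(track = dr$track, dr = dr, segments = segments, metrics = metrics,
       cluster = cluster, summary = summary, fixes = dr$fixes,
       config = config)
}

# Mean bottom-phase position per dive (for mapping cluster membership).
bottom_centroids <- function(segments, track) {
  sp <- split(segments$bottoms$i, segments$bottoms$dive_id)
  data.frame(dive_id = as.integer(names(sp)),
             lat = vapply(sp, function(i) mean(track$lat[i]), 0),
             lon = vapply(sp, function(i) mean(track$lon[i]), 0))
}

# CSV with provenance comment lines (read back with comment.char = "#").
write_artifact_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", names(config), "=",
                   vapply(config, function(v) format(v, digits = 15), "")),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export a track and clustered bottom phases as GeoJSON
#'
#' One LineString feature for the georeferenced track and one Point
#' feature per bottom-phase centroid carrying \code{dive_id},
#' \code{cluster} and \code{bottom_time} properties.
#'
#' @param track A \code{geo_track}.
#' @param centroids Data frame \code{dive_id, lat, lon} (may have zero
#'   rows).
#' @param metrics Dive-metrics table (for \code{bottom_time}).
#' @param assignments Cluster labels aligned with \code{metrics} rows, or
#'   NULL.
#' @param path Output file; when NULL the GeoJSON list is returned
#'   unserialised.
#' @return The GeoJSON structure (invisibly when written to file).
#' @export
export_geojson <- function(track, centroids, metrics, assignments = NULL,
                           path = NULL) {
  line <- list(type = "Feature",
               properties = list(kind = "geo_track", n = nrow(track)),
               geometry = list(type = "LineString",
                               coordinates = lapply(seq_len(nrow(track)),
                                 function(i) c(track$lon[i], track$lat[i]))))
  pts <- list()
  if (nrow(centroids) > 0) {
    m <- match(centroids$dive_id, metrics$dive_id)
    for (j in seq_len(nrow(centroids))) {
      if (is.na(m[j])) next
      pts[[length(pts) + 1]] <- list(
        type = "Feature",
        properties = list(dive_id = centroids$dive_id[j],
                          cluster = if (is.null(assignments)) NA
                                    else assignments[m[j]],
                          bottom_time = metrics$bottom_time[m[j]]),
        geometry = list(type = "Point",
                        coordinates = c(centroids$lon[j], centroids$lat[j])))
    }
  }
  gj <- list(type = "FeatureCollection", features = c(list(line), pts))
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(gj))
  }
  gj
}

#' Run the pipeline from files on disk and write all artifacts
#'
#' Reads the four sensor CSVs (and a calibration file when present), runs
#' \code{\link{run_trip_analysis}}, and writes: the georeferenced track
#' (CSV + GeoJSON), dive table, metrics and correlation matrix, cluster
#' assignments with per-dive silhouette widths, a solution JSON (k,
#' centroids, sizes, silhouette curve, stepwise history), a summary JSON,
#' the echoed configuration, and a MANIFEST. Every artifact embeds the full
#' parameter set for provenance. If a stage fails, the MANIFEST names the
#' failing stage and the partial artifacts are kept.
#'
#' @param input_dir Directory holding \code{accel.csv, mag.csv, depth.csv,
#'   fixes.csv} and optionally \code{calibration.csv}.
#' @param out_dir Output directory (created).
#' @param config A \code{bottomuse_config}.
#' @return Invisibly, the analysis list.
#' @export
run_pipeline <- function(input_dir, out_dir, config = bottomuse_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  stage <- "ingest"
  res <- tryCatch({
    paths <- list(accel = file.path(input_dir, "accel.csv"),
                  mag = file.path(input_dir, "mag.csv"),
                  depth = file.path(input_dir, "depth.csv"),
                  fixes = file.path(input_dir, "fixes.csv"))
    for (p in paths) stop_if(!file.exists(p), sprintf("missing input %s", p))
    bundle <- read_sensor_bundle(paths, config)
    cal_path <- file.path(input_dir, "calibration.csv")
    calibration <- if (file.exists(cal_path)) read_calibration(cal_path)
                   else NULL
    stage <- "analysis"
    analysis <- run_trip_analysis(bundle, config, calibration)
    stage <- "export"
    write_artifact_csv(as.data.frame(analysis$track),
                       file.path(out_dir, "geotrack.csv"), config)
    write_artifact_csv(analysis$segments$dives[,
        c("dive_id", "t_start", "t_end", "max_depth",
          "bottom_start", "bottom_end", "bottom_n")],
        file.path(out_dir, "dives.csv"), config)
    write_artifact_csv(analysis$metrics, file.path(out_dir, "metrics.csv"),
                       config)
    cents <- bottom_centroids(analysis$segments, analysis$track)
    assignments <- NULL
    if (!is.null(analysis$cluster)) {
      sol <- analysis$cluster$solution
      assignments <- sol$assignments
      write_artifact_csv(
        data.frame(dive_id = analysis$metrics$dive_id,
                   cluster = sol$assignments,
                   silhouette = sol$sil_widths),
        file.path(out_dir, "assignments.csv"), config)
      write_artifact_csv(as.data.frame(analysis$cluster$screen$correlation),
                         file.path(out_dir, "correlation.csv"), config)
      sw <- analysis$cluster$stepwise
      jsonlite::write_json(list(
        config = unclass(config),
        k = sol$k, sizes = sol$sizes,
        centroids = as.data.frame(sol$centroids),
        avg_silhouette = sol$avg_silhouette,
        silhouette_curve = analysis$cluster$sil_curve,
        retained = analysis$cluster$columns,
        stepwise = if (is.null(sw)) NULL else
          list(retained = sw$retained, p_values = as.list(sw$p_values),
               adj_r2 = sw$adj_r2, history = sw$history)),
        file.path(out_dir, "solution.json"), auto_unbox = TRUE, digits = NA)
    }
    export_geojson(analysis$track, cents, analysis$metrics, assignments,
                   file.path(out_dir, "geotrack.geojson"))
    jsonlite::write_json(c(list(config = unclass(config)),
                           lapply(unclass(analysis$summary), function(x)
                             if (is.matrix(x)) as.data.frame(x) else x)),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.txt"))
    writeLines(c("status: ok",
                 paste("artifact:", list.files(out_dir))), manifest)
    analysis
  }, error = function(e) {
    writeLines(c("status: failed", paste("stage:", stage),
                 paste("error:", conditionMessage(e))), manifest)
    stop(e)
  })
  invisible(res)
}
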