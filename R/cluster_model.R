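# Run code under a temporary RNG state so library calls stay reproducible
# without clobbering the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Standardise a metrics table to z-scores
#'
#' Column-wise (x - mean) / sd, with the means and sds stored so centroids
#' can be mapped back to physical units.
#'
#' @param metrics Data frame of numeric predictors (a \code{dive_id} column
#'   is dropped).
#' @return Matrix of z-scores with attributes \code{center} and
#'   \code{scale}.
#' @export
zscore <- function(metrics) {
  X <- as.matrix(metrics[, setdiff(colnames(metrics), "dive_id"), drop = FALSE])
  stop_if(nrow(X) < 2, "need at least 2 rows")
  sds <- apply(X, 2, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  stop_if(any(bad), sprintf("constant column(s): %s",
                            paste(colnames(X)[bad], collapse = ", ")))
  scale(X)
}

#' Hartigan-Wong k-means with seeded restarts
#'
#' Thin, reproducible wrapper around the Hartigan-Wong algorithm of
#' \code{stats::kmeans}: the best of \code{n_restarts} random starts by
#' total within-cluster sum of squares, under a local seed, augmented with
#' per-point silhouette widths.
#'
#' @param X Numeric matrix (rows = dives, columns = z-scored predictors).
#' @param k Number of clusters.
#' @param n_restarts Random restarts.
#' @param seed Integer seed.
#' @return A \code{cluster_solution}: \code{k}, \code{assignments},
#'   \code{centroids}, \code{wcss}, \code{bcss}, \code{totss},
#'   \code{sizes}, \code{sil_widths}, \code{avg_silhouette}.
#' @export
kmeans_cluster <- function(X, k, n_restarts = 25, seed = 1L) {
  X <- as.matrix(X)
  stop_if(k < 1, "k must be >= 1")
  stop_if(nrow(unique(X)) < k, "k exceeds the number of distinct rows")
  km <- with_seed(seed,
                  stats::kmeans(X, centers = k, nstart = n_restarts,
                                iter.max = 100, algorithm = "Hartigan-Wong"))
  sw <- if (k >= 2) silhouette_widths(X, km$cluster) else rep(NA_real_, nrow(X))
  structure(list(k = k,
                 assignments = km$cluster,
                 centroids = km$centers,
                 wcss = km$tot.withinss,
                 bcss = km$betweenss,
                 totss = km$totss,
                 sizes = km$size,
                 sil_widths = sw,
                 avg_silhouette = if (k >= 2) mean(sw) else NA_real_),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, sizes = %s\n", x$k,
              paste(x$sizes, collapse = "/")))
  cat(sprintf("  WCSS %.3f | BCSS %.3f | avg silhouette %.3f\n",
              x$wcss, x$bcss, x$avg_silhouette))
  invisible(x)
}

#' Per-point silhouette widths
#'
#' For point i with mean within-cluster distance a(i) (excluding itself)
#' and smallest mean distance to another cluster b(i), the silhouette is
#' (b - a) / max(a, b), in [-1, 1]; singletons score 0. Euclidean distance.
#'
#' @param X Numeric matrix.
#' @param assignments Integer cluster labels.
#' @return Numeric vector of widths.
#' @export
silhouette_widths <- function(X, assignments) {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if(length(assignments) != n, "assignments length mismatch")
  d <- as.matrix(stats::dist(X))
  cl <- as.integer(factor(assignments))
  k <- max(cl)
  if (k < 2) return(rep(0, n))
  Z <- outer(cl, seq_len(k), `==`) * 1
  counts <- colSums(Z)
  S <- d %*% Z                                  # total distance to each cluster
  own <- cbind(seq_len(n), cl)
  a <- ifelse(counts[cl] > 1, S[own] / (counts[cl] - 1), NA)
  Sm <- sweep(S, 2, counts, `/`)
  Sm[own] <- Inf
  b <- apply(Sm, 1, min)
  s <- ifelse(counts[cl] == 1, 0,
              ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b)))
  as.numeric(s)
}

#' Select the number of clusters by average silhouette width
#'
#' Fits seeded k-means for each k in \code{k_min:k_max} and returns the k
#' maximising the average silhouette width; ties break toward smaller k
#' (parsimony).
#'
#' @param X z-scored matrix.
#' @param k_min,k_max Search range (k_max is truncated to n - 1).
#' @param n_restarts,seed Passed to \code{\link{kmeans_cluster}}.
#' @return List with \code{k} (the selection), \code{curve} (data frame of
#'   k and average width, for plotting) and \code{solution} (the selected
#'   \code{cluster_solution}).
#' @export
silhouette_select <- function(X, k_min = 2, k_max = 8, n_restarts = 25,
                              seed = 1L) {
  X <- as.matrix(X)
  k_max <- min(k_max, nrow(unique(X)) - 1L)
  stop_if(k_max < k_min, "k range empty for this data size")
  ks <- k_min:k_max
  sols <- lapply(ks, function(k) kmeans_cluster(X, k, n_restarts, seed + k))
  widths <- vapply(sols, `[[`, 0, "avg_silhouette")
  best <- which.max(widths)                     # first max: smaller k wins ties
  list(k = ks[best],
       curve = data.frame(k = ks, avg_width = widths),
       solution = sols[[best]])
}

#' Backwards stepwise predictor selection against cluster membership
#'
#' Regresses the binary cluster indicator (0/1) on the z-scored predictors
#' by least squares and iteratively removes the single least-significant
#' term with p > \code{alpha}, refitting until every remaining term is
#' significant. Reports per-term p-values and the adjusted R-squared of the
#' final fit. Only defined for two clusters.
#'
#' @param X z-scored predictor matrix.
#' @param assignments Cluster labels with exactly two levels.
#' @param alpha Removal threshold (default 0.05).
#' @return A \code{stepwise_result}: \code{retained}, \code{p_values},
#'   \code{adj_r2}, \code{history} (data frame of iteration, dropped term
#'   and its p-value).
#' @export
stepwise_select <- function(X, assignments, alpha = 0.05) {
  X <- as.matrix(X)
  lev <- sort(unique(assignments))
  stop_if(length(lev) != 2, "stepwise selection requires exactly 2 clusters")
  stop_if(nrow(X) <= ncol(X) + 2, "too few rows for the number of predictors")
  y <- as.integer(assignments == lev[2])
  vars <- colnames(X)
  history <- data.frame(iteration = integer(), dropped = character(),
                        p_value = numeric())
  it <- 0L
  repeat {
    if (length(vars) == 0) {
      warning("all terms removed; empty model")
      return(structure(list(retained = character(0),
                            p_values = numeric(0), adj_r2 = NA_real_,
                            history = history), class = "stepwise_result"))
    }
    df <- data.frame(y = y, X[, vars, drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    coefs <- summary(fit)$coefficients
    p <- coefs[setdiff(rownames(coefs), "(Intercept)"), 4]
    names(p) <- setdiff(rownames(coefs), "(Intercept)")
    if (max(p) <= alpha) {
      return(structure(list(retained = vars, p_values = p,
                            adj_r2 = summary(fit)$adj.r.squared,
                            history = history), class = "stepwise_result"))
    }
    it <- it + 1L
    worst <- names(p)[which.max(p)]
    history <- rbind(history, data.frame(iteration = it, dropped = worst,
                                         p_value = unname(max(p))))
    vars <- setdiff(vars, worst)
  }
}

#' Iterated clustering and predictor selection
#'
#' The decision loop of the bottom-use analysis: screen predictors for
#' collinearity, then repeat \{z-score, silhouette-based k selection,
#' k-means, backwards stepwise selection\}; any predictor dropped by the
#' stepwise step is removed and the loop re-runs on the reduced set, until
#' the retained set is stable (the most parsimonious model). The column set
#' strictly shrinks, so the loop terminates within one pass per predictor.
#' Stepwise selection is only defined for two clusters; when silhouette
#' selection prefers a different k on the first pass, the loop stops there
#' and reports that clustering without a stepwise refinement. When it
#' happens on a later pass (re-selection on a pruned predictor set drifting
#' away from two clusters), the most recent coherent two-cluster iteration
#' — its clustering, predictor columns and stepwise model — is returned,
#' with a message.
#'
#' @param metrics Dive-metrics data frame (with optional \code{dive_id}).
#' @param config A \code{bottomuse_config}.
#' @return List with \code{solution} (final \code{cluster_solution}),
#'   \code{stepwise} (final \code{stepwise_result} or NULL), \code{columns}
#'   (retained predictors), \code{screen} (collinearity report),
#'   \code{sil_curve}, and \code{iterations}.
#' @export
iterate_cluster_selection <- function(metrics, config = bottomuse_config()) {
  screen <- collinearity_screen(metrics, config$r_max)
  cols <- screen$retained
  iterations <- 0L
  last_k2 <- NULL
  repeat {
    iterations <- iterations + 1L
    Z <- zscore(metrics[, cols, drop = FALSE])
    sel <- silhouette_select(Z, config$k_min, config$k_max,
                             config$n_restarts, config$seed)
    sol <- sel$solution
    cur <- list(solution = sol, stepwise = NULL, columns = cols,
                screen = screen, sil_curve = sel$curve,
                iterations = iterations)
    if (sol$k != 2) {
      message(sprintf("silhouette selected k = %d; stepwise refinement %s",
                      sol$k,
                      if (is.null(last_k2)) "not applicable"
                      else "stopped; returning the last two-cluster solution"))
      return(if (is.null(last_k2)) cur else last_k2)
    }
    sw <- stepwise_select(Z, sol$assignments, config$alpha)
    cur$stepwise <- sw
    last_k2 <- cur
    if (setequal(sw$retained, cols)) return(cur)
    if (length(sw$retained) < 2) {
      warning("fewer than 2 predictors retained; returning last valid solution")
      return(cur)
    }
    cols <- sw$retained
  }
}

#' Percentage of bottom phases per cluster
#'
#' @param sizes Integer vector of cluster sizes.
#' @return Percentages summing to ~100, rounded to 2 decimal places.
#' @export
cluster_percentages <- function(sizes) round(100 * sizes / sum(sizes), 2)

#' Mean location acquisition rate
#'
#' @param n_locations Fix count(s).
#' @param duration_h Trip duration(s) in hours.
#' @return Locations per hour, rounded to 2 decimal places.
#' @export
location_frequency <- function(n_locations, duration_h)
  round(n_locations / duration_h, 2)

#' Pooled mean interval between fixes, in minutes
#'
#' @param n_locations Per-trip fix counts.
#' @param duration_h Per-trip durations (hours).
#' @return Pooled mean minutes between fixes across the trips.
#' @export
mean_fix_interval_min <- function(n_locations, duration_h)
  sum(duration_h) * 60 / sum(n_locations)

#' Per-trip summary of locations, dives and clusters
#'
#' Condenses one animal's processed trip into the quantities reported in
#' deployment summaries: location counts and rates, bottom-phase counts,
#' mean and sd of bottom time, dive time and bottom depth, maximum depth,
#' and (when a clustering is supplied) per-cluster sizes, percentages (2
#' dp) and standardised centroid means (3 dp).
#'
#' @param fixes Retained \code{fix_series}.
#' @param segments Output of \code{\link{segment_dives}}.
#' @param metrics Dive-metrics table.
#' @param solution Optional \code{cluster_solution}.
#' @param trip_window Optional \code{c(t0, t1)}; defaults to the depth
#'   record span.
#' @return List of class \code{trip_summary}.
#' @export
trip_summary <- function(fixes, segments, metrics, solution = NULL,
                         trip_window = NULL) {
  if (is.null(trip_window))
    trip_window <- range(segments$smoothed$t)
  duration_h <- diff(trip_window) / 3600
  dives <- segments$dives
  dive_time <- dives$t_end - dives$t_start
  mean_bottom_depth <- vapply(split(segments$bottoms$depth,
                                    segments$bottoms$dive_id), mean, 0)
  out <- list(
    n_locations = nrow(fixes),
    trip_duration_h = duration_h,
    location_frequency = location_frequency(nrow(fixes), duration_h),
    n_bottom_phases = nrow(metrics),
    bottom_time_mean = mean(metrics$bottom_time),
    bottom_time_sd = stats::sd(metrics$bottom_time),
    dive_time_mean = mean(dive_time),
    dive_time_sd = stats::sd(dive_time),
    bottom_depth_mean = mean(mean_bottom_depth),
    bottom_depth_sd = stats::sd(mean_bottom_depth),
    max_depth = max(dives$max_depth))
  if (!is.null(solution)) {
    out$cluster_sizes <- solution$sizes
    out$cluster_percent <- cluster_percentages(solution$sizes)
    out$centroids <- round(solution$centroids, 3)
  }
  structure(out, class = "trip_summary")
}

#' @export
print.trip_summary <- function(x, ...) {
  cat(sprintf("locations: %d (%.2f h trip, %.2f h^-1)\n",
              x$n_locations, x$trip_duration_h, x$location_frequency))
  cat(sprintf("bottom phases: %d | bottom time %.0f +/- %.0f s | max depth %.1f m\n",
              x$n_bottom_phases, x$bottom_time_mean, x$bottom_time_sd,
              x$max_depth))
  if (!is.null(x$cluster_sizes))
    cat(sprintf("clusters: %s (%s%%)\n",
                paste(x$cluster_sizes, collapse = "/"),
                paste(sprintf("%.2f", x$cluster_percent), collapse = "/")))
  invisible(x)
}
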