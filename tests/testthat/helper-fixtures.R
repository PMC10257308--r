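# Shared fixtures and independent oracles, built in code at test time.

M_DEG <- pi / 180 * 6378137   # metres per degree latitude on the test sphere

# Independent haversine oracle (kept separate from the package's geosphere
# route so distance-based checks have two code paths).
haversine_oracle <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(sqrt(a))
}

# Independent z-y-x rotation oracle: full 3x3 matrices, no shared code with
# the package's vectorised ned_to_device().
rot_oracle <- function(yaw, pitch, roll) {
  Rz <- matrix(c(cos(yaw), -sin(yaw), 0, sin(yaw), cos(yaw), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(pitch), 0, sin(pitch), 0, 1, 0,
                 -sin(pitch), 0, cos(pitch)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(roll), -sin(roll),
                 0, sin(roll), cos(roll)), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

to_device_oracle <- function(v, yaw, pitch, roll)
  as.numeric(t(rot_oracle(yaw, pitch, roll)) %*% v)

# Brute-force silhouette from the definition: explicit loops, no matrix
# algebra shared with silhouette_widths().
silhouette_brute <- function(X, cl) {
  X <- as.matrix(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(sqrt(rowSums((X[own, , drop = FALSE] -
                            matrix(X[i, ], length(own), ncol(X),
                                   byrow = TRUE))^2)))
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      oth <- which(cl == g)
      b <- min(b, mean(sqrt(rowSums((X[oth, , drop = FALSE] -
                              matrix(X[i, ], length(oth), ncol(X),
                                     byrow = TRUE))^2))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# Trapezoid dive depth record: descent/ascent at `rate` m/s, plateau at
# `depth` m for `plateau` s, flanked by `surface` s of zero depth.
trapezoid_depth <- function(depth = 50, rate = 1, plateau = 120,
                            surface = 120) {
  ramp <- seq(rate, depth, by = rate)
  d <- c(rep(0, surface), ramp, rep(depth, plateau), rev(ramp),
         rep(0, surface))
  depth_series(seq_along(d) - 1, d)
}

# Straight-line 1 Hz geo track heading east at `speed` m/s.
straight_track <- function(n, lat0 = -36, lon0 = 137, speed = 2) {
  lon <- lon0 + (seq_len(n) - 1) * speed / (M_DEG * cos(lat0 * pi / 180))
  lat <- rep(lat0, n)
  step <- c(0, haversine_oracle(lon[-n], lat[-n], lon[-1], lat[-1]))
  structure(data.frame(t = seq_len(n) - 1, lat = lat, lon = lon,
                       depth = 50, step_dist = step),
            class = c("geo_track", "data.frame"))
}

# Directly generated two-mode metrics table where each informative
# predictor carries its own independent archetype channel (the premise of
# the decision-loop recovery checks), plus two pure-noise predictors.
make_archetype_metrics <- function(n = 500, d = 3, seed = 1) {
  withr::with_seed(seed, {
    type <- rbinom(n, 1, 0.5)
    inf <- function(mu0, sd0) mu0 + type * d * sd0 + rnorm(n, 0, sd0)
    list(metrics = data.frame(
           bottom_time = inf(90, 30),
           tad_index = inf(2, 0.6),
           bottom_distance = inf(120, 40),
           depth_var_index = inf(0.04, 0.012),
           bottom_speed = rnorm(n, 1, 0.3),
           colony_distance = rnorm(n, 6, 2)),
         type = type + 1L)
  })
}
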