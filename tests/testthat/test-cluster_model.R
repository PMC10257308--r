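test_that("z-scoring centres and scales every column and is idempotent", {
  set.seed(6)
  m <- data.frame(a = rnorm(50, 10, 3), b = runif(50), dive_id = 1:50)
  Z <- zscore(m)
  expect_equal(colnames(Z), c("a", "b"))
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-9))
  Z2 <- zscore(as.data.frame(Z))
  expect_equal(unname(Z2[, ]), unname(Z[, ]), tolerance = 1e-12)
  expect_error(zscore(data.frame(a = rnorm(10), b = rep(1, 10))), "b")
})

test_that("k-means solutions satisfy the sum-of-squares identity", {
  set.seed(10)
  X <- matrix(rnorm(200 * 3), 200, 3)
  one <- kmeans_cluster(X, 1, 5, 1)
  expect_equal(one$wcss, one$totss, tolerance = 1e-9)
  for (k in c(2, 4)) {
    s <- kmeans_cluster(X, k, 10, 2)
    expect_equal(s$wcss + s$bcss, s$totss, tolerance = 1e-6 * s$totss)
    expect_equal(sum(s$sizes), 200)
  }
})

test_that("k-means separates distant blobs and is seed-deterministic", {
  set.seed(20)
  X <- rbind(matrix(rnorm(100 * 2), 100, 2),
             matrix(rnorm(100 * 2, mean = 10), 100, 2))
  truth <- rep(1:2, each = 100)
  s1 <- kmeans_cluster(X, 2, 25, 99)
  agree <- max(mean(s1$assignments == truth),
               mean(s1$assignments == 3 - truth))
  expect_equal(agree, 1)
  s2 <- kmeans_cluster(X, 2, 25, 99)
  expect_identical(s1$assignments, s2$assignments)
  expect_error(kmeans_cluster(matrix(1, 4, 2), 2), "distinct")
})

test_that("silhouette widths match brute force and perfect clusters score 1", {
  X <- matrix(c(0, 0, 10, 10), 4, 1)
  cl <- c(1, 1, 2, 2)
  expect_equal(silhouette_widths(X, cl), rep(1, 4))
  expect_equal(mean(silhouette_widths(X, cl)), 1)
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    p <- sample(1:3, 1)
    Y <- matrix(rnorm(n * p), n, p)
    k <- sample(2:3, 1)
    cl <- sample(k, n, replace = TRUE)
    if (length(unique(cl)) < 2) next
    expect_equal(silhouette_widths(Y, cl), silhouette_brute(Y, cl),
                 tolerance = 1e-12)
  }
})

test_that("silhouette selection finds the true number of blobs", {
  set.seed(40)
  blobs <- rbind(matrix(rnorm(60 * 2, 0), 60, 2),
                 matrix(rnorm(60 * 2, 12), 60, 2),
                 matrix(rnorm(60 * 2, c(24, 0)), 60, 2))
  sel <- silhouette_select(blobs, 2, 6, 10, 7)
  expect_equal(sel$k, 3)
  expect_true(all(sel$curve$avg_width >= -1 & sel$curve$avg_width <= 1))
  # four nearly-duplicated points: 2 clusters beat 3
  pts <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  sel2 <- silhouette_select(pts, 2, 3, 10, 7)
  expect_equal(sel2$k, 2)
})

test_that("stepwise keeps an informative predictor and rejects pure noise", {
  set.seed(50)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  X <- cbind(signal = y + rnorm(n, 0, 0.03), noise = rnorm(n))
  out <- stepwise_select(X, y + 1, alpha = 0.05)
  expect_equal(out$retained, "signal")
  expect_lt(out$p_values[["signal"]], 1e-10)
  expect_equal(out$history$dropped, "noise")
  expect_gt(out$adj_r2, 0.99)
})

test_that("stepwise type-I behaviour: pure-noise predictors usually all removed", {
  empty <- 0
  for (i in 1:100) {
    set.seed(1000 + i)
    n <- 300
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(NULL, paste0("n", 1:2)))
    out <- suppressWarnings(stepwise_select(X, y + 1, alpha = 0.05))
    if (length(out$retained) == 0) empty <- empty + 1
  }
  expect_gte(empty, 90)
})

test_that("decision loop retains independent informative terms and recovers the modes", {
  sim <- make_archetype_metrics(n = 500, d = 3, seed = 17)
  cfg <- bottomuse_config(seed = 17)
  res <- iterate_cluster_selection(sim$metrics, cfg)
  expect_equal(res$solution$k, 2)
  expect_setequal(res$columns, c("bottom_time", "tad_index",
                                 "bottom_distance", "depth_var_index"))
  agree <- max(mean(res$solution$assignments == sim$type),
               mean(res$solution$assignments == 3 - sim$type))
  expect_gte(agree, 0.95)
  expect_true(all(res$stepwise$p_values <= 0.05))
  # a second pass on the already-final set is a fixed point
  res2 <- iterate_cluster_selection(sim$metrics[, res$columns], cfg)
  expect_setequal(res2$columns, res$columns)
  expect_lte(res$iterations, 7)
})

test_that("centroids in z-space average to zero with size weights", {
  sim <- make_archetype_metrics(n = 200, d = 3, seed = 23)
  Z <- zscore(sim$metrics)
  s <- kmeans_cluster(Z, 3, 10, 5)
  wsum <- colSums(s$centroids * s$sizes)
  expect_true(all(abs(wsum) < 1e-6))
})

test_that("summary arithmetic reproduces percentages and rates", {
  expect_equal(cluster_percentages(c(237, 283)), c(45.58, 54.42))
  expect_equal(cluster_percentages(c(427, 248)), c(63.26, 36.74))
  expect_equal(cluster_percentages(c(271, 243)), c(52.72, 47.28))
  expect_equal(cluster_percentages(c(100, 100)), c(50, 50))
  expect_equal(location_frequency(343, 85 + 18 / 60), 4.02)
  expect_equal(round(mean_fix_interval_min(
    c(253, 343, 335),
    c(47 + 23 / 60, 85 + 18 / 60, 56 + 44 / 60))), 12)
})

test_that("trip summary collects location and dive statistics", {
  trip <- simulate_trip(trip_config(duration_h = 1.5, seed = 19))
  an <- suppressWarnings(suppressMessages(
    run_trip_analysis(trip$bundle, bottomuse_config(seed = 19),
                      trip$calibration, min_dives = Inf)))
  s <- an$summary
  expect_equal(s$n_locations, nrow(an$fixes))
  expect_equal(s$n_bottom_phases, nrow(an$metrics))
  expect_equal(s$location_frequency,
               round(s$n_locations / s$trip_duration_h, 2))
  expect_gt(s$max_depth, 20)
})
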