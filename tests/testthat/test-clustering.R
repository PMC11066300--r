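# Cluster analysis: input assembly, DBSCAN, Voronoi, NASTIC, metrics.

test_that("cluster inputs expose the requested point sets", {
  tracks <- data.frame(track_id = rep(1:2, each = 2), frame = rep(1:2, 2),
                       x_nm = c(0, 100, 1000, 1100), y_nm = c(0, 0, 500, 500))
  ci <- make_cluster_input(tracks = tracks, mode = "centroids")
  expect_identical(nrow(ci$points), 2L)
  expect_equal(ci$points$x_nm, c(50, 1050), tolerance = 1e-12)
  expect_equal(ci$points$y_nm[1], 0, tolerance = 1e-12)
  locs <- as_locs(rep(1L, 5), runif(5, 0, 1000), runif(5, 0, 1000))
  expect_identical(nrow(make_cluster_input(locs = locs, mode = "locs")$points), 5L)
  expect_error(make_cluster_input(locs = locs, mode = "tracks"), "requires tracks")
  ti <- make_cluster_input(tracks = tracks, mode = "tracks")
  expect_error(cluster_dbscan(ti), "point-mode")
})

test_that("DBSCAN handles trivial configurations", {
  # fewer points than min_pts: all noise
  few <- cbind(rep(0, 3), rep(0, 3))
  r <- cluster_dbscan(few, 50, 5)
  expect_identical(r$n_clusters, 0L)
  expect_identical(length(r$noise_ids), 3L)
  # coincident points: one cluster of n
  co <- cbind(rep(10, 7), rep(20, 7))
  r2 <- cluster_dbscan(co, 50, 5)
  expect_identical(r2$n_clusters, 1L)
  expect_identical(r2$clustered_fraction, 1)
})

test_that("DBSCAN equals the queue-expansion oracle across a parameter grid", {
  set.seed(80)
  for (rep in 1:10) {
    xy <- cbind(runif(200, 0, 2000), runif(200, 0, 2000))
    for (eps in c(60, 120)) for (mp in c(3L, 5L)) {
      got <- cluster_dbscan(xy, eps, mp)
      want <- dbscan_oracle(xy, eps, mp)
      expect_true(same_partition(got$labels, want),
                  label = sprintf("dbscan oracle rep=%d eps=%g min_pts=%d", rep, eps, mp))
    }
  }
})

test_that("partition and scale equivariance hold for DBSCAN", {
  set.seed(81)
  xy <- cbind(runif(300, 0, 3000), runif(300, 0, 3000))
  r <- cluster_dbscan(xy, 100, 4)
  expect_identical(sort(c(which(r$labels > 0), r$noise_ids)), seq_len(300))
  r_scaled <- cluster_dbscan(xy * 3, 300, 4)
  expect_identical(r_scaled$labels, r$labels)
})

test_that("uniform grids yield no Voronoi clusters and degenerate input errors", {
  g <- expand.grid(x = seq(100, 1000, 100), y = seq(100, 1000, 100))
  r <- cluster_voronoi(cbind(g$x, g$y), density_factor = 2, min_pts = 5)
  expect_identical(r$n_clusters, 0L)
  expect_error(cluster_voronoi(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(cluster_voronoi(cbind(1:3, c(1, 5, 2))), "at least 4")
})

test_that("Voronoi clustering recovers planted Thomas clusters", {
  th <- gen_thomas_points(seed = 82)
  r <- cluster_voronoi(th$xy, density_factor = 2, min_pts = 5)
  expect_gte(r$n_clusters, 18L)
  expect_lte(r$n_clusters, 22L)
  # clustered points are overwhelmingly true cluster members
  expect_gt(mean(!is.na(th$parent[r$labels > 0])), 0.95)
})

test_that("Voronoi control: complete spatial randomness seeds almost nothing", {
  counts <- vapply(1:20, function(s) {
    set.seed(500 + s)
    cluster_voronoi(cbind(runif(660, 0, 5000), runif(660, 0, 5000)), 2, 5)$n_clusters
  }, 0L)
  expect_lte(median(counts), 1)
})

test_that("Voronoi areas scale with the square of coordinates", {
  set.seed(83)
  xy <- cbind(runif(100, 0, 2000), runif(100, 0, 2000))
  r1 <- cluster_voronoi(xy, 2, 5)
  r2 <- cluster_voronoi(xy * 2, 2, 5)
  expect_identical(r1$labels, r2$labels)
  expect_equal(r2$cell_area_nm2, 4 * r1$cell_area_nm2, tolerance = 1e-9)
})

test_that("NASTIC groups overlapping boxes and matches the all-pairs oracle", {
  # identical bounding boxes: one cluster of 2
  t2 <- data.frame(track_id = rep(1:2, each = 2), frame = rep(1:2, 2),
                   x_nm = c(0, 100, 0, 100), y_nm = c(0, 100, 0, 100))
  r <- cluster_nastic(t2, min_tracks = 2L)
  expect_identical(r$n_clusters, 1L)
  # far-separated tracks: all noise
  t2$x_nm[3:4] <- t2$x_nm[3:4] + 1e6
  r2 <- cluster_nastic(t2, min_tracks = 2L)
  expect_identical(r2$n_clusters, 0L)
  expect_identical(length(r2$noise_ids), 2L)
  # random track sets: component structure equals the all-pairs oracle
  set.seed(84)
  for (rep in 1:10) {
    nt <- 40
    tracks <- do.call(rbind, lapply(seq_len(nt), function(i) {
      cx <- runif(1, 0, 6000); cy <- runif(1, 0, 6000)
      data.frame(track_id = i, frame = 1:6,
                 x_nm = cx + cumsum(rnorm(6, 0, 80)),
                 y_nm = cy + cumsum(rnorm(6, 0, 80)))
    }))
    got <- cluster_nastic(tracks, 1.2, 3L)
    want <- nastic_oracle(tracks, 1.2, 3L)
    expect_true(same_partition(got$labels, want),
                label = sprintf("nastic oracle rep=%d", rep))
  }
})

test_that("NASTIC resolves planted hotspots from confined tracks", {
  cfg <- simulation_config(field_px = c(128, 128), n_frames = 40, n_molecules = 70,
                           populations = data.frame(fraction = 1, D_um2_per_s = 0.05),
                           spatial_layout = "thomas", thomas_n_parents = 5L,
                           thomas_sigma_nm = 50, thomas_background_fraction = 20 / 70,
                           confined_layout = TRUE, confined_radius_nm = 150,
                           rng_seed = 85)
  gt <- simulate_trajectories(cfg)
  tracks <- do.call(rbind, lapply(1:70, function(i)
    data.frame(track_id = i, frame = 1:11, x_nm = gt$X[i, 1:11], y_nm = gt$Y[i, 1:11])))
  res <- cluster_nastic(tracks, 1.2, 3L)
  confined <- !is.na(gt$molecules$parent_cluster)
  expect_identical(res$n_clusters, 5L)
  expect_gte(mean(res$labels[confined] > 0), 0.95)
  # temporal gating with a huge window changes nothing
  res_t <- cluster_nastic(tracks, 1.2, 3L, temporal_window_s = 1e6,
                          frame_interval_s = 0.05)
  expect_identical(res_t$labels, res$labels)
  # a zero window still links concurrent tracks
  res_0 <- cluster_nastic(tracks, 1.2, 3L, temporal_window_s = 0,
                          frame_interval_s = 0.05)
  expect_identical(res_0$labels, res$labels)
})

test_that("cluster metrics compute exact hull areas and are deterministic", {
  # right triangle with 100 nm legs: area 5000 nm^2 = 5e-6 um^2
  pts <- rbind(c(0, 0), c(100, 0), c(0, 100), c(10, 10), c(20, 5), c(30, 30))
  r <- cluster_dbscan(pts, 200, 3)
  met <- cluster_metrics(r)
  expect_identical(met$summary$n_clusters, 1L)
  expect_equal(met$clusters$area_um2, 5000 / 1e6, tolerance = 1e-12)
  expect_equal(met$clusters$diameter_nm, 2 * sqrt(5000 / pi), tolerance = 1e-9)
  # two points: degenerate, zero area and diameter
  r2 <- cluster_dbscan(rbind(c(0, 0), c(10, 0)), 50, 2)
  met2 <- cluster_metrics(r2)
  expect_identical(met2$clusters$area_um2, 0)
  expect_identical(met2$clusters$diameter_nm, 0)
  expect_true(met2$clusters$degenerate)
  # determinism
  expect_identical(cluster_metrics(r), met)
})

test_that("cluster results serialize to CSV plus JSON sidecar", {
  set.seed(86)
  th <- gen_thomas_points(seed = 86, n_parents = 3L, pts_per_parent = 20L,
                          n_background = 10L, field_nm = 3000)
  r <- cluster_dbscan(th$xy, 120, 5)
  stem <- file.path(withr::local_tempdir(), "clus")
  write_cluster_result(r, stem)
  members <- read.csv(paste0(stem, "_members.csv"))
  expect_identical(nrow(members), nrow(th$xy))
  sidecar <- jsonlite::read_json(paste0(stem, "_params.json"), simplifyVector = TRUE)
  expect_identical(sidecar$algorithm, "dbscan")
  expect_equal(sidecar$eps_nm, 120)
})
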