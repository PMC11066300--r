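# MSD computation, diffusion fits and population decomposition.

test_that("MSD matches hand arithmetic and handles gaps by frame", {
  tr <- data.frame(track_id = 1L, frame = 1:3, x_nm = c(0, 100, 200), y_nm = 0)
  m <- compute_msd(tr, 0.05)
  expect_equal(m$msd_um2, c(0.01, 0.04), tolerance = 1e-12)
  expect_equal(m$lag_s, c(0.05, 0.10), tolerance = 1e-12)
  expect_identical(m$n_pairs, c(2L, 1L))
  # stationary track: identically zero
  st <- data.frame(track_id = 1L, frame = 1:10, x_nm = 5, y_nm = 5)
  expect_true(all(compute_msd(st, 0.05)$msd_um2 == 0))
  # bridged gap: frame arithmetic, no fabricated pairs
  gap <- data.frame(track_id = 1L, frame = c(1L, 2L, 4L), x_nm = c(0, 100, 300), y_nm = 0)
  mg <- compute_msd(gap, 0.05, max_lag = 3L)
  expect_identical(mg$lag_frames, c(1L, 2L, 3L))
  expect_identical(mg$n_pairs, c(1L, 1L, 1L))
  expect_equal(mg$msd_um2[2], 0.04, tolerance = 1e-12)  # frames 2 -> 4
  expect_error(compute_msd(st[1, ], 0.05), "at least 2")
})

test_that("pair bookkeeping sums to N(N-1)/2 for gap-free tracks", {
  set.seed(50)
  for (N in c(5L, 9L, 17L)) {
    tr <- data.frame(track_id = 1L, frame = seq_len(N),
                     x_nm = cumsum(rnorm(N, 0, 50)), y_nm = cumsum(rnorm(N, 0, 50)))
    m <- compute_msd(tr, 0.05, max_lag = N - 1L)
    expect_identical(m$n_pairs, N - seq_len(N - 1L))
    expect_identical(sum(m$n_pairs), N * (N - 1L) %/% 2L)
  }
})

test_that("MSD line fits recover exact lines and match lm", {
  dt <- 0.05
  lags <- data.frame(lag_frames = 1:6, lag_s = (1:6) * dt,
                     msd_um2 = 4 * 0.05 * (1:6) * dt, n_pairs = 10L)
  f <- fit_msd_linear(lags, 4)
  expect_equal(f$D_um2_per_s, 0.05, tolerance = 1e-12)
  expect_equal(f$intercept_um2, 0, tolerance = 1e-12)
  expect_equal(f$adj_r2, 1, tolerance = 1e-12)
  lags$msd_um2 <- 4 * 0.02 * lags$lag_s + 0.004
  f2 <- fit_msd_linear(lags, 4)
  expect_equal(f2$D_um2_per_s, 0.02, tolerance = 1e-12)
  expect_equal(f2$intercept_um2, 0.004, tolerance = 1e-12)
  # against lm on random curves
  set.seed(51)
  for (rep in 1:10) {
    curve <- data.frame(lag_frames = 1:8, lag_s = (1:8) * dt,
                        msd_um2 = runif(8, 0, 0.2), n_pairs = 5L)
    f3 <- fit_msd_linear(curve, 5)
    ref <- lm(msd_um2 ~ lag_s, data = curve[1:5, ])
    expect_equal(f3$D_um2_per_s, unname(coef(ref)[2]) / 4, tolerance = 1e-10)
    expect_equal(f3$intercept_um2, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(f3$adj_r2, summary(ref)$adj.r.squared, tolerance = 1e-10)
  }
  expect_error(fit_msd_linear(lags[1:3, ], 4), "fewer lags")
})

test_that("Brownian simulations recover D without intercept bias", {
  dt <- 0.05
  # long single track at MSD(1 lag)/(4 dt)
  tr <- simulate_track_set(1, 10000, 0.05, dt, 0, rng_seed = 52)
  m <- compute_msd(tr, dt, max_lag = 4L)
  expect_lt(abs(m$msd_um2[1] / (4 * dt) - 0.05) / 0.05, 0.05)
  # noiseless ensembles across three decades of D: truth within 3 SE,
  # intercept consistent with zero
  for (D in c(0.001, 0.01, 0.1)) {
    trs <- simulate_track_set(200, 30, D, dt, 0, rng_seed = 53 + round(1000 * D))
    mm <- mean_msd(trs, dt, 4)
    expect_lt(abs(mm$fit$D_um2_per_s - D) / D, 0.15)
    expect_lt(abs(mm$fit$intercept_um2), 4 * 4 * D * dt / sqrt(200))
  }
  # localization noise adds ~4 sigma_loc^2 of intercept without biasing D
  trn <- simulate_track_set(300, 30, 0.05, dt, 30, rng_seed = 54)
  mmn <- mean_msd(trn, dt, 4)
  expect_lt(abs(mmn$fit$D_um2_per_s - 0.05) / 0.05, 0.10)
  expect_lt(abs(mmn$fit$intercept_um2 - 4 * 0.03^2) / (4 * 0.03^2), 0.30)
})

test_that("mean MSD equals the single-track curve for identical tracks", {
  tr <- data.frame(track_id = 1L, frame = 1:10,
                   x_nm = cumsum(c(0, rep(100, 9))), y_nm = 0)
  single <- mean_msd(tr, 0.05, 2)
  expect_equal(single$curve$msd_um2, compute_msd(tr, 0.05, 10L)$msd_um2[1:nrow(single$curve)],
               tolerance = 1e-12)
  two <- rbind(tr, transform(tr, track_id = 2L))
  expect_equal(mean_msd(two, 0.05, 2)$curve$msd_um2, single$curve$msd_um2,
               tolerance = 1e-12)
  expect_error(mean_msd(tr[0, ], 0.05), "no eligible tracks")
})

test_that("per-track classification separates clean, noisy and immobile tracks", {
  dt <- 0.05
  # clean Brownian tracks: overwhelmingly accepted
  pt <- per_track_mobility(simulate_track_set(20, 40, 0.05, dt, 0, rng_seed = 60), dt)
  expect_gt(mean(pt$accepted), 0.8)
  # stationary noisy tracks: mostly rejected or immobile, never NaN logD
  stn <- simulate_track_set(40, 20, 0, dt, 10, rng_seed = 61)
  pts <- per_track_mobility(stn, dt)
  logD <- log10(pts$D_um2_per_s[pts$accepted])
  expect_true(all(is.finite(logD)))
  accepted_mobile <- sum(pts$accepted & pts$D_um2_per_s > 0.01)
  expect_lte(accepted_mobile, 2)
  expect_true(all(pts$reason %in% c("accepted", "low_adj_r2", "nonpositive_D", "too_short")))
})

test_that("population decomposition recovers planted mixtures deterministically", {
  # all values equal: single component at that mean, floored sd
  same <- rep(-2.5, 25)
  pop <- population_analysis(same, 2)
  expect_identical(nrow(pop$components), 1L)
  expect_equal(pop$components$mean, -2.5, tolerance = 1e-9)
  expect_equal(pop$components$sd, 0.05, tolerance = 1e-9)
  expect_error(population_analysis(rep(-2, 5)), "at least 10")

  set.seed(62)
  x <- c(rnorm(200, -3, 0.25), rnorm(200, -1, 0.25))
  pop2 <- population_analysis(x, 2)
  expect_identical(nrow(pop2$components), 2L)
  expect_lt(max(abs(pop2$components$weight - 0.5)), 0.10)
  expect_lt(abs(pop2$components$mean[1] + 3), 0.1)
  expect_lt(abs(pop2$components$mean[2] + 1), 0.1)
  expect_equal(sum(pop2$components$weight), 1, tolerance = 1e-9)
  expect_equal(pop2$mobile_fraction, 0.5, tolerance = 0.05)
  # deterministic: same input, same result
  expect_identical(population_analysis(x, 2), pop2)

  # independent cross-check with a reference mixture fitter
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressPackageStartupMessages(library(mclust))
    ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(ref$parameters$mean) - pop2$components$mean)), 0.05)
    expect_lt(max(abs(ref$parameters$pro[order(ref$parameters$mean)] -
                        pop2$components$weight)), 0.05)
  }
})

test_that("weight recovery improves on average with more tracks", {
  err_at_n <- function(n, reps = 20) {
    mean(vapply(seq_len(reps), function(r) {
      set.seed(1000 + r)
      n2 <- rbinom(1, n, 0.5)  # multinomial membership, not an exact split
      x <- c(rnorm(n - n2, -3, 0.25), rnorm(n2, -1, 0.25))
      p <- population_analysis(x, 2)
      if (nrow(p$components) < 2) return(0.5)
      max(abs(p$components$weight - 0.5))
    }, 0))
  }
  expect_lte(err_at_n(400), err_at_n(100))
})

test_that("mobility summary counts non-positive slopes as immobile", {
  dt <- 0.05
  mobile <- simulate_track_set(30, 30, 0.1, dt, 0, rng_seed = 70)
  immob <- simulate_track_set(30, 30, 1e-6, dt, 1, rng_seed = 71)
  immob$track_id <- immob$track_id + 30L
  ms <- mobility_summary(rbind(mobile, immob), dt)
  expect_true(ms$mobile_fraction >= 0 && ms$mobile_fraction <= 1)
  pt <- ms$per_track
  n_nonpos <- sum(pt$reason == "nonpositive_D")
  expect_equal(ms$mobile_fraction,
               sum(ms$logD_values > -2) / (length(ms$logD_values) + n_nonpos),
               tolerance = 1e-12)
})
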