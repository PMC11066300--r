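# Simulator: trajectories, photophysics, rendering, ground-truth I/O.

test_that("configurations validate their invariants", {
  expect_error(simulation_config(populations = data.frame(fraction = c(0.5, 0.4),
                                                          D_um2_per_s = c(0.01, 0.1))),
               "sum to 1")
  expect_error(simulation_config(p_blink_off = 1.5), "p_blink_off")
  cfg <- fluorophore_preset("PA-GFP-like", n_frames = 10L)
  expect_identical(cfg$photons_per_frame, 500)
})

test_that("trajectories obey the Brownian step law and boundaries", {
  # D = 0: static
  cfg0 <- simulation_config(n_frames = 50L, n_molecules = 10L,
                            populations = data.frame(fraction = 1, D_um2_per_s = 0),
                            rng_seed = 90)
  gt0 <- simulate_trajectories(cfg0)
  expect_true(all(gt0$X == gt0$X[, 1]))
  # mean squared step within 3 SE of 4 D dt over 10^4 steps
  cfg <- simulation_config(field_px = c(512, 512), n_frames = 10001L, n_molecules = 1L,
                           populations = data.frame(fraction = 1, D_um2_per_s = 0.05),
                           rng_seed = 91)
  gt <- simulate_trajectories(cfg)
  d2 <- diff(gt$X[1, ])^2 + diff(gt$Y[1, ])^2  # nm^2
  msq <- mean(d2) / 1e6                        # um^2
  se <- sd(d2 / 1e6) / sqrt(length(d2))
  expect_lt(abs(msq - 4 * 0.05 * 0.05), 3 * se)
  # reflecting boundaries keep everything inside
  expect_true(all(gt$X >= 0 & gt$X <= 512 * 100))
  # determinism
  gt2 <- simulate_trajectories(cfg)
  expect_identical(gt$X, gt2$X)
})

test_that("photophysics produces the scheduled statistics", {
  base <- list(field_px = c(32L, 32L), n_frames = 200L, n_molecules = 400L)
  # no activation: no emissions
  cfg0 <- do.call(simulation_config, c(base, list(activation_rate_per_frame = 0, rng_seed = 92)))
  gt0 <- simulate_photophysics(cfg0, simulate_trajectories(cfg0))
  expect_identical(nrow(gt0$emissions), 0L)
  # immediate bleaching: exactly one frame per activated molecule
  cfg1 <- do.call(simulation_config, c(base, list(activation_rate_per_frame = 1,
                                                  p_bleach_per_frame = 1,
                                                  p_blink_off = 0, rng_seed = 93)))
  gt1 <- simulate_photophysics(cfg1, simulate_trajectories(cfg1))
  expect_identical(nrow(gt1$emissions), 400L)
  expect_true(all(gt1$emissions$frame == 1L))
  # mean on-time matches the geometric law without blinking/bleaching
  cfg2 <- simulation_config(field_px = c(32L, 32L), n_frames = 2000L,
                            n_molecules = 5000L, activation_rate_per_frame = 1,
                            mean_on_frames = 8, p_blink_off = 0,
                            p_bleach_per_frame = 0, rng_seed = 94)
  gt2 <- simulate_photophysics(cfg2, simulate_trajectories(cfg2))
  on_times <- table(gt2$emissions$molecule_id)
  se <- sd(on_times) / sqrt(length(on_times))
  expect_lt(abs(mean(on_times) - 8), 3 * se)
})

test_that("rendering follows the camera model moments", {
  # no emitters, no background, no read noise: constant offset
  cfg <- simulation_config(field_px = c(16L, 16L), n_frames = 3L, n_molecules = 0L,
                           background_photons_per_px = 0,
                           camera = list(offset_adu = 100, e_per_adu = 0.5,
                                         read_noise_adu = 0, qe = 1),
                           rng_seed = 95)
  gt <- simulate_photophysics(cfg, simulate_trajectories(cfg))
  mv <- render_movie(cfg, gt)
  expect_true(all(mv$frames == 100))
  # one bright static emitter: frame maximum at its pixel
  cfg1 <- simulation_config(field_px = c(32L, 32L), n_frames = 1L, n_molecules = 1L,
                            populations = data.frame(fraction = 1, D_um2_per_s = 0),
                            activation_rate_per_frame = 1, photons_per_frame = 5000,
                            background_photons_per_px = 0,
                            camera = list(offset_adu = 100, e_per_adu = 0.5,
                                          read_noise_adu = 0, qe = 1),
                            rng_seed = 96)
  gt1 <- simulate_photophysics(cfg1, simulate_trajectories(cfg1))
  mv1 <- render_movie(cfg1, gt1)
  peak <- which(mv1$frames[, , 1] == max(mv1$frames[, , 1]), arr.ind = TRUE)
  true_px <- c(floor(gt1$emissions$y_nm[1] / 100) + 1, floor(gt1$emissions$x_nm[1] / 100) + 1)
  expect_lte(max(abs(peak[1, ] - true_px)), 1)
  # dark-stack moments: offset and read-noise variance within 3 SE
  cfgd <- simulation_config(field_px = c(24L, 24L), rng_seed = 97)
  dark <- simulate_dark_stack(cfgd, 500)
  cal <- calibrate_camera(dark)
  n_px <- length(cal$offset)
  expect_lt(abs(mean(cal$offset) - 100), 3 * 2 / sqrt(500 * n_px))
  # discretization (rounding to ADU) adds 1/12 ADU^2 to the dark variance
  expect_lt(abs(mean(cal$variance) - (4 + 1 / 12)),
            3 * sqrt(2 / 499) * 4 / sqrt(n_px))
})

test_that("photon counts are conserved in expectation", {
  cfg <- simulation_config(field_px = c(32L, 32L), n_frames = 60L, n_molecules = 30L,
                           activation_rate_per_frame = 0.05,
                           background_photons_per_px = 5,
                           camera = list(offset_adu = 100, e_per_adu = 0.5,
                                         read_noise_adu = 0, qe = 1),
                           rng_seed = 98)
  sim <- simulate_sptpalm(cfg)
  detected <- (sim$movie$frames - 100) * 0.5
  total <- sum(detected)
  # scheduled photons, corrected for the PSF tail falling off the frame
  sig <- 130 / 100
  ems <- sim$gt$emissions
  inx <- pnorm((32 - ems$x_nm / 100) / sig) - pnorm((0 - ems$x_nm / 100) / sig)
  iny <- pnorm((32 - ems$y_nm / 100) / sig) - pnorm((0 - ems$y_nm / 100) / sig)
  scheduled <- sum(ems$photons * inx * iny) + 5 * 32 * 32 * 60
  # Poisson: SE of the total is sqrt(total expected)
  expect_lt(abs(total - scheduled), 4 * sqrt(scheduled))
})

test_that("identical configurations give bit-identical simulations", {
  cfg <- simulation_config(field_px = c(24L, 24L), n_frames = 30L, n_molecules = 10L,
                           rng_seed = 99)
  s1 <- simulate_sptpalm(cfg)
  s2 <- simulate_sptpalm(cfg)
  expect_identical(s1$movie$frames, s2$movie$frames)
  expect_identical(s1$gt$emissions, s2$gt$emissions)
  expect_identical(s1$dark$frames, s2$dark$frames)
})

test_that("ground truth tables round-trip", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(field_px = c(24L, 24L), n_frames = 30L, n_molecules = 8L,
                           rng_seed = 100)
  gt <- simulate_photophysics(cfg, simulate_trajectories(cfg))
  write_ground_truth(gt, dir)
  back <- read_ground_truth(dir)
  expect_identical(nrow(back$emissions), nrow(gt$emissions))
  expect_equal(back$emissions$x_nm, gt$emissions$x_nm, tolerance = 1e-9)
  expect_identical(back$molecules$molecule_id, gt$molecules$molecule_id)
  # empty ground truth still writes headers
  cfg0 <- simulation_config(n_molecules = 0L, n_frames = 5L, rng_seed = 101)
  gt0 <- simulate_photophysics(cfg0, simulate_trajectories(cfg0))
  write_ground_truth(gt0, dir)
  expect_identical(nrow(read_ground_truth(dir)$emissions), 0L)
})
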