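# Synthetic sptPALM data: Brownian trajectories with one or two mobility
# populations, photoactivation/blinking/bleaching photophysics, and an
# integrated-Gaussian + Poisson + sCMOS camera rendering model. Every
# stage of the analysis pipeline can be tested against the ground truth
# this module produces.
#
# Reproducibility: `rng_seed` fixes all draws. The three stochastic stages
# use seeds rng_seed, rng_seed+1, rng_seed+2 (dark stacks rng_seed+3) so
# that each stage is individually reproducible; keep rng_seed < 2^31 - 10.

#' Simulation configuration
#'
#' Defaults describe a typical plant sptPALM acquisition: 128x128 px at
#' 100 nm/px, 3000 frames at 20 Hz, 800 photons per molecule per frame on
#' a background of 10 photons/px, PSF sigma 130 nm, and a 30%/70%
#' immobile/mobile split (D = 0.001 / 0.05 um^2/s). The sCMOS camera model
#' is `ADU = detected_photons / e_per_adu + offset + N(0, read_noise)`.
#'
#' @param field_px frame size `(rows, cols)` in pixels.
#' @param n_frames frames per movie.
#' @param frame_interval_s seconds per frame.
#' @param pixel_size_nm nm per pixel.
#' @param populations data frame `fraction, D_um2_per_s` (fractions sum
#'   to 1).
#' @param n_molecules molecules placed in the field.
#' @param activation_rate_per_frame per-frame photoactivation probability
#'   (geometric waiting time).
#' @param mean_on_frames mean fluorescent on-time, frames (geometric).
#' @param p_blink_off per-on-frame probability of a reversible dark state.
#' @param mean_dark_frames mean blink dark time, frames (geometric).
#' @param p_bleach_per_frame per-on-frame irreversible bleaching
#'   probability.
#' @param photons_per_frame mean emitted photons per on-frame (Poisson).
#' @param background_photons_per_px uniform background level.
#' @param psf_sigma_nm PSF standard deviation.
#' @param camera list `offset_adu, e_per_adu, read_noise_adu, qe`.
#' @param spatial_layout `"uniform"` or `"thomas"` (clustered: parent
#'   centers uniform, offspring Gaussian around parents).
#' @param thomas_n_parents,thomas_sigma_nm,thomas_background_fraction
#'   Thomas-process layout parameters.
#' @param confined_layout confine clustered molecules to discs of
#'   `confined_radius_nm` around their parent (hotspot scenario for
#'   track-based clustering).
#' @param confined_radius_nm confinement disc radius.
#' @param n_dark_frames frames in the companion dark-noise stack.
#' @param rng_seed integer seed fixing all stochastic draws.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(field_px = c(128L, 128L), n_frames = 3000L,
                              frame_interval_s = 0.05, pixel_size_nm = 100,
                              populations = data.frame(fraction = c(0.3, 0.7),
                                                       D_um2_per_s = c(0.001, 0.05)),
                              n_molecules = 500L,
                              activation_rate_per_frame = 0.001,
                              mean_on_frames = 20, p_blink_off = 0.1,
                              mean_dark_frames = 1, p_bleach_per_frame = 0.03,
                              photons_per_frame = 800,
                              background_photons_per_px = 10,
                              psf_sigma_nm = 130,
                              camera = list(offset_adu = 100, e_per_adu = 0.5,
                                            read_noise_adu = 2, qe = 1),
                              spatial_layout = c("uniform", "thomas"),
                              thomas_n_parents = 20L, thomas_sigma_nm = 40,
                              thomas_background_fraction = 0.1,
                              confined_layout = FALSE, confined_radius_nm = 100,
                              n_dark_frames = 200L,
                              rng_seed = 1L) {
  spatial_layout <- match.arg(spatial_layout)
  if (abs(sum(populations$fraction) - 1) > 1e-9)
    stop("population fractions must sum to 1")
  if (any(populations$fraction < 0) || any(populations$D_um2_per_s < 0))
    stop("population fractions and D must be non-negative")
  stopifnot(activation_rate_per_frame >= 0, activation_rate_per_frame <= 1,
            p_blink_off >= 0, p_blink_off <= 1,
            p_bleach_per_frame >= 0, p_bleach_per_frame <= 1,
            mean_on_frames >= 1, mean_dark_frames >= 1,
            n_frames >= 1, n_molecules >= 0, rng_seed < 2^31 - 10)
  cfg <- as.list(environment())
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Fluorophore presets
#'
#' Convenience configurations that differ only in mean photon yield per
#' frame and mean on-time; the values are generic ballpark figures for the
#' named photoactivatable/photoconvertible protein classes, not
#' measurements.
#'
#' @param name preset name.
#' @param ... overrides passed to [simulation_config()].
#' @export
fluorophore_preset <- function(name = c("mEos3.2-like", "PA-GFP-like", "PATagRFP-like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "mEos3.2-like" = list(photons_per_frame = 800, mean_on_frames = 20),
    "PA-GFP-like" = list(photons_per_frame = 500, mean_on_frames = 12),
    "PATagRFP-like" = list(photons_per_frame = 1000, mean_on_frames = 25))
  do.call(simulation_config, c(base, list(...)))
}

.reflect <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

#' Simulate Brownian trajectories
#'
#' Places `n_molecules` according to the spatial layout and lets each
#' perform 2-D Brownian motion with per-axis step variance `2 D dt`
#' (reflecting boundaries at the field edges). With `confined_layout`,
#' molecules that belong to a Thomas-process cluster are kept inside a
#' disc around their parent by radial reflection.
#'
#' @param cfg a [simulation_config()].
#' @return ground-truth list with `molecules` (one row per molecule:
#'   population, D, parent cluster) and position matrices `X`, `Y`
#'   (molecule x frame, nm).
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  nm <- cfg$n_molecules
  nf <- cfg$n_frames
  Lx <- cfg$field_px[2] * cfg$pixel_size_nm
  Ly <- cfg$field_px[1] * cfg$pixel_size_nm
  pop <- sample.int(nrow(cfg$populations), nm, replace = TRUE,
                    prob = cfg$populations$fraction)
  D <- cfg$populations$D_um2_per_s[pop]
  step_sd <- sqrt(2 * D * 1e6 * cfg$frame_interval_s)  # nm per axis

  parent <- rep(NA_integer_, nm)
  px0 <- py0 <- rep(NA_real_, nm)
  if (cfg$spatial_layout == "thomas" && nm > 0) {
    ppx <- runif(cfg$thomas_n_parents, 0, Lx)
    ppy <- runif(cfg$thomas_n_parents, 0, Ly)
    bg <- runif(nm) < cfg$thomas_background_fraction
    parent[!bg] <- sample.int(cfg$thomas_n_parents, sum(!bg), replace = TRUE)
    x0 <- ifelse(bg, runif(nm, 0, Lx), NA)
    y0 <- ifelse(bg, runif(nm, 0, Ly), NA)
    cl <- !bg
    x0[cl] <- .reflect(ppx[parent[cl]] + rnorm(sum(cl), 0, cfg$thomas_sigma_nm), 0, Lx)
    y0[cl] <- .reflect(ppy[parent[cl]] + rnorm(sum(cl), 0, cfg$thomas_sigma_nm), 0, Ly)
    px0[cl] <- ppx[parent[cl]]; py0[cl] <- ppy[parent[cl]]
  } else {
    x0 <- runif(nm, 0, Lx)
    y0 <- runif(nm, 0, Ly)
  }

  X <- matrix(NA_real_, nm, nf)
  Y <- matrix(NA_real_, nm, nf)
  if (nm > 0) {
    X[, 1] <- x0; Y[, 1] <- y0
    confined <- isTRUE(cfg$confined_layout) & !is.na(parent)
    R <- cfg$confined_radius_nm
    for (t in seq_len(nf - 1L)) {
      xn <- .reflect(X[, t] + rnorm(nm, 0, step_sd), 0, Lx)
      yn <- .reflect(Y[, t] + rnorm(nm, 0, step_sd), 0, Ly)
      if (any(confined)) {
        dx <- xn[confined] - px0[confined]
        dy <- yn[confined] - py0[confined]
        r <- sqrt(dx^2 + dy^2)
        over <- r > R
        if (any(over)) {
          scl <- (2 * R - r[over]) / r[over]
          scl[scl < 0] <- 0
          xn[confined][over] <- px0[confined][over] + dx[over] * scl
          yn[confined][over] <- py0[confined][over] + dy[over] * scl
        }
      }
      X[, t + 1L] <- xn
      Y[, t + 1L] <- yn
    }
  }
  molecules <- data.frame(molecule_id = seq_len(nm), population = pop,
                          D_um2_per_s = D, parent_cluster = parent,
                          activation_frame = rep(NA_integer_, nm),
                          bleach_frame = rep(NA_integer_, nm))
  list(molecules = molecules, X = X, Y = Y, cfg = cfg)
}

#' Simulate photoactivation, blinking and bleaching
#'
#' Each molecule activates once (geometric waiting time with
#' `activation_rate_per_frame`). After each emitted frame it bleaches
#' permanently with `p_bleach_per_frame`; otherwise it may blink into a
#' reversible dark state (`p_blink_off`, geometric dark time with mean
#' `mean_dark_frames`); otherwise the on-run ends for good with
#' probability `1/mean_on_frames`, so that without blinking and bleaching
#' the total on-time is geometric with mean `mean_on_frames`. Photons per
#' on-frame are Poisson with mean `photons_per_frame`.
#'
#' @param cfg a [simulation_config()].
#' @param gt output of [simulate_trajectories()].
#' @return `gt` with `molecules$activation_frame`, `molecules$bleach_frame`
#'   filled in and an `emissions` table (`molecule_id, frame, x_nm, y_nm,
#'   photons`) sorted by frame.
#' @export
simulate_photophysics <- function(cfg, gt) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed + 1L)
  nm <- cfg$n_molecules
  nf <- cfg$n_frames
  p_end <- 1 / cfg$mean_on_frames
  p_dark <- 1 / cfg$mean_dark_frames
  ems <- vector("list", nm)
  for (i in seq_len(nm)) {
    if (cfg$activation_rate_per_frame <= 0) break
    a <- 1L + rgeom(1, cfg$activation_rate_per_frame)
    if (a > nf) next
    gt$molecules$activation_frame[i] <- a
    frames <- integer(0)
    f <- a
    repeat {
      if (f > nf) break
      frames <- c(frames, f)
      if (runif(1) < cfg$p_bleach_per_frame) { gt$molecules$bleach_frame[i] <- f; break }
      if (runif(1) < cfg$p_blink_off) {
        f <- f + 1L + 1L + rgeom(1, p_dark)  # next frame + dark period
      } else if (runif(1) < p_end) {
        break
      } else {
        f <- f + 1L
      }
    }
    if (length(frames) > 0) {
      ems[[i]] <- data.frame(molecule_id = i, frame = frames,
                             x_nm = gt$X[i, frames], y_nm = gt$Y[i, frames],
                             photons = rpois(length(frames), cfg$photons_per_frame))
    }
  }
  ems <- ems[!vapply(ems, is.null, TRUE)]
  emissions <- if (length(ems) > 0) do.call(rbind, ems) else
    data.frame(molecule_id = integer(), frame = integer(),
               x_nm = numeric(), y_nm = numeric(), photons = numeric())
  emissions <- emissions[order(emissions$frame, emissions$molecule_id), , drop = FALSE]
  rownames(emissions) <- NULL
  gt$emissions <- emissions
  gt
}

# Add one emitter's expected photon image to `expected` (in place value
# return). Integrated Gaussian over a window of +-(4 sigma + 1) px.
.add_emitter <- function(expected, x_nm, y_nm, photons, psf_sigma_px, pixel_size_nm) {
  nr <- nrow(expected); nc <- ncol(expected)
  xp <- x_nm / pixel_size_nm  # pixel-edge coordinates
  yp <- y_nm / pixel_size_nm
  w <- ceiling(4 * psf_sigma_px) + 1L
  jlo <- max(1L, floor(xp) + 1L - w); jhi <- min(nc, floor(xp) + 1L + w)
  ilo <- max(1L, floor(yp) + 1L - w); ihi <- min(nr, floor(yp) + 1L + w)
  if (jlo > jhi || ilo > ihi) return(expected)
  dEx <- diff(pnorm(((jlo - 1L):jhi - xp) / psf_sigma_px))
  dEy <- diff(pnorm(((ilo - 1L):ihi - yp) / psf_sigma_px))
  expected[ilo:ihi, jlo:jhi] <- expected[ilo:ihi, jlo:jhi] + photons * outer(dEy, dEx)
  expected
}

.camera_frame <- function(expected, cam) {
  detected <- rpois(length(expected), as.numeric(expected) * cam$qe)
  adu <- detected / cam$e_per_adu + cam$offset_adu +
    rnorm(length(expected), 0, cam$read_noise_adu)
  adu <- round(adu)
  clipped <- sum(adu < 0 | adu > 65535)
  adu[adu < 0] <- 0; adu[adu > 65535] <- 65535
  list(frame = matrix(adu, nrow(expected), ncol(expected)), clipped = clipped)
}

#' Render the movie through the camera model
#'
#' Per frame, the expected photon image is the sum of the scheduled
#' emitters (integrated Gaussian at the true position, sigma
#' `psf_sigma_nm`) plus the uniform background. Detected photons are
#' Poisson with mean `expected * qe`; counts are converted to ADU with the
#' affine camera model plus Gaussian read noise, rounded and clipped to
#' the 16-bit range (clipping is reported via a warning if it occurs).
#' Emitters are rendered at their frame-start position (no intra-frame
#' motion blur).
#'
#' @param cfg a [simulation_config()].
#' @param gt output of [simulate_photophysics()].
#' @return a [movie_stack()] of ADU frames.
#' @export
render_movie <- function(cfg, gt) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(gt$emissions))
  set.seed(cfg$rng_seed + 2L)
  nr <- cfg$field_px[1]; nc <- cfg$field_px[2]
  sig_px <- cfg$psf_sigma_nm / cfg$pixel_size_nm
  frames <- array(0, dim = c(nr, nc, cfg$n_frames))
  by_frame <- split(seq_len(nrow(gt$emissions)), gt$emissions$frame)
  n_clipped <- 0
  for (fr in seq_len(cfg$n_frames)) {
    expected <- matrix(cfg$background_photons_per_px, nr, nc)
    rows <- by_frame[[as.character(fr)]]
    for (r in rows) {
      expected <- .add_emitter(expected, gt$emissions$x_nm[r], gt$emissions$y_nm[r],
                               gt$emissions$photons[r], sig_px, cfg$pixel_size_nm)
    }
    cf <- .camera_frame(expected, cfg$camera)
    frames[, , fr] <- cf$frame
    n_clipped <- n_clipped + cf$clipped
  }
  if (n_clipped > 0)
    warning(n_clipped, " pixel value(s) clipped to the 16-bit range")
  movie_stack(frames, cfg$pixel_size_nm, cfg$frame_interval_s,
              source = sprintf("<simulated seed %d>", cfg$rng_seed))
}

#' Simulate a dark-noise stack
#'
#' Zero expected photons through the same camera model; used to exercise
#' and test [calibrate_camera()].
#'
#' @param cfg a [simulation_config()].
#' @param n_frames number of dark frames.
#' @export
simulate_dark_stack <- function(cfg, n_frames = cfg$n_dark_frames) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed + 3L)
  nr <- cfg$field_px[1]; nc <- cfg$field_px[2]
  frames <- array(0, dim = c(nr, nc, n_frames))
  zero <- matrix(0, nr, nc)
  for (fr in seq_len(n_frames)) frames[, , fr] <- .camera_frame(zero, cfg$camera)$frame
  movie_stack(frames, cfg$pixel_size_nm, cfg$frame_interval_s,
              source = sprintf("<simulated dark seed %d>", cfg$rng_seed))
}

#' Run the full simulation
#'
#' Trajectories, photophysics, rendered movie and companion dark stack in
#' one call. Identical configurations (including `rng_seed`) give
#' bit-identical output.
#'
#' @param cfg a [simulation_config()].
#' @return list `movie`, `dark`, `gt` (molecules, emissions), `cfg`.
#' @export
simulate_sptpalm <- function(cfg = simulation_config()) {
  gt <- simulate_photophysics(cfg, simulate_trajectories(cfg))
  movie <- render_movie(cfg, gt)
  dark <- simulate_dark_stack(cfg)
  list(movie = movie, dark = dark, gt = gt, cfg = cfg)
}

#' Simulate idealized track sets
#'
#' Pure Brownian tracks observed at every frame with optional Gaussian
#' localization noise — the standard benchmark input for the MSD stage,
#' bypassing rendering and detection.
#'
#' @param n_tracks number of tracks.
#' @param n_steps steps per track (track length is `n_steps + 1`).
#' @param D_um2_per_s diffusion coefficient, scalar or per-track vector.
#' @param frame_interval_s seconds per frame.
#' @param loc_noise_nm localization error SD added per coordinate.
#' @param rng_seed seed.
#' @return track data frame `track_id, frame, x_nm, y_nm`.
#' @export
simulate_track_set <- function(n_tracks, n_steps, D_um2_per_s,
                               frame_interval_s = 0.05, loc_noise_nm = 0,
                               rng_seed = 1L) {
  set.seed(rng_seed)
  D <- rep_len(D_um2_per_s, n_tracks)
  rows <- lapply(seq_len(n_tracks), function(i) {
    sd_step <- sqrt(2 * D[i] * 1e6 * frame_interval_s)
    x <- cumsum(c(0, rnorm(n_steps, 0, sd_step)))
    y <- cumsum(c(0, rnorm(n_steps, 0, sd_step)))
    data.frame(track_id = i, frame = seq_len(n_steps + 1L),
               x_nm = x + rnorm(n_steps + 1L, 0, loc_noise_nm),
               y_nm = y + rnorm(n_steps + 1L, 0, loc_noise_nm))
  })
  do.call(rbind, rows)
}

#' Write and read ground-truth tables
#'
#' Two CSVs (`gt_emissions.csv`, `gt_molecules.csv`) with fixed headers;
#' the round trip is lossless.
#'
#' @param gt ground-truth list with `molecules` and `emissions`.
#' @param dir output directory (created if needed).
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(format(gt$emissions, digits = 15, trim = TRUE, scientific = FALSE),
            file.path(dir, "gt_emissions.csv"), row.names = FALSE, quote = FALSE)
  write.csv(format(gt$molecules, digits = 15, trim = TRUE, scientific = FALSE),
            file.path(dir, "gt_molecules.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  ems <- read.csv(file.path(dir, "gt_emissions.csv"))
  mol <- read.csv(file.path(dir, "gt_molecules.csv"))
  for (col in c("x_nm", "y_nm", "photons")) ems[[col]] <- as.numeric(ems[[col]])
  ems$molecule_id <- as.integer(ems$molecule_id); ems$frame <- as.integer(ems$frame)
  list(molecules = mol, emissions = ems)
}
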