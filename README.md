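# sptpalm

An R package for analyzing single-particle tracking photoactivated
localization microscopy (sptPALM) data of membrane proteins. sptPALM
movies show sparse, stochastically activated fluorophores blinking on and
off across thousands of camera frames; turning them into biology takes
four stages, all implemented here as a scriptable pipeline:

1. **Localization** — candidate spots are detected per frame
   (difference-of-Gaussians band-pass, threshold in robust noise units)
   and each is fitted by maximum likelihood with a pixel-integrated 2-D
   Gaussian PSF model under Poisson noise,
   `mu_k = N * ΔEx_k * ΔEy_k + b`, optionally adding the per-pixel
   `var/gain^2` map of an sCMOS camera to data and model. The theoretical
   precision of each fit is the Mortensen-style closed form
   `sigma_loc^2 = (sigma_a^2/N) * (16/9 + 8*pi*sigma_a^2*b/(N*a^2))`,
   `sigma_a^2 = sigma^2 + a^2/12`.
2. **Tracking** — localizations are linked frame-to-frame by solving a
   linear assignment problem to global optimality (squared-distance costs,
   fixed non-link alternative cost, maximum link distance), and short
   blinking gaps are bridged by a second global assignment between
   segment ends and starts.
3. **Mobility** — per-track and ensemble mean-square displacement;
   `MSD(n Δt)` fitted over its first few points gives `D = slope/4`
   (2-D diffusion), the intercept absorbing localization error
   (`≈ 4 sigma_loc^2`). Per-track `log10(D)` distributions are decomposed
   into Gaussian populations (deterministic EM, BIC model choice) and
   split into mobile/immobile fractions at a configurable threshold.
4. **Cluster analysis** — nanoscale organization from all localizations,
   track centroids, or the tracks themselves: Voronoi tessellation
   (neighbor-averaged cell density vs. a multiple of the mean density),
   DBSCAN, and NASTIC (connected components of overlapping, expanded
   track bounding boxes).

A full synthetic-movie **simulator** (Brownian mobility populations,
photoactivation/blinking/bleaching, integrated-Gaussian rendering,
Poisson + sCMOS camera noise) provides ground truth for every stage, and
a **batch** driver processes file lists with one frozen parameter set,
embedding the complete parameter snapshot in the results workbook so
every number can be traced back to its settings.

## Worked example

```r
library(sptpalm)

# simulate a short acquisition: 64x64 px, 500 frames at 20 Hz
cfg <- simulation_config(field_px = c(64, 64), n_frames = 500,
                         n_molecules = 120, rng_seed = 42)
sim <- simulate_sptpalm(cfg)
sim$movie
#> movie_stack: 500 frames of 64x64 px, 100 nm/px, 0.05 s/frame (<simulated seed 42>)

# camera calibration from the dark stack, then localization
calib <- calibrate_camera(sim$dark, e_per_adu = 0.5, qe = 1)
locs <- filter_localizations(localize_stack(sim$movie, calib, sptpalm_params()))
#> 365 localizations, median precision 7.1 nm

# trajectories with gap closing, then MSD mobility analysis
tracks <- build_tracks(locs, tracking_params(max_link_distance_nm = 500,
                                             max_gap_frames = 1,
                                             min_track_length = 8))
mob <- mobility_summary(tracks, cfg$frame_interval_s)
#> 14 tracks (>= 8 locs): D_mean = 0.0377 um2/s, peak log10(D) = -1.29, mobile fraction = 0.64

# nanoscale organization from the tracks themselves
cluster_nastic(make_cluster_input(tracks = tracks, mode = "tracks"))
#> cluster_result (nastic): 14 tracks, 0 clusters, clustered fraction 0.000
```

The simulated sample plants a 30%/70% immobile/mobile mixture
(D = 0.001 / 0.05 µm²/s); the recovered ensemble coefficient
(0.0377 µm²/s vs. a planted track-weighted mean of 0.0353), peak
log10(D) near log10(0.05) = −1.30 and mobile fraction near 0.7 show the
pipeline recovering its inputs. Molecules were laid out uniformly, so the
track-based cluster analysis correctly finds nothing.

A thin command-line front end (`exec/sptpalm`) exposes the same stages as
`simulate`, `localize`, `track`, `mobility`, `cluster` and `batch`
subcommands operating on TIFF/CSV/JSON files.

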