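---
title: "sptpalm: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sptpalm: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models behind each pipeline stage, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical and design choices made where the
method descriptions in the literature leave room.

# The measurement being modeled

sptPALM films sparse, stochastically photoactivated fluorophore fusions
in a living cell's plasma membrane: typically 100×100 to 400×400 pixels
at 100 nm/pixel, several thousand frames at 20–50 Hz, recorded on an
sCMOS camera together with a dark-image series for noise calibration.
Each frame shows a handful of diffraction-limited spots; each spot is one
molecule, visible for a geometric handful of frames, blinking off and on
before bleaching. The analysis must (i) localize each emission well below
the diffraction limit, (ii) string emissions into per-molecule
trajectories across blinking gaps, (iii) convert trajectories into
diffusion coefficients and population structure, and (iv) quantify
nanoscale spatial organization.

# Localization

## Detection

Each photon-converted frame is band-passed with a difference of
Gaussians (`dog_sigma_small_px = 1.0`, `dog_sigma_large_px = 2.5`); local
8-neighborhood maxima above `threshold_factor = 4` times the robust noise
scale of the filtered frame (1.4826 × median absolute deviation) become
candidates. MAD-based thresholding makes the cutoff insensitive to the
bright spots themselves. Candidates within `roi_halfsize_px = 3` of the
border are dropped because their 7×7 fit window would leave the frame.
Plateau ties in the maximum test are resolved to the first pixel in
column-major order, making detection fully deterministic.

## The integrated-Gaussian MLE fit

The expected photon count in ROI pixel *k* is
`mu_k = N · ΔEx_k · ΔEy_k + b`, where `ΔE` are the Gaussian integrals
over the pixel's extent (erf differences), `N` the total signal photons,
`b` a flat per-pixel background and `sigma` the PSF width, free per spot
(PSF-size histograms are a primary quality-control output). The Poisson
log-likelihood is maximized by Levenberg-damped Fisher scoring with
analytic derivatives; `N`, `b`, `sigma` are optimized on the log scale,
which enforces positivity without constraints. Iteration stops when the
maximum parameter change drops below `tol = 1e-6` (positions in pixels,
log-parameters relative) or after `max_iterations = 30`; a fit that stops
on the iteration cap, or lands in implausible geometry (center beyond the
ROI, `sigma` below 0.1 px or above the ROI side), is flagged
not-converged. Flagged fits are retained in the raw table and removed by
the quality filter, so the table always accounts for every candidate.

With a per-pixel camera calibration available, the sCMOS read noise is
handled with the standard variance-offset approximation: `var/gain^2`
(in photon units) is added to both the data and the model before
evaluating the likelihood. A zero variance map reproduces the
pure-Poisson path exactly, which is tested to 1e-9.

Initial values come from the data: border-median background, photon sum
for `N`, a background-subtracted centroid clamped to ±1 px of the ROI
center for the position, and `initial_sigma_px = 1.3` (a 130 nm PSF at
100 nm pixels, the visible-FP regime this pipeline targets).

When two candidates sit closer than one ROI, both are fitted and any fit
whose center lands more than one pixel from its own candidate pixel is
discarded; this removes the duplicate of a pair of fits that converged to
the same emitter. Multi-emitter fitting is out of scope.

## Precision and quality filtering

The per-localization precision uses the Mortensen-style MLE
approximation

```
sigma_loc^2 = (sigma_a^2 / N) · (16/9 + 8·pi·sigma_a^2·b / (N·a^2)),
sigma_a^2   = sigma^2 + a^2/12,
```

with `a` the pixel size. At `sigma` = 130 nm, `a` = 100 nm, `N` = 1000,
`b` = 0 this gives 5.6 nm. The statistical efficiency of the whole fit is
checked in the test suite against a Cramér–Rao bound computed numerically
from the Fisher information of the same model (1000 simulated spots at
`N` = 1000, `b` = 10): the empirical RMSE must sit within 15% of the
bound and the mean signed error below 2 nm.

The default quality window — `sigma` ∈ [80, 250] nm, `photons` ≥ 100,
`precision` ≤ 50 nm — is deliberately loose for the 100 nm-pixel,
fluorescent-protein regime: it removes fits of noise, aggregates and
out-of-focus emitters without biasing the retained distributions. All
bounds are user parameters.

# Tracking

Frame-to-frame linking is a linear assignment problem per consecutive
frame pair: candidate links are gated at `max_link_distance_nm = 500`,
cost is squared distance, and every unlinked localization pays the fixed
alternative cost `(1.05 × max_link_distance_nm)^2` (the convention of the
widely used simple LAP trackers). Minimizing that objective is equivalent
to a maximum-weight bipartite matching with edge weights
`2·alt − d^2`, which the package solves exactly via igraph's
maximum-weight bipartite matcher; optimality is verified in the tests
against brute-force enumeration on small instances. Ties are broken by a
tiny index-ordered weight perturbation, so linking is deterministic for
a given input order.

Gap closing is a second global assignment between segment ends and
segment starts with frame gap in `[2, max_gap_frames + 1]` and distance
at most `max_gap_distance_nm` (default: equal to the link distance, not
scaled with gap length — conservative, because a molecule should not be
granted extra travel for having blinked). Bridged frames are recorded;
no positions are interpolated. Defaults `max_gap_frames = 1` and
`min_track_length = 8` reflect standard sptPALM practice: single-frame
dark states dominate fluorophore blinking at these frame rates, and
tracks of at least eight localizations give usable individual MSD fits.
Merge/split handling is omitted: sptPALM activation keeps densities low
enough that it buys nothing.

# Mobility analysis

Per track, `MSD(n·Δt)` is the mean squared displacement over all ordered
position pairs `n` *frames* apart — frame arithmetic, not index
arithmetic, so pairs spanning a bridged blinking gap contribute at their
true lag and no pairs are invented for missing frames. The diffusion
coefficient is `slope/4` from an ordinary least-squares fit of the first
`n_fit_points = 4` lags, intercept free: for 2-D Brownian motion
`MSD = 4Dt + 4·sigma_loc^2`, so the intercept absorbs the localization
error and the slope stays unbiased. Four points is the usual compromise
between bias (later MSD points of short tracks are dominated by noise
and correlations) and variance.

The ensemble "mean MSD" averages per-track MSD values per lag,
unweighted, and retains lags from 1 upward only while at least half of
the tracks contribute — the tail of the lag axis otherwise reflects only
the few longest tracks. Weighting tracks by pair counts was considered
and rejected: it couples the ensemble estimate to track-length
(i.e. photophysics) statistics.

Per-track fits are accepted when the adjusted R²
(`1 − (1−R²)(m−1)/(m−2)`, `m = n_fit_points`) reaches
`adj_r2_min = 0.7` and the slope is positive. Tracks with non-positive
slope have no `log10(D)`; they are counted and treated as immobile in the
mobile-fraction calculation, while low-R² tracks are treated as
*inconclusive* and excluded from the fraction entirely. The mobile/
immobile boundary defaults to `log10(D) = −2` (0.01 µm²/s), a
conventional split for membrane proteins.

The `log10(D)` distribution is decomposed into one or two Gaussian
components by maximum likelihood. The EM fitter is deliberately free of
randomness: five quantile-based initializations, best likelihood kept,
component SDs floored at 0.05 decades to forbid degenerate spikes, model
order chosen by BIC. "Peak log(D)" is defined as the mean of the
highest-weight fitted component (not a histogram mode, which depends on
binning); this definition is stated here because the term is used
loosely in the field.

# Cluster analysis

All three methods share a result container (labels, clusters, noise,
clustered fraction) and metrics: convex-hull area (exact polygon area,
reported in µm²; 0 for degenerate clusters) and the equivalent-circle
diameter `2·sqrt(area/pi)`.

**Voronoi.** Cells are built inside an analysis rectangle (input
bounding box expanded 2%) by half-plane clipping in compiled code, which
also yields exact cell adjacency and boundary contact. The local density
of a point is averaged over its own cell and its first-rank neighbors,
`delta_i = (1+|N(i)|) / (A_i + Σ_{j∈N(i)} A_j)`. Own-cell density alone
was evaluated and rejected: the cell-area fluctuations of a completely
random pattern are so large that a 2× mean-density threshold seeds many
spurious clusters, while neighbor averaging suppresses them without
affecting genuinely dense regions (planted clusters are two orders of
magnitude above threshold). Seeds are points with density at least
`density_factor = 2` times the global mean `n/rect area`; boundary-
touching cells (truncated areas) cannot seed. Clusters are connected
components of seed cells sharing an edge, kept at `min_pts = 5`. The
false-positive control — 20 replicates of complete spatial randomness at
matched density must yield a median of at most one cluster — is part of
the acceptance tests.

**DBSCAN.** Canonical semantics (core iff ≥ `min_pts` neighbors within
`eps` including itself; clusters are density-connected components of
cores plus border points), with the one free choice pinned for
determinism: a border point reachable from several clusters joins the
lowest cluster id. Neighbor search uses grid bucketing; the test suite
proves label equality with a brute-force queue-expansion reference over
a parameter grid and 50 random instances.

**NASTIC.** Each track becomes the axis-aligned bounding box of its
localizations, expanded about its center by `radius_factor = 1.2`;
tracks whose boxes intersect (closed intervals — touching counts) are
connected and components with at least `min_tracks = 3` tracks are
clusters, with metrics computed on the union of member localizations.
Overlaps are found by a plane sweep over x-sorted boxes (expected
O(n log n) for sparse layouts) and are verified against an all-pairs
union-find oracle. Temporal gating (requiring track time intervals
within `temporal_window_s`) is available but off by default: the method's
discriminating signal here is spatial overlap, and sptPALM activation
already spreads tracks over the whole movie.

# The simulator: what it emulates, and what it does not

The generator produces the study conditions the pipeline is designed
for, with defaults fixed once: 128×128 px at 100 nm/px, 3000 frames at
20 Hz, 500 molecules in two mobility populations (30% at 0.001 µm²/s,
70% at 0.05 µm²/s — a typical immobile/mobile split, planted mobile
fraction 0.70), 800 photons per frame on 10 background photons/px, PSF
sigma 130 nm, camera offset 100 ADU, 0.5 e⁻/ADU, 2 ADU read noise.
Photophysics is frame-discrete: one geometric activation per molecule
(rate 1/1000 per frame), after each emitted frame bleaching with
p = 0.03, otherwise blinking with p = 0.1 into a geometric dark state of
mean 1 frame, otherwise run termination with hazard 1/20 (so the no-
blink no-bleach on-time is geometric with mean `mean_on_frames`). These
rates give on the order of 0.04 active tracks/µm²/frame — the sparse
regime sptPALM needs — and several thousand localizations per movie.
Mean dark times of one frame are the canonical single-frame blink case
that `max_gap_frames = 1` gap closing exists for; the blinking benchmark
in the tests (50 tracks, ~10% dropped frames, ≥90% reassembly) uses
single-frame dropouts for the same reason.

Rendering draws per-pixel Poisson photons around integrated-Gaussian
expected images at the frame-start position of each emitter and applies
the affine camera model with Gaussian read noise, rounding and 16-bit
clipping. Deliberate non-features, so that passing tests are read
correctly: no intra-frame motion blur, no drift, no depth (2-D only), no
EMCCD excess noise, no structured cellular background, no autofluorescent
gradients. Real data adds all of these; the simulator validates the
*algorithms*, not the microscope.

Layouts: uniform; a Thomas process (uniform parents, Gaussian offspring)
for planted spatial clusters; and a confined variant that reflects
clustered molecules back into discs around their parent, which produces
the hotspot-track scenario used to exercise NASTIC. Test fixtures built
on these layouts pin the quantities the generator leaves open: Thomas
benchmarks use a 5×5 µm field with parent centers at least 500 nm apart
(overlapping parents would make the planted cluster count ill-defined),
and hotspot scenarios use 11-frame tracks, a typical sptPALM track
length that keeps free-track bounding boxes small relative to the field.

Determinism: `rng_seed` fixes everything; the trajectory, photophysics,
rendering and dark-stack stages use consecutive derived seeds so each
stage is individually reproducible.

# Problem sizes and runtime

The shipped test-suite and acceptance-script workloads are sized so the
statistical assertions have power without waste: 1000 spots for the
efficiency/bias checks, 50 tracks for reassembly, ~1600 links for link
accuracy, 300–400 tracks for diffusion and mixture recovery, 50 random
instances per clustering oracle, 20 CSR replicates, and one full
3000-frame default movie end-to-end. The complete suite runs in a few
minutes on one CPU.

# Known limitations

* Single-emitter fitting only; overlapping emitters are detected but one
  of the duplicate fits is discarded, so very high activation densities
  lose recall.
* The sCMOS treatment is the Poisson-approximation variance offset, not
  an exact Poisson–Gaussian likelihood; at very low signal the
  approximation costs a little efficiency.
* `D = slope/4` assumes free 2-D diffusion in the membrane plane;
  anomalous exponents, confinement radii and state-switching models are
  out of scope.
* The Voronoi variant thresholds neighbor-averaged first-rank density;
  published tessellation tools differ in this detail, so absolute cluster
  counts should be compared only within one parameter setting — which is
  also the practical advice for every clustering method implemented
  here, as their outputs are parameter-sensitive by nature.
* Batch processing is sequential; there is no GUI and no proprietary
  format reader (TIFF/CSV/JSON only).
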