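# Shared programmatic fixtures.

# Thomas-process point pattern with separable parents (parent centers at
# least min_sep apart by rejection), plus uniform background points.
gen_thomas_points <- function(seed, n_parents = 20L, pts_per_parent = 30L,
                              sigma_nm = 40, field_nm = 5000, margin_nm = 300,
                              n_background = 60L, min_sep_nm = 500) {
  set.seed(seed)
  px <- py <- numeric(0)
  while (length(px) < n_parents) {
    x <- runif(1, margin_nm, field_nm - margin_nm)
    y <- runif(1, margin_nm, field_nm - margin_nm)
    if (length(px) == 0 || min((px - x)^2 + (py - y)^2) > min_sep_nm^2) {
      px <- c(px, x); py <- c(py, y)
    }
  }
  n <- n_parents * pts_per_parent
  xs <- rep(px, each = pts_per_parent) + rnorm(n, 0, sigma_nm)
  ys <- rep(py, each = pts_per_parent) + rnorm(n, 0, sigma_nm)
  list(xy = cbind(c(xs, runif(n_background, 0, field_nm)),
                  c(ys, runif(n_background, 0, field_nm))),
       parent = c(rep(seq_len(n_parents), each = pts_per_parent),
                  rep(NA_integer_, n_background)))
}

# Well-separated Brownian tracks on a grid of start points, with
# single-frame blink dropouts at roughly `miss_rate` of interior frames.
gen_blinking_tracks <- function(seed, n_tracks = 50L, len = 20L,
                                D = 0.05, dt = 0.05, miss_rate = 0.12,
                                spacing_nm = 3000) {
  set.seed(seed)
  sd_step <- sqrt(2 * D * 1e6 * dt)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    cx <- ((i - 1) %% 8) * spacing_nm + 1000
    cy <- ((i - 1) %/% 8) * spacing_nm + 1000
    x <- cumsum(c(cx, rnorm(len - 1, 0, sd_step)))
    y <- cumsum(c(cy, rnorm(len - 1, 0, sd_step)))
    f0 <- sample.int(50, 1)
    present <- rep(TRUE, len)
    t <- 2L
    while (t <= len - 1L) {  # never two consecutive dark frames
      if (runif(1) < miss_rate) { present[t] <- FALSE; t <- t + 2L } else t <- t + 1L
    }
    rows[[i]] <- data.frame(mol = i, frame = f0 + (0:(len - 1)),
                            x_nm = x, y_nm = y)[present, ]
  }
  gt <- do.call(rbind, rows)
  gt[order(gt$frame, gt$mol), ]
}

# For reassembly checks: fraction of molecules whose localizations ended
# up in exactly one track that contains nothing else.
reassembled_fraction <- function(gt, tracks) {
  tr_of <- tracks$track_id[order(tracks$loc_index)]
  mol <- gt$mol
  per_mol <- tapply(tr_of, mol, function(v) length(unique(v)))
  mols_of_tr <- tapply(mol, tr_of, function(v) length(unique(v)))
  mean(vapply(unique(mol), function(i) {
    trs <- unique(tr_of[mol == i])
    length(trs) == 1 && mols_of_tr[as.character(trs)] == 1
  }, TRUE))
}

# Localization table with the minimal columns tracking needs.
as_locs <- function(frame, x_nm, y_nm) {
  data.frame(frame = frame, x_nm = x_nm, y_nm = y_nm, sigma_nm = 130,
             photons = 500, background_photons = 10, precision_nm = 10,
             converged = TRUE)
}
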