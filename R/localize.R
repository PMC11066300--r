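# Single-molecule localization: candidate detection on a
# difference-of-Gaussians filtered frame, maximum-likelihood fitting of an
# integrated 2-D Gaussian PSF under Poisson noise (with an optional sCMOS
# read-noise treatment), closed-form precision, and quality filtering.

# --- separable Gaussian smoothing -----------------------------------------

# Dense row-convolution matrix for a truncated, edge-renormalized Gaussian.
# Applying S %*% F smooths columns of F; F %*% t(S) smooths rows.
.gauss_smoother <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  idx <- seq_len(n)
  S <- matrix(0, n, n)
  kern <- dnorm(-half:half, sd = sigma)
  for (i in idx) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    w <- kern[ok]
    S[i, j[ok]] <- w / sum(w)
  }
  S
}

.dog_filter <- function(frame, sigma_small, sigma_large, smoothers = NULL) {
  if (is.null(smoothers)) {
    smoothers <- list(sr = .gauss_smoother(nrow(frame), sigma_small),
                      sc = .gauss_smoother(ncol(frame), sigma_small),
                      lr = .gauss_smoother(nrow(frame), sigma_large),
                      lc = .gauss_smoother(ncol(frame), sigma_large))
  }
  (smoothers$sr %*% frame %*% t(smoothers$sc)) -
    (smoothers$lr %*% frame %*% t(smoothers$lc))
}

# 8-neighborhood local maxima; plateaus resolved to the first pixel in
# column-major order by requiring strict inequality against the already
# visited half of the neighborhood.
.local_maxima <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- f
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ok <- ctr > sh(-1L, -1L) & ctr > sh(0L, -1L) & ctr > sh(1L, -1L) & ctr > sh(-1L, 0L) &
        ctr >= sh(1L, 0L) & ctr >= sh(-1L, 1L) & ctr >= sh(0L, 1L) & ctr >= sh(1L, 1L)
  which(ok, arr.ind = TRUE)
}

#' Detect candidate emitters in one frame
#'
#' Applies a difference-of-Gaussians band-pass filter and returns local
#' maxima (8-neighborhood) whose filtered value exceeds
#' `threshold_factor` times the robust noise scale of the filtered frame
#' (1.4826 x median absolute deviation). Candidates closer than
#' `roi_halfsize_px` to the frame border are dropped, because their fit
#' window would leave the frame.
#'
#' @param photon_frame 2-D photon image.
#' @param frame_index 1-based frame number recorded with each candidate.
#' @param dog_sigma_small_px,dog_sigma_large_px band-pass sigmas in pixels.
#' @param threshold_factor detection threshold in robust noise SDs.
#' @param roi_halfsize_px half-size of the fit window in pixels.
#' @param smoothers internal cache of smoothing matrices (per frame size).
#' @return data frame `frame,row,col,score`, sorted by descending score.
#' @export
detect_candidates <- function(photon_frame, frame_index = 1L,
                              dog_sigma_small_px = 1.0, dog_sigma_large_px = 2.5,
                              threshold_factor = 4.0, roi_halfsize_px = 3L,
                              smoothers = NULL) {
  if (dog_sigma_small_px <= 0 || dog_sigma_large_px <= 0 || threshold_factor <= 0)
    stop("detection sigmas and threshold_factor must be positive")
  h <- as.integer(roi_halfsize_px)
  if (nrow(photon_frame) < 2 * h + 1 || ncol(photon_frame) < 2 * h + 1)
    stop("frame smaller than the fit window")
  f <- .dog_filter(photon_frame, dog_sigma_small_px, dog_sigma_large_px, smoothers)
  noise <- mad(f)  # 1.4826 * MAD
  thr <- threshold_factor * noise
  mx <- .local_maxima(f)
  if (nrow(mx) == 0)
    return(data.frame(frame = integer(), row = integer(), col = integer(), score = numeric()))
  score <- f[mx]
  keep <- score > thr &
    mx[, 1] > h & mx[, 1] <= nrow(f) - h &
    mx[, 2] > h & mx[, 2] <= ncol(f) - h
  mx <- mx[keep, , drop = FALSE]
  score <- score[keep]
  ord <- order(-score, mx[, 1], mx[, 2])
  data.frame(frame = rep(as.integer(frame_index), nrow(mx)),
             row = as.integer(mx[ord, 1]),
             col = as.integer(mx[ord, 2]), score = score[ord])
}

# --- integrated-Gaussian Poisson MLE --------------------------------------

# Pixel-integrated Gaussian weights along one axis for pixel edges 0..s
# (ROI coordinates): Delta E_j = Phi((j - x0)/sigma) - Phi((j-1 - x0)/sigma).
.psf_edge_terms <- function(edges, x0, sigma) {
  u <- (edges - x0) / sigma
  list(dE = diff(pnorm(u)),
       d_dx0 = -diff(dnorm(u)) / sigma,
       d_dsig = -diff(u * dnorm(u)) / sigma)
}

#' Fit one spot by maximum likelihood
#'
#' Maximizes the Poisson log-likelihood of the integrated-Gaussian model
#' `mu_ij = N * dEx_j * dEy_i + b` over `(x0, y0, N, b, sigma)` on a square
#' ROI, by Levenberg-damped Fisher scoring with analytic derivatives.
#' `N`, `b` and `sigma` are optimized on the log scale, which enforces
#' positivity. With `var_over_gain2` supplied (per-pixel read-noise
#' variance divided by squared gain, in photon units), that map is added to
#' both the data and the model before evaluating the likelihood — the
#' standard Poisson-approximation treatment of sCMOS read noise; a zero map
#' reduces exactly to the pure-Poisson path.
#'
#' ROI coordinates place the left/top edge of the first pixel at 0, so the
#' center of the ROI's central pixel is at `(h + 0.5, h + 0.5)`.
#'
#' @param roi square photon image with odd side length.
#' @param init_xy optional initial center (ROI coordinates); defaults to a
#'   background-subtracted centroid.
#' @param initial_sigma_px starting PSF sigma, pixels.
#' @param max_iterations,tol iteration cap and relative-change tolerance.
#' @param var_over_gain2 optional per-pixel sCMOS variance map (photons^2).
#' @return list with `x0_px, y0_px, N, b, sigma_px, converged, loglik,
#'   iterations`.
#' @export
fit_spot_mle <- function(roi, init_xy = NULL, initial_sigma_px = 1.3,
                         max_iterations = 30L, tol = 1e-6,
                         var_over_gain2 = NULL) {
  if (!is.matrix(roi) || nrow(roi) != ncol(roi) || nrow(roi) %% 2L != 1L)
    stop("roi must be a square matrix with odd side length")
  if (any(!is.finite(roi))) stop("roi contains non-finite values")
  s <- nrow(roi)
  vg2 <- if (is.null(var_over_gain2)) matrix(0, s, s) else {
    stopifnot(identical(dim(var_over_gain2), dim(roi)))
    var_over_gain2
  }
  k <- as.numeric(roi + vg2)
  vg2v <- as.numeric(vg2)
  edges <- 0:s

  # initial values: border-median background, photon sum, centroid
  border <- c(roi[1, ], roi[s, ], roi[, 1], roi[, s])
  b0 <- max(median(border), 0.01)
  N0 <- max(sum(roi) - b0 * s^2, 10)
  if (is.null(init_xy)) {
    w <- pmax(roi - b0, 0)
    tw <- sum(w)
    ctr <- (s + 1) / 2  # center-pixel index
    if (tw > 0) {
      cx <- sum(w * matrix(rep(seq_len(s) - 0.5, each = s), s, s)) / tw
      cy <- sum(w * matrix(rep(seq_len(s) - 0.5, s), s, s)) / tw
      # keep the start within one pixel of the ROI center
      init_xy <- c(min(max(cx, ctr - 1.5), ctr + 0.5), min(max(cy, ctr - 1.5), ctr + 0.5))
    } else init_xy <- c(ctr - 0.5, ctr - 0.5)
  }

  theta <- c(init_xy[1], init_xy[2], log(N0), log(b0), log(initial_sigma_px))
  nll <- function(theta) {
    ex <- .psf_edge_terms(edges, theta[1], exp(theta[5]))
    ey <- .psf_edge_terms(edges, theta[2], exp(theta[5]))
    mu <- exp(theta[3]) * outer(ey$dE, ex$dE) + exp(theta[4]) + vg2
    mu <- pmax(as.numeric(mu), 1e-12)
    -sum(k * log(mu) - mu)
  }

  lambda <- 1e-3
  obj <- nll(theta)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    xg <- exp(theta[3]); bg <- exp(theta[4]); sg <- exp(theta[5])
    ex <- .psf_edge_terms(edges, theta[1], sg)
    ey <- .psf_edge_terms(edges, theta[2], sg)
    mu <- xg * outer(ey$dE, ex$dE) + bg + vg2
    mu <- pmax(as.numeric(mu), 1e-12)
    # Jacobian of mu w.r.t. (x0, y0, logN, logb, logsigma), pixels stacked
    J <- cbind(as.numeric(xg * outer(ey$dE, ex$d_dx0)),
               as.numeric(xg * outer(ey$d_dx0, ex$dE)),
               as.numeric(xg * outer(ey$dE, ex$dE)),
               rep(bg, length(mu)),
               as.numeric(xg * sg * (outer(ey$d_dsig, ex$dE) + outer(ey$dE, ex$d_dsig))))
    r <- k / mu - 1
    grad <- crossprod(J, r)                       # gradient of the log-likelihood
    FI <- crossprod(J, J / mu)                    # Fisher information
    step_ok <- FALSE
    for (inner in 1:10) {
      H <- FI + lambda * diag(pmax(diag(FI), 1e-12))
      delta <- tryCatch(solve(H, grad), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- theta + as.numeric(delta)
        cobj <- nll(cand)
        if (is.finite(cobj) && cobj <= obj + 1e-12) {
          theta <- cand; obj <- cobj
          lambda <- max(lambda / 3, 1e-10)
          step_ok <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) break
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  out <- list(x0_px = theta[1], y0_px = theta[2], N = exp(theta[3]),
              b = exp(theta[4]), sigma_px = exp(theta[5]),
              converged = converged, loglik = -obj, iterations = it)
  if (!all(is.finite(unlist(out[1:5])))) {
    out$converged <- FALSE
  }
  # reject fits that ran to an implausible geometry
  if (out$sigma_px > s || out$sigma_px < 0.1 ||
      out$x0_px < -1 || out$x0_px > s + 1 || out$y0_px < -1 || out$y0_px > s + 1)
    out$converged <- FALSE
  out
}

#' Theoretical localization precision
#'
#' Closed-form standard error of a maximum-likelihood position estimate
#' for a Gaussian PSF on a pixelated detector with uniform background
#' (Mortensen-style MLE approximation):
#' `sigma_loc^2 = (sigma_a^2 / N) * (16/9 + 8 pi sigma_a^2 b / (N a^2))`,
#' with `sigma_a^2 = sigma^2 + a^2 / 12`, `a` the pixel size, `N` the
#' fitted photon count and `b` the background photons per pixel.
#'
#' @param sigma_nm fitted PSF standard deviation, nm.
#' @param photons fitted photon count `N` (> 0).
#' @param background_photons fitted background per pixel.
#' @param pixel_size_nm camera pixel size, nm.
#' @return precision (standard error) in nm; vectorized.
#' @export
estimate_precision <- function(sigma_nm, photons, background_photons, pixel_size_nm) {
  if (any(photons <= 0)) stop("photons must be > 0")
  sa2 <- sigma_nm^2 + pixel_size_nm^2 / 12
  sqrt((sa2 / photons) * (16 / 9 + 8 * pi * sa2 * pmax(background_photons, 0) /
                            (photons * pixel_size_nm^2)))
}

#' Localize an entire movie
#'
#' Per frame: photon conversion, candidate detection, per-candidate MLE
#' fitting and precision estimation. Results are concatenated in frame
#' order; non-converged fits are flagged but retained until
#' [filter_localizations()]. Fits whose center lands more than one pixel
#' from their own candidate pixel are discarded (this also removes
#' duplicate fits of near-coincident candidates). The whole procedure is
#' deterministic.
#'
#' @param movie a [movie_stack()].
#' @param calib a [camera_calibration()]; per-pixel maps enable the sCMOS
#'   likelihood correction when `params$fit$use_scmos` is `TRUE`.
#' @param params a [sptpalm_params()] object.
#' @return localization data frame (`frame, x_nm, y_nm, sigma_nm, photons,
#'   background_photons, precision_nm, converged`), with attributes
#'   `source` and `params_hash`.
#' @export
localize_stack <- function(movie, calib = NULL, params = sptpalm_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  validate_params(params)
  if (is.null(calib))
    calib <- camera_calibration(params$camera$offset_adu, 0,
                                params$camera$e_per_adu, params$camera$qe)
  det <- params$detection
  fitp <- params$fit
  h <- as.integer(det$roi_halfsize_px)
  px <- movie$pixel_size_nm
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  smoothers <- list(sr = .gauss_smoother(nr, det$dog_sigma_small_px),
                    sc = .gauss_smoother(nc, det$dog_sigma_small_px),
                    lr = .gauss_smoother(nr, det$dog_sigma_large_px),
                    lc = .gauss_smoother(nc, det$dog_sigma_large_px))
  use_scmos <- isTRUE(fitp$use_scmos) && is.matrix(calib$variance)
  vg2_full <- if (use_scmos) calib$variance * (calib$e_per_adu / calib$qe)^2 else NULL

  out <- vector("list", n_frames(movie))
  for (fr in seq_len(n_frames(movie))) {
    ph <- adu_to_photons(movie$frames[, , fr], calib)
    cand <- detect_candidates(ph, fr, det$dog_sigma_small_px, det$dog_sigma_large_px,
                              det$threshold_factor, h, smoothers = smoothers)
    if (nrow(cand) == 0) next
    rows <- vector("list", nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      r0 <- cand$row[ci]; c0 <- cand$col[ci]
      roi <- ph[(r0 - h):(r0 + h), (c0 - h):(c0 + h)]
      vg2 <- if (use_scmos) vg2_full[(r0 - h):(r0 + h), (c0 - h):(c0 + h)] else NULL
      fit <- fit_spot_mle(roi, initial_sigma_px = fitp$initial_sigma_px,
                          max_iterations = fitp$max_iterations, tol = fitp$tol,
                          var_over_gain2 = vg2)
      ctr <- h + 0.5
      if (abs(fit$x0_px - ctr) > 1 || abs(fit$y0_px - ctr) > 1) next
      x_nm <- (c0 - h - 1 + fit$x0_px) * px
      y_nm <- (r0 - h - 1 + fit$y0_px) * px
      prec <- if (fit$N > 0)
        estimate_precision(fit$sigma_px * px, fit$N, fit$b, px) else NA_real_
      rows[[ci]] <- data.frame(frame = fr, x_nm = x_nm, y_nm = y_nm,
                               sigma_nm = fit$sigma_px * px, photons = fit$N,
                               background_photons = fit$b, precision_nm = prec,
                               converged = fit$converged)
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) > 0) out[[fr]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  locs <- if (length(out) > 0) do.call(rbind, out) else empty_localizations()
  rownames(locs) <- NULL
  attr(locs, "source") <- movie$source
  attr(locs, "params_hash") <- params_hash(params)
  locs
}

#' Filter localizations by fit quality
#'
#' Keeps converged localizations whose PSF sigma, photon count and
#' precision fall inside the requested ranges; order is preserved. The
#' number removed by each criterion is attached as attribute `removed`.
#'
#' @param locs localization data frame.
#' @param sigma_range_nm,photon_range,precision_max_nm quality windows.
#' @export
filter_localizations <- function(locs, sigma_range_nm = c(80, 250),
                                 photon_range = c(100, Inf),
                                 precision_max_nm = 50) {
  if (sigma_range_nm[1] > sigma_range_nm[2] || photon_range[1] > photon_range[2])
    stop("filter ranges must satisfy min <= max")
  conv <- locs$converged %in% TRUE
  ok_sigma <- conv & locs$sigma_nm >= sigma_range_nm[1] & locs$sigma_nm <= sigma_range_nm[2]
  ok_phot <- conv & locs$photons >= photon_range[1] & locs$photons <= photon_range[2]
  ok_prec <- conv & !is.na(locs$precision_nm) & locs$precision_nm <= precision_max_nm
  keep <- ok_sigma & ok_phot & ok_prec
  out <- locs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- attr(locs, "source")
  attr(out, "params_hash") <- attr(locs, "params_hash")
  attr(out, "removed") <- c(not_converged = sum(!conv),
                            sigma = sum(conv & !ok_sigma),
                            photons = sum(conv & !ok_phot),
                            precision = sum(conv & !ok_prec))
  out
}

# Freedman-Diaconis histogram clipped to the data range.
.fd_hist <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0)
    return(list(breaks = numeric(), counts = integer(), mids = numeric()))
  rng <- range(x)
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  bw <- 2 * iqr / length(x)^(1 / 3)
  if (!is.finite(bw) || bw <= 0 || rng[1] == rng[2]) {
    breaks <- c(rng[1] - 0.5, rng[2] + 0.5)
  } else {
    breaks <- seq(rng[1], rng[2] + bw, by = bw)
  }
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE, right = TRUE)))
  list(breaks = breaks, counts = counts, mids = (head(breaks, -1) + tail(breaks, -1)) / 2)
}

#' Quality-control histograms
#'
#' Binned distributions (Freedman-Diaconis rule, clipped to the data
#' range) of the three per-localization quality quantities: PSF sigma,
#' photons, and localization precision.
#'
#' @param locs localization data frame.
#' @return list of three histogram summaries (`sigma_nm`, `photons`,
#'   `precision_nm`), each with `breaks`, `counts`, `mids`.
#' @export
localization_histograms <- function(locs) {
  list(sigma_nm = .fd_hist(locs$sigma_nm),
       photons = .fd_hist(locs$photons),
       precision_nm = .fd_hist(locs$precision_nm))
}
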