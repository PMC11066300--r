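# Mobility analysis: per-track and ensemble mean-square displacement,
# diffusion coefficients from linear fits of the first few MSD points
# (2-D diffusion, D = slope/4), and decomposition of the log10(D)
# distribution into Gaussian populations.

#' Mean square displacement of one track
#'
#' `MSD(n dt)` is the mean over all ordered position pairs `(i, j)` whose
#' frame difference equals `n` of the squared displacement, in um^2. Frame
#' arithmetic (not index arithmetic) is used, so pairs spanning a bridged
#' blinking gap contribute at their true lag and no pairs are fabricated
#' for the missing frames. Lags run from 1 to
#' `min(max_lag, frame span)`; lags with no pairs are dropped.
#'
#' @param track data frame with `frame, x_nm, y_nm` for a single track.
#' @param frame_interval_s seconds per frame.
#' @param max_lag maximum lag in frames.
#' @return data frame `lag_frames, lag_s, msd_um2, n_pairs`.
#' @export
compute_msd <- function(track, frame_interval_s, max_lag = 10L) {
  if (nrow(track) < 2) stop("track must have at least 2 members")
  ord <- order(track$frame)
  f <- track$frame[ord]
  x <- track$x_nm[ord] / 1000  # um
  y <- track$y_nm[ord] / 1000
  span <- f[length(f)] - f[1]
  lags <- seq_len(min(max_lag, span))
  out <- lapply(lags, function(n) {
    j <- match(f + n, f)
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    data.frame(lag_frames = n, lag_s = n * frame_interval_s,
               msd_um2 = mean(d2), n_pairs = sum(ok))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(data.frame(lag_frames = integer(), lag_s = numeric(),
                      msd_um2 = numeric(), n_pairs = integer()))
  do.call(rbind, out)
}

#' Linear fit of an MSD curve
#'
#' Ordinary least squares of MSD versus time over the first
#' `n_fit_points` lags of the curve. The diffusion coefficient is
#' `D = slope / 4` (2-D diffusion in the membrane plane); the intercept is
#' free and absorbs the localization-error offset. The adjusted R^2 is
#' `1 - (1 - R^2) (m - 1) / (m - 2)` with `m = n_fit_points`.
#'
#' @param curve output of [compute_msd()].
#' @param n_fit_points number of leading lags to fit (>= 2).
#' @return list `D_um2_per_s, intercept_um2, adj_r2`.
#' @export
fit_msd_linear <- function(curve, n_fit_points = 4L) {
  m <- as.integer(n_fit_points)
  if (m < 2) stop("n_fit_points must be >= 2")
  if (nrow(curve) < m) stop("MSD curve has fewer lags than n_fit_points")
  t <- curve$lag_s[seq_len(m)]
  v <- curve$msd_um2[seq_len(m)]
  tm <- mean(t); vm <- mean(v)
  sxx <- sum((t - tm)^2)
  slope <- sum((t - tm) * (v - vm)) / sxx
  intercept <- vm - slope * tm
  ss_tot <- sum((v - vm)^2)
  ss_res <- sum((v - intercept - slope * t)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  adj_r2 <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (m - 1) / (m - 2)
  list(D_um2_per_s = slope / 4, intercept_um2 = intercept, adj_r2 = adj_r2)
}

.split_tracks <- function(tracks) split(tracks, tracks$track_id)

#' Ensemble mean MSD and its diffusion coefficient
#'
#' For each lag, the unweighted mean of the per-track MSD values over all
#' tracks that contribute that lag. Lags are retained from lag 1 upward
#' while at least 50% of the tracks contribute, which avoids noisy tail
#' lags dominated by the few longest tracks. `D_mean` comes from
#' [fit_msd_linear()] on the mean curve.
#'
#' @param tracks track data frame (>= 1 track with >= 2 members).
#' @param frame_interval_s seconds per frame.
#' @param n_fit_points leading lags for the fit.
#' @param max_lag maximum lag in frames.
#' @return list `curve` (mean MSD data frame with `n_tracks` per lag) and
#'   `fit` (list from [fit_msd_linear()]).
#' @export
mean_msd <- function(tracks, frame_interval_s, n_fit_points = 4L, max_lag = 10L) {
  per <- .split_tracks(tracks)
  per <- per[vapply(per, nrow, 0L) >= 2]
  if (length(per) == 0) stop("no eligible tracks for mean MSD")
  curves <- lapply(per, compute_msd, frame_interval_s = frame_interval_s, max_lag = max_lag)
  n_tracks <- length(curves)
  rows <- list()
  for (n in seq_len(max_lag)) {
    vals <- unlist(lapply(curves, function(cv) cv$msd_um2[cv$lag_frames == n]))
    if (length(vals) < 0.5 * n_tracks) break
    rows[[n]] <- data.frame(lag_frames = n, lag_s = n * frame_interval_s,
                            msd_um2 = mean(vals), n_tracks = length(vals))
  }
  if (length(rows) == 0) stop("no lag is shared by at least half of the tracks")
  curve <- do.call(rbind, rows)
  fit <- if (nrow(curve) >= n_fit_points) fit_msd_linear(curve, n_fit_points) else
    list(D_um2_per_s = NA_real_, intercept_um2 = NA_real_, adj_r2 = NA_real_)
  list(curve = curve, fit = fit)
}

#' Per-track diffusion coefficients
#'
#' Fits each track's MSD curve and classifies the result: `accepted`
#' requires an adjusted R^2 of at least `adj_r2_min` and a positive
#' diffusion coefficient. Tracks with a non-positive fitted slope have no
#' defined log10(D); they are reported separately and count as immobile in
#' [mobility_summary()]. Tracks with too few lags are flagged `too_short`.
#'
#' @param tracks track data frame.
#' @param frame_interval_s seconds per frame.
#' @param n_fit_points,max_lag MSD fitting controls.
#' @param adj_r2_min goodness-of-fit acceptance threshold.
#' @return data frame `track_id, D_um2_per_s, intercept_um2, adj_r2,
#'   accepted, reason` with attribute `rejected` (counts per reason).
#' @export
per_track_mobility <- function(tracks, frame_interval_s, n_fit_points = 4L,
                               max_lag = 10L, adj_r2_min = 0.7) {
  per <- .split_tracks(tracks)
  rows <- lapply(names(per), function(id) {
    tr <- per[[id]]
    base <- data.frame(track_id = as.integer(id), D_um2_per_s = NA_real_,
                       intercept_um2 = NA_real_, adj_r2 = NA_real_,
                       accepted = FALSE, reason = "too_short",
                       stringsAsFactors = FALSE)
    if (nrow(tr) < 2) return(base)
    curve <- compute_msd(tr, frame_interval_s, max_lag)
    if (nrow(curve) < n_fit_points) return(base)
    fit <- fit_msd_linear(curve, n_fit_points)
    base$D_um2_per_s <- fit$D_um2_per_s
    base$intercept_um2 <- fit$intercept_um2
    base$adj_r2 <- fit$adj_r2
    if (!is.na(fit$D_um2_per_s) && fit$D_um2_per_s <= 0) {
      base$reason <- "nonpositive_D"
    } else if (is.na(fit$adj_r2) || fit$adj_r2 < adj_r2_min) {
      base$reason <- "low_adj_r2"
    } else {
      base$accepted <- TRUE
      base$reason <- "accepted"
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rejected") <- table(factor(out$reason,
    levels = c("accepted", "low_adj_r2", "nonpositive_D", "too_short")))
  out
}

# ---- 1-D Gaussian mixture by EM ------------------------------------------

# Deterministic EM for a K-component 1-D Gaussian mixture. Started from a
# fixed set of quantile-based initializations (no RNG) and the best
# likelihood kept; component SDs floored at `sd_floor` to prevent
# degenerate spikes.
.gmm1d <- function(x, K, sd_floor = 0.05, max_iter = 500L, tol = 1e-9) {
  n <- length(x)
  loglik_of <- function(w, mu, sdv) {
    dens <- vapply(seq_len(K), function(k) w[k] * dnorm(x, mu[k], sdv[k]), numeric(n))
    if (K == 1) dens <- matrix(dens, ncol = 1)
    sum(log(pmax(rowSums(dens), 1e-300)))
  }
  run_em <- function(mu0) {
    w <- rep(1 / K, K)
    mu <- mu0
    sdv <- rep(max(sd(x) / K, sd_floor), K)
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k) w[k] * dnorm(x, mu[k], sdv[k]), numeric(n))
      if (K == 1) dens <- matrix(dens, ncol = 1)
      tot <- pmax(rowSums(dens), 1e-300)
      resp <- dens / tot
      nk <- colSums(resp)
      if (any(nk < 1e-8)) break
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sdv <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
      sdv <- pmax(sdv, sd_floor)
      ll_new <- sum(log(tot))
      if (is.finite(ll) && abs(ll_new - ll) < tol) { ll <- ll_new; break }
      ll <- ll_new
    }
    list(w = w, mu = mu, sd = sdv, loglik = loglik_of(w, mu, sdv))
  }
  inits <- if (K == 1) list(mean(x)) else {
    qs <- list(c(0.25, 0.75), c(0.10, 0.90), c(1 / 3, 2 / 3), c(0.20, 0.60), c(0.40, 0.80))
    lapply(qs, function(q) quantile(x, q, names = FALSE))
  }
  fits <- lapply(inits, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  ord <- order(best$mu)
  best$w <- best$w[ord]; best$mu <- best$mu[ord]; best$sd <- best$sd[ord]
  best$bic <- -2 * best$loglik + (3 * K - 1) * log(n)
  best
}

#' Decompose the log10(D) distribution into populations
#'
#' Fits Gaussian mixtures with 1 to `max_components` components to the
#' per-track `log10(D)` values by maximum likelihood (deterministic EM,
#' quantile-based starts, component SD floor 0.05) and selects the
#' component count by BIC. The "peak log(D)" reported per file is the mean
#' of the highest-weight component. `mobile_fraction` is the fraction of
#' the supplied values above `threshold_logD`; the pipeline-level summary
#' additionally counts tracks with non-positive fitted slope as immobile.
#'
#' @param logD_values per-track `log10(D)` values of accepted tracks
#'   (>= 10 values).
#' @param max_components 1 or 2.
#' @param threshold_logD mobile/immobile boundary (default -2, i.e.
#'   D = 0.01 um^2/s).
#' @return list `components` (data frame `weight, mean, sd`), `bic`,
#'   `peak_logD`, `mobile_fraction`.
#' @export
population_analysis <- function(logD_values, max_components = 2L, threshold_logD = -2) {
  x <- logD_values[is.finite(logD_values)]
  if (length(x) < 10)
    stop("population analysis needs at least 10 accepted tracks; aggregate more files")
  max_components <- max(1L, min(2L, as.integer(max_components)))
  fits <- lapply(seq_len(max_components), function(K) .gmm1d(x, K))
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- fits[[which.min(bics)]]
  comp <- data.frame(weight = best$w, mean = best$mu, sd = best$sd)
  list(components = comp,
       bic = best$bic,
       peak_logD = comp$mean[which.max(comp$weight)],
       mobile_fraction = mean(x > threshold_logD))
}

#' Full mobility summary for one file
#'
#' Combines [mean_msd()], [per_track_mobility()] and (given enough
#' accepted tracks) [population_analysis()]. The mobile fraction counts a
#' track as mobile when its `log10(D)` exceeds `threshold_logD`; tracks
#' rejected for a non-positive slope count as immobile, tracks rejected as
#' inconclusive (low adjusted R^2) are excluded from the fraction.
#'
#' @param tracks track data frame (after length filtering).
#' @param frame_interval_s seconds per frame.
#' @param n_fit_points,max_lag,adj_r2_min,threshold_logD,max_components
#'   analysis parameters, see [sptpalm_params()].
#' @return list `mean_msd`, `per_track`, `logD_values`, `population`,
#'   `D_mean_um2_per_s`, `peak_logD`, `mobile_fraction`.
#' @export
mobility_summary <- function(tracks, frame_interval_s, n_fit_points = 4L,
                             max_lag = 10L, adj_r2_min = 0.7,
                             threshold_logD = -2, max_components = 2L) {
  mm <- mean_msd(tracks, frame_interval_s, n_fit_points, max_lag)
  pt <- per_track_mobility(tracks, frame_interval_s, n_fit_points, max_lag, adj_r2_min)
  logD <- log10(pt$D_um2_per_s[pt$accepted])
  n_immobile_extra <- sum(pt$reason == "nonpositive_D")
  pop <- if (length(logD) >= 10)
    tryCatch(population_analysis(logD, max_components, threshold_logD),
             error = function(e) NULL) else NULL
  denom <- length(logD) + n_immobile_extra
  mobile_fraction <- if (denom > 0) sum(logD > threshold_logD) / denom else NA_real_
  list(mean_msd = mm, per_track = pt, logD_values = logD, population = pop,
       D_mean_um2_per_s = mm$fit$D_um2_per_s,
       peak_logD = if (!is.null(pop)) pop$peak_logD else NA_real_,
       mobile_fraction = mobile_fraction)
}

#' Write the per-track mobility table
#'
#' CSV `track_id,D_um2_per_s,intercept_um2,adj_r2,accepted`.
#'
#' @param mobility output of [per_track_mobility()].
#' @param path CSV file path.
#' @export
write_mobility_table <- function(mobility, path) {
  df <- mobility[, c("track_id", "D_um2_per_s", "intercept_um2", "adj_r2", "accepted")]
  write.csv(format(df, digits = 15, trim = TRUE), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
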