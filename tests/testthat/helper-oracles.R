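# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: brute-force enumeration for the
# assignment problem, queue-expansion DBSCAN, all-pairs box overlap with
# union-find, and a finite-difference Fisher information for the CRLB.

# Integrated-Gaussian spot on an s x s ROI (closed form, shared model).
render_spot <- function(s, x0, y0, N, b, sigma) {
  dEx <- diff(pnorm((0:s - x0) / sigma))
  dEy <- diff(pnorm((0:s - y0) / sigma))
  N * outer(dEy, dEx) + b
}

# CRLB of the x-coordinate from numerically differentiated Fisher
# information of the Poisson integrated-Gaussian model.
numerical_crlb_x <- function(s, x0, y0, N, b, sigma) {
  th <- c(x0, y0, N, b, sigma)
  mu_of <- function(th) as.numeric(render_spot(s, th[1], th[2], th[3], th[4], th[5]))
  mu <- mu_of(th)
  J <- matrix(0, length(mu), 5)
  for (p in 1:5) {
    h <- max(1e-6, abs(th[p]) * 1e-6)
    d <- rep(0, 5); d[p] <- h
    J[, p] <- (mu_of(th + d) - mu_of(th - d)) / (2 * h)
  }
  FI <- crossprod(J, J / mu)
  sqrt(diag(solve(FI)))[1]
}

# Minimum total cost over all feasible partial assignments between two
# point sets: cost = sum of squared link distances + alt_cost per
# unmatched point on either side; links allowed only within max_dist.
brute_force_assignment_cost <- function(xy1, xy2, max_dist, alt_cost = (1.05 * max_dist)^2) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  best <- Inf
  recurse <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n1) { best <<- min(best, cost + alt_cost * (n2 - sum(used))); return() }
    recurse(i + 1, used, cost + alt_cost)  # leave i unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && d2[i, j] <= max_dist^2) {
        used[j] <- TRUE
        recurse(i + 1, used, cost + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n2), 0)
  best
}

# Cost of the package's linking for one frame pair, under the same
# objective as the brute-force oracle.
linking_cost <- function(locs2frames, max_dist, alt_cost = (1.05 * max_dist)^2) {
  tr <- link_frames(locs2frames, tracking_params(max_dist, 0L))
  i1 <- which(locs2frames$frame == min(locs2frames$frame))
  i2 <- which(locs2frames$frame == max(locs2frames$frame))
  tr_of <- tr$track_id[order(tr$loc_index)]
  cost <- 0
  matched2 <- logical(length(i2))
  for (a in seq_along(i1)) {
    b <- which(tr_of[i2] == tr_of[i1[a]])
    if (length(b) == 1) {
      cost <- cost + (locs2frames$x_nm[i1[a]] - locs2frames$x_nm[i2[b]])^2 +
        (locs2frames$y_nm[i1[a]] - locs2frames$y_nm[i2[b]])^2
      matched2[b] <- TRUE
    } else cost <- cost + alt_cost
  }
  cost + alt_cost * sum(!matched2)
}

# Classic queue-expansion DBSCAN; labels 0 = noise. Border points join the
# first cluster that reaches them (lowest id, since clusters are grown in
# ascending core order).
dbscan_oracle <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d2 <- as.matrix(dist(xy))^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Two labelings describe the same partition-with-noise.
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  ok <- a > 0
  tab <- table(a[ok], b[ok])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# All-pairs expanded-bounding-box overlap graph over tracks, components by
# union-find; labels 0 for components below min_tracks.
nastic_oracle <- function(tracks, radius_factor, min_tracks) {
  ids <- unique(tracks$track_id)
  nt <- length(ids)
  box <- t(vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    cx <- mean(range(tr$x_nm)); cy <- mean(range(tr$y_nm))
    hx <- diff(range(tr$x_nm)) / 2 * radius_factor
    hy <- diff(range(tr$y_nm)) / 2 * radius_factor
    c(cx - hx, cx + hx, cy - hy, cy + hy)
  }, numeric(4)))
  parent <- seq_len(nt)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (j <= i) next
    if (box[i, 1] <= box[j, 2] && box[j, 1] <= box[i, 2] &&
        box[i, 3] <= box[j, 4] && box[j, 3] <= box[i, 4]) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(nt), find, 0L)
  sizes <- table(comp)
  labels <- ifelse(sizes[as.character(comp)] >= min_tracks, comp, 0L)
  as.integer(labels)
}

# Greedy globally-sorted matching of detections to ground-truth emissions
# within a gate; returns the fraction of ground-truth rows matched.
match_fraction <- function(gt, locs, gate_nm = 50) {
  matched <- 0L
  for (fr in unique(gt$frame)) {
    g <- gt[gt$frame == fr, ]
    l <- locs[locs$frame == fr, ]
    if (nrow(l) == 0) next
    d <- sqrt(outer(g$x_nm, l$x_nm, "-")^2 + outer(g$y_nm, l$y_nm, "-")^2)
    repeat {
      m <- which.min(d)
      if (d[m] > gate_nm) break
      matched <- matched + 1L
      gi <- (m - 1) %% nrow(d) + 1
      li <- (m - 1) %/% nrow(d) + 1
      d[gi, ] <- Inf; d[, li] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  matched / nrow(gt)
}
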