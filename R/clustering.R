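# Nanoscale spatial organization: Voronoi tessellation, DBSCAN and NASTIC
# cluster analysis with a uniform result container and metrics.
#
# All geometry is in nm internally; areas are reported in um^2.

#' Assemble input for cluster analysis
#'
#' Cluster analysis can run on (i) all filtered localizations, (ii) the
#' centroids of the assembled tracks (one point per detected protein;
#' generally preferred), or (iii) the tracks themselves (NASTIC only).
#' The analysis rectangle — needed by the Voronoi method to define the
#' average density and to flag boundary cells — is the tight bounding box
#' of the input expanded by 2% about its center.
#'
#' @param locs filtered localization data frame (for `mode = "locs"`).
#' @param tracks track data frame (for `"centroids"` and `"tracks"`).
#' @param mode one of `"locs"`, `"centroids"`, `"tracks"`.
#' @return list of class `cluster_input` with `mode`, `points`
#'   (`member_id, x_nm, y_nm`; for point modes), `tracks` (for NASTIC)
#'   and `rect` (`xmin, xmax, ymin, ymax`).
#' @export
make_cluster_input <- function(locs = NULL, tracks = NULL,
                               mode = c("centroids", "locs", "tracks")) {
  mode <- match.arg(mode)
  if (mode == "locs") {
    if (is.null(locs)) stop("mode 'locs' requires localizations")
    pts <- data.frame(member_id = seq_len(nrow(locs)), x_nm = locs$x_nm, y_nm = locs$y_nm)
    trk <- NULL
  } else {
    if (is.null(tracks) || nrow(tracks) == 0) stop("mode '", mode, "' requires tracks")
    if (mode == "centroids") {
      xs <- tapply(tracks$x_nm, tracks$track_id, mean)
      ys <- tapply(tracks$y_nm, tracks$track_id, mean)
      pts <- data.frame(member_id = as.integer(names(xs)),
                        x_nm = as.numeric(xs), y_nm = as.numeric(ys))
      trk <- NULL
    } else {
      pts <- NULL
      trk <- tracks
    }
  }
  xs <- if (is.null(pts)) trk$x_nm else pts$x_nm
  ys <- if (is.null(pts)) trk$y_nm else pts$y_nm
  cx <- mean(range(xs)); cy <- mean(range(ys))
  hw <- diff(range(xs)) / 2 * 1.02; hh <- diff(range(ys)) / 2 * 1.02
  structure(list(mode = mode, points = pts, tracks = trk,
                 rect = c(xmin = cx - hw, xmax = cx + hw,
                          ymin = cy - hh, ymax = cy + hh)),
            class = "cluster_input")
}

# Build the uniform result container. labels: integer per element, 0 =
# noise. element_type: "point" or "track".
.cluster_result <- function(algorithm, parameters, labels, element_type,
                            points = NULL, tracks = NULL, extra = list()) {
  ids <- sort(unique(labels[labels > 0]))
  # relabel clusters 1..k by first-appearing member
  if (length(ids) > 0) {
    first <- vapply(ids, function(id) min(which(labels == id)), 0L)
    remap <- integer(max(ids))
    remap[ids[order(first)]] <- seq_along(ids)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  res <- structure(list(algorithm = algorithm, parameters = parameters,
                        labels = labels, element_type = element_type,
                        points = points, tracks = tracks,
                        n_clusters = length(ids),
                        noise_ids = which(labels == 0),
                        clustered_fraction =
                          if (length(labels) > 0) mean(labels > 0) else NA_real_),
                   class = "cluster_result")
  res[names(extra)] <- extra
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result (%s): %d %ss, %d clusters, clustered fraction %.3f\n",
              x$algorithm, length(x$labels), x$element_type, x$n_clusters,
              x$clustered_fraction))
  invisible(x)
}

# ---- DBSCAN --------------------------------------------------------------

# eps-neighbor lists (including self) via grid bucketing; O(n * k).
.eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  cellx <- floor(x / eps); celly <- floor(y / eps)
  key <- paste(cellx, celly)
  buckets <- split(seq_len(n), key)
  nb <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cellx[i] + dx, celly[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    nb[[i]] <- cand[d2 <= eps2]
  }
  nb
}

#' DBSCAN cluster analysis
#'
#' Canonical density-based clustering: a point is a core point iff it has
#' at least `min_pts` neighbors within `eps_nm` (counting itself);
#' clusters are the density-connected components of core points plus their
#' border points. A border point reachable from several clusters is
#' assigned to the lowest cluster id, making the labeling deterministic.
#'
#' @param input a `cluster_input` in a point mode, or a data frame /
#'   matrix of `x_nm, y_nm`.
#' @param eps_nm neighborhood radius, nm.
#' @param min_pts minimum neighborhood size for a core point.
#' @return a `cluster_result` over points.
#' @export
cluster_dbscan <- function(input, eps_nm = 50, min_pts = 5L) {
  if (eps_nm <= 0 || min_pts < 1) stop("eps_nm must be > 0 and min_pts >= 1")
  pts <- if (inherits(input, "cluster_input")) {
    if (is.null(input$points)) stop("DBSCAN needs a point-mode cluster input")
    input$points
  } else data.frame(member_id = seq_len(nrow(input)),
                    x_nm = input[, 1], y_nm = input[, 2])
  n <- nrow(pts)
  params <- list(eps_nm = eps_nm, min_pts = as.integer(min_pts))
  if (n == 0)
    return(.cluster_result("dbscan", params, integer(0), "point", points = pts))
  nb <- .eps_neighbors(pts$x_nm, pts$y_nm, eps_nm)
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    core_idx <- which(core)
    # density-connected components of core points
    edges <- lapply(core_idx, function(i) {
      j <- nb[[i]]
      j <- j[core[j] & j > i]
      if (length(j) > 0) cbind(i, j) else NULL
    })
    edges <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
    comp <- igraph::components(g)$membership
    # provisional cluster ids ordered by first core member
    core_comp <- unique(comp[core_idx][order(core_idx)])
    labels[core_idx] <- match(comp[core_idx], core_comp)
    # border points: lowest reachable cluster id wins
    for (i in which(!core)) {
      cl <- labels[nb[[i]]]
      cl <- cl[cl > 0 & core[nb[[i]]]]
      if (length(cl) > 0) labels[i] <- min(cl)
    }
  }
  .cluster_result("dbscan", params, labels, "point", points = pts)
}

# ---- Voronoi tessellation ------------------------------------------------

#' Voronoi tessellation cluster analysis
#'
#' Builds the Voronoi tessellation of the points inside the analysis
#' rectangle. The local density of point i is averaged over its first-rank
#' neighborhood, `delta_i = (1 + |N(i)|) / (A_i + sum_{j in N(i)} A_j)`
#' with `A` the cell areas and `N(i)` the Voronoi neighbors of i; the
#' averaging suppresses the large cell-to-cell area fluctuations of a
#' random point pattern that would otherwise seed spurious clusters.
#' Points whose density is at least `density_factor` times the average
#' density `n / rectangle area` become seeds; cells touching the rectangle
#' boundary are excluded from seeding (their areas are truncated).
#' Clusters are connected components of seeds whose cells share an edge;
#' components smaller than `min_pts` are returned to noise.
#'
#' @param input a `cluster_input` in a point mode, or `x_nm, y_nm` data.
#' @param density_factor density threshold relative to the mean.
#' @param min_pts minimum seeds per retained cluster.
#' @return a `cluster_result` over points, with per-point `cell_area_nm2`
#'   and `density_factor_used` stored alongside.
#' @export
cluster_voronoi <- function(input, density_factor = 2, min_pts = 5L) {
  if (inherits(input, "cluster_input")) {
    if (is.null(input$points)) stop("Voronoi analysis needs a point-mode cluster input")
    pts <- input$points
    rect <- input$rect
  } else {
    pts <- data.frame(member_id = seq_len(nrow(input)),
                      x_nm = input[, 1], y_nm = input[, 2])
    rect <- make_cluster_input(locs = data.frame(x_nm = pts$x_nm, y_nm = pts$y_nm),
                               mode = "locs")$rect
  }
  n <- nrow(pts)
  if (n < 4) stop("Voronoi analysis needs at least 4 points")
  # degenerate geometry: all points collinear
  if (sd(pts$x_nm) == 0 || sd(pts$y_nm) == 0 ||
      abs(stats::cor(pts$x_nm, pts$y_nm)) > 1 - 1e-12)
    stop("degenerate geometry: points are collinear")
  cells <- .voronoi_cells_cpp(pts$x_nm, pts$y_nm,
                              rect["xmin"], rect["xmax"], rect["ymin"], rect["ymax"])
  rect_area <- (rect["xmax"] - rect["xmin"]) * (rect["ymax"] - rect["ymin"])
  dens <- vapply(seq_len(n), function(i) {
    j <- c(i, cells$neighbors[[i]])
    length(j) / sum(cells$area[j])
  }, 0)
  mean_dens <- n / rect_area
  seed <- !cells$on_boundary & is.finite(dens) & dens >= density_factor * mean_dens
  labels <- integer(n)
  if (any(seed)) {
    seed_idx <- which(seed)
    edges <- lapply(seed_idx, function(i) {
      j <- cells$neighbors[[i]]
      j <- j[seed[j] & j > i]
      if (length(j) > 0) cbind(i, j) else NULL
    })
    edges <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
    comp <- igraph::components(g)$membership
    labels[seed_idx] <- comp[seed_idx]
    keep <- as.integer(names(which(table(labels[labels > 0]) >= min_pts)))
    labels[!(labels %in% keep)] <- 0L
  }
  .cluster_result("voronoi",
                  list(density_factor = density_factor, min_pts = as.integer(min_pts)),
                  labels, "point", points = pts,
                  extra = list(cell_area_nm2 = cells$area,
                               cell_on_boundary = cells$on_boundary))
}

# ---- NASTIC --------------------------------------------------------------

# Expanded axis-aligned bounding boxes per track.
.track_boxes <- function(tracks, radius_factor) {
  ids <- unique(tracks$track_id)
  per <- split(tracks, tracks$track_id)[as.character(ids)]
  boxes <- t(vapply(per, function(tr) {
    cx <- mean(range(tr$x_nm)); cy <- mean(range(tr$y_nm))
    hx <- diff(range(tr$x_nm)) / 2 * radius_factor
    hy <- diff(range(tr$y_nm)) / 2 * radius_factor
    c(cx - hx, cx + hx, cy - hy, cy + hy, min(tr$frame), max(tr$frame))
  }, numeric(6)))
  colnames(boxes) <- c("xmin", "xmax", "ymin", "ymax", "fmin", "fmax")
  list(ids = ids, boxes = boxes)
}

# All intersecting box pairs by plane sweep over x (sorted xmin; a pair is
# examined only while xmin_j <= xmax_i), expected O(n log n) for sparse
# layouts. Intervals touching at the boundary count as overlapping.
.box_overlap_pairs <- function(boxes) {
  nb <- nrow(boxes)
  if (nb < 2) return(matrix(integer(0), ncol = 2))
  ord <- order(boxes[, "xmin"])
  pairs <- list()
  np <- 0L
  for (a in seq_len(nb - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):nb) {
      j <- ord[b]
      if (boxes[j, "xmin"] > boxes[i, "xmax"]) break
      if (boxes[j, "ymin"] <= boxes[i, "ymax"] && boxes[j, "ymax"] >= boxes[i, "ymin"]) {
        np <- np + 1L
        pairs[[np]] <- c(min(i, j), max(i, j))
      }
    }
  }
  if (np == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

#' NASTIC cluster analysis of trajectories
#'
#' Nanoscale spatiotemporal indexing clustering: each track is reduced to
#' the axis-aligned bounding box of its localizations, expanded about its
#' center by `radius_factor` in both dimensions; tracks whose expanded
#' boxes overlap are connected, and clusters are the connected components
#' with at least `min_tracks` tracks. With `temporal_window_s` set, two
#' tracks are additionally required to be within that time of each other
#' (gap between their frame intervals). Overlaps are found by a plane
#' sweep over sorted box edges (expected O(n log n)); the result is
#' identical to checking all pairs.
#'
#' @param tracks track data frame, or a `cluster_input` with
#'   `mode = "tracks"`.
#' @param radius_factor box expansion factor.
#' @param min_tracks minimum tracks per cluster.
#' @param temporal_window_s optional temporal gate, seconds (`NA` = off).
#' @param frame_interval_s needed when `temporal_window_s` is set.
#' @return a `cluster_result` over tracks (`labels` follow the order of
#'   `unique(tracks$track_id)`).
#' @export
cluster_nastic <- function(tracks, radius_factor = 1.2, min_tracks = 3L,
                           temporal_window_s = NA_real_, frame_interval_s = NULL) {
  if (inherits(tracks, "cluster_input")) {
    if (tracks$mode != "tracks") stop("NASTIC requires a cluster input with mode = 'tracks'")
    tracks <- tracks$tracks
  }
  if (is.null(tracks) || nrow(tracks) == 0)
    return(.cluster_result("nastic",
                           list(radius_factor = radius_factor, min_tracks = as.integer(min_tracks),
                                temporal_window_s = temporal_window_s),
                           integer(0), "track", tracks = tracks))
  tb <- .track_boxes(tracks, radius_factor)
  nt <- length(tb$ids)
  pairs <- .box_overlap_pairs(tb$boxes)
  if (!is.na(temporal_window_s) && nrow(pairs) > 0) {
    if (is.null(frame_interval_s)) stop("temporal_window_s requires frame_interval_s")
    gap_frames <- pmax(tb$boxes[pairs[, 2], "fmin"] - tb$boxes[pairs[, 1], "fmax"],
                       tb$boxes[pairs[, 1], "fmin"] - tb$boxes[pairs[, 2], "fmax"], 0)
    pairs <- pairs[gap_frames * frame_interval_s <= temporal_window_s, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(nt, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, as.vector(t(pairs)))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  labels <- ifelse(sizes[as.character(comp)] >= min_tracks, comp, 0L)
  .cluster_result("nastic",
                  list(radius_factor = radius_factor, min_tracks = as.integer(min_tracks),
                       temporal_window_s = temporal_window_s),
                  as.integer(labels), "track", tracks = tracks,
                  extra = list(track_ids = tb$ids, boxes = tb$boxes))
}

# ---- metrics -------------------------------------------------------------

.hull_area_nm2 <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  k2 <- c(seq_along(h)[-1], 1L)
  abs(sum(hx * hy[k2] - hx[k2] * hy)) / 2
}

#' Per-cluster metrics and global summary
#'
#' For each cluster: member count, centroid, convex-hull area (exact
#' polygon area; 0 for degenerate clusters of fewer than 3 non-collinear
#' members) and the equivalent-circle diameter `2 sqrt(area / pi)`. For
#' NASTIC results metrics are computed on the union of the member tracks'
#' localizations.
#'
#' @param result a `cluster_result`.
#' @return list `clusters` (data frame `cluster_id, n_members, centroid_x_nm,
#'   centroid_y_nm, area_um2, diameter_nm, degenerate`) and `summary`
#'   (`n_clusters, median_diameter_nm, clustered_fraction`).
#' @export
cluster_metrics <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  ids <- seq_len(result$n_clusters)
  rows <- lapply(ids, function(cl) {
    if (result$element_type == "point") {
      sel <- result$labels == cl
      xs <- result$points$x_nm[sel]; ys <- result$points$y_nm[sel]
      nm <- sum(sel)
    } else {
      tids <- result$track_ids[result$labels == cl]
      sel <- result$tracks$track_id %in% tids
      xs <- result$tracks$x_nm[sel]; ys <- result$tracks$y_nm[sel]
      nm <- length(tids)
    }
    a <- .hull_area_nm2(xs, ys)
    data.frame(cluster_id = cl, n_members = nm,
               centroid_x_nm = mean(xs), centroid_y_nm = mean(ys),
               area_um2 = a / 1e6, diameter_nm = 2 * sqrt(a / pi),
               degenerate = a <= 0)
  })
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), n_members = integer(),
               centroid_x_nm = numeric(), centroid_y_nm = numeric(),
               area_um2 = numeric(), diameter_nm = numeric(), degenerate = logical())
  list(clusters = clusters,
       summary = list(n_clusters = result$n_clusters,
                      median_diameter_nm = if (nrow(clusters) > 0)
                        median(clusters$diameter_nm) else NA_real_,
                      clustered_fraction = result$clustered_fraction))
}

#' Write cluster results
#'
#' Two CSVs (`<stem>_members.csv`: `member_id,cluster_id`;
#' `<stem>_clusters.csv`: per-cluster metrics) plus a JSON sidecar
#' (`<stem>_params.json`) echoing the algorithm and its parameters.
#'
#' @param result a `cluster_result`.
#' @param stem output path prefix.
#' @export
write_cluster_result <- function(result, stem) {
  member_id <- if (result$element_type == "point") result$points$member_id else result$track_ids
  write.csv(data.frame(member_id = member_id, cluster_id = result$labels),
            paste0(stem, "_members.csv"), row.names = FALSE, quote = FALSE)
  met <- cluster_metrics(result)
  write.csv(format(met$clusters, digits = 10, trim = TRUE),
            paste0(stem, "_clusters.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(algorithm = result$algorithm), result$parameters),
                       paste0(stem, "_params.json"), auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(stem)
}
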