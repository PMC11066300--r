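# Trajectory building: globally optimal frame-to-frame linking and gap
# closing, both posed as linear assignment problems.
#
# A min-cost assignment with squared-distance link costs and a fixed
# non-link (birth/death) alternative cost b for every unmatched point is
# equivalent to a maximum-weight bipartite matching with edge weights
# w = 2*b - d^2 on distance-gated edges: total cost =
# b*(n1 + n2) - sum_matched(2*b - d^2). The matching is solved exactly
# with igraph's maximum-weight bipartite matcher.

# Match points xy1 (rows) to xy2 within max_dist; returns for every row of
# xy1 the matched row of xy2 or NA. Ties are broken deterministically by a
# tiny index-ordered weight perturbation.
.lap_match <- function(xy1, xy2, max_dist, alt_cost = (1.05 * max_dist)^2) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  ok <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(ok) == 0) return(rep(NA_integer_, n1))
  w <- 2 * alt_cost - d2[ok]
  # deterministic tie-break: prefer links between lower indices
  eps <- alt_cost * 1e-9
  w <- w - eps * ((ok[, 1] - 1) * n2 + (ok[, 2] - 1)) / (n1 * n2)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n1), rep(TRUE, n2)),
                                    as.vector(t(cbind(ok[, 1], n1 + ok[, 2]))))
  m <- igraph::max_bipartite_match(g, weights = w)
  match1 <- m$matching[seq_len(n1)]
  out <- ifelse(is.na(match1), NA_integer_, as.integer(match1) - n1)
  out
}

#' Tracking parameters
#'
#' Convenience constructor; identical to `sptpalm_params()$tracking`.
#'
#' @param max_link_distance_nm maximum frame-to-frame displacement.
#' @param max_gap_frames number of missed frames that gap closing may
#'   bridge (0 disables gap closing).
#' @param max_gap_distance_nm maximum displacement across a bridged gap.
#' @param min_track_length minimum localizations per retained track.
#' @export
tracking_params <- function(max_link_distance_nm = 500, max_gap_frames = 1L,
                            max_gap_distance_nm = max_link_distance_nm,
                            min_track_length = 8L) {
  if (max_link_distance_nm <= 0 || max_gap_distance_nm <= 0)
    stop("link distances must be > 0")
  if (max_gap_frames < 0) stop("max_gap_frames must be >= 0")
  if (min_track_length < 2) stop("min_track_length must be >= 2")
  list(max_link_distance_nm = max_link_distance_nm,
       max_gap_frames = as.integer(max_gap_frames),
       max_gap_distance_nm = max_gap_distance_nm,
       min_track_length = as.integer(min_track_length))
}

# internal track representation: data.frame(track_id, frame, x_nm, y_nm,
# loc_index) ordered by (track_id, frame).
.as_tracks <- function(df) {
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Link localizations frame-to-frame
#'
#' For every consecutive frame pair, solves the linear assignment problem
#' to global optimality: squared-distance costs for candidate links within
#' `max_link_distance_nm`, against a fixed non-link alternative cost of
#' `(1.05 * max_link_distance_nm)^2`. Every localization ends up in
#' exactly one segment (possibly a singleton). Deterministic given input
#' order.
#'
#' @param locs localization data frame sorted by frame.
#' @param p [tracking_params()].
#' @return track data frame `track_id, frame, x_nm, y_nm, loc_index`
#'   (segments, before gap closing), grouped by track and ordered by frame.
#' @export
link_frames <- function(locs, p = tracking_params()) {
  n <- nrow(locs)
  if (n == 0)
    return(.as_tracks(data.frame(track_id = integer(), frame = integer(),
                                 x_nm = numeric(), y_nm = numeric(),
                                 loc_index = integer())))
  if (is.unsorted(locs$frame)) stop("localizations must be sorted by frame")
  succ <- rep(NA_integer_, n)
  frames <- sort(unique(locs$frame))
  idx_by_frame <- split(seq_len(n), locs$frame)
  for (fi in seq_len(length(frames) - 1L)) {
    if (frames[fi + 1L] != frames[fi] + 1L) next
    i1 <- idx_by_frame[[as.character(frames[fi])]]
    i2 <- idx_by_frame[[as.character(frames[fi + 1L])]]
    m <- .lap_match(cbind(locs$x_nm[i1], locs$y_nm[i1]),
                    cbind(locs$x_nm[i2], locs$y_nm[i2]),
                    p$max_link_distance_nm)
    linked <- which(!is.na(m))
    succ[i1[linked]] <- i2[m[linked]]
  }
  # walk successor chains to assign segment ids in first-appearance order
  track_id <- rep(NA_integer_, n)
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  next_id <- 0L
  for (i in seq_len(n)) {
    if (has_pred[i]) next
    next_id <- next_id + 1L
    j <- i
    while (!is.na(j)) { track_id[j] <- next_id; j <- succ[j] }
  }
  .as_tracks(data.frame(track_id = track_id, frame = locs$frame,
                        x_nm = locs$x_nm, y_nm = locs$y_nm,
                        loc_index = seq_len(n)))
}

#' Close short detection gaps
#'
#' Bridges fluorophore blinking: solves a second global assignment between
#' segment ends and later segment starts with a frame gap between 2 and
#' `max_gap_frames + 1` and a displacement of at most
#' `max_gap_distance_nm` (squared-distance cost, non-link alternative
#' `(1.05 * max_gap_distance_nm)^2`). Accepted pairs are concatenated; no
#' positions are fabricated for the bridged frames. Bridged frame indices
#' are recorded in the `gaps` attribute.
#'
#' @param segments output of [link_frames()].
#' @param p [tracking_params()].
#' @export
close_gaps <- function(segments, p = tracking_params()) {
  if (p$max_gap_frames < 1L || nrow(segments) == 0) {
    attr(segments, "gaps") <- list()
    return(segments)
  }
  ids <- unique(segments$track_id)
  first <- match(ids, segments$track_id)
  lastrev <- nrow(segments) + 1L - match(ids, rev(segments$track_id))
  ends <- segments[lastrev, ]
  starts <- segments[first, ]
  ns <- length(ids)
  # candidate pairs gated by frame gap and distance
  gap <- outer(ends$frame, starts$frame, function(a, b) b - a)
  d2 <- outer(ends$x_nm, starts$x_nm, "-")^2 + outer(ends$y_nm, starts$y_nm, "-")^2
  allowed <- gap >= 2 & gap <= p$max_gap_frames + 1L & d2 <= p$max_gap_distance_nm^2
  succ_seg <- rep(NA_integer_, ns)
  if (any(allowed)) {
    alt <- (1.05 * p$max_gap_distance_nm)^2
    ok <- which(allowed, arr.ind = TRUE)
    w <- 2 * alt - d2[ok]
    w <- w - alt * 1e-9 * ((ok[, 1] - 1) * ns + (ok[, 2] - 1)) / (ns * ns)
    g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), each = ns),
                                      as.vector(t(cbind(ok[, 1], ns + ok[, 2]))))
    m <- igraph::max_bipartite_match(g, weights = w)
    ms <- m$matching[seq_len(ns)]
    succ_seg <- ifelse(is.na(ms), NA_integer_, as.integer(ms) - ns)
  }
  # concatenate chains end -> start
  has_pred <- rep(FALSE, ns)
  has_pred[succ_seg[!is.na(succ_seg)]] <- TRUE
  new_id <- rep(NA_integer_, ns)
  gaps <- list()
  next_id <- 0L
  for (si in seq_len(ns)) {
    if (has_pred[si]) next
    next_id <- next_id + 1L
    j <- si
    bridged <- integer()
    while (!is.na(j)) {
      new_id[j] <- next_id
      nj <- succ_seg[j]
      if (!is.na(nj)) {
        fe <- ends$frame[j]; fs <- starts$frame[nj]
        if (fs - fe > 1L) bridged <- c(bridged, seq.int(fe + 1L, fs - 1L))
      }
      j <- nj
    }
    gaps[[next_id]] <- bridged
  }
  out <- segments
  out$track_id <- new_id[match(segments$track_id, ids)]
  out <- .as_tracks(out)
  attr(out, "gaps") <- gaps
  out
}

#' Remove tracks touching excluded regions
#'
#' Drops every track having at least one member whose containing pixel is
#' excluded by the mask (e.g. extracellular areas). Members falling
#' outside the mask grid count as excluded.
#'
#' @param tracks track data frame.
#' @param mask logical matrix aligned to the movie frame grid.
#' @param pixel_size_nm camera pixel size, nm.
#' @export
apply_mask <- function(tracks, mask, pixel_size_nm) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (nrow(tracks) == 0) { attr(tracks, "n_removed") <- 0L; return(tracks) }
  col <- floor(tracks$x_nm / pixel_size_nm) + 1L
  row <- floor(tracks$y_nm / pixel_size_nm) + 1L
  inside <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
  ok <- inside
  ok[inside] <- mask[cbind(row[inside], col[inside])]
  bad_tracks <- unique(tracks$track_id[!ok])
  out <- tracks[!(tracks$track_id %in% bad_tracks), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gaps") <- attr(tracks, "gaps")
  attr(out, "n_removed") <- length(bad_tracks)
  out
}

#' Keep tracks with a minimum number of localizations
#'
#' Short tracks (fewer than `min_track_length` localizations) are
#' background artifacts and are removed before mobility analysis.
#' Surviving tracks are re-indexed consecutively in order of first
#' appearance.
#'
#' @param tracks track data frame.
#' @param min_track_length minimum localizations per track.
#' @export
filter_tracks <- function(tracks, min_track_length = 8L) {
  if (nrow(tracks) == 0) return(tracks)
  counts <- table(tracks$track_id)
  keep_ids <- as.integer(names(counts))[counts >= min_track_length]
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  old_gaps <- attr(tracks, "gaps")
  kept_order <- unique(out$track_id)
  out$track_id <- match(out$track_id, kept_order)
  rownames(out) <- NULL
  if (!is.null(old_gaps) && length(old_gaps) > 0)
    attr(out, "gaps") <- old_gaps[kept_order]
  out
}

#' Read and write track tables
#'
#' CSV `track_id,frame,x_nm,y_nm`, grouped by track with frames ascending;
#' the round trip preserves the track partition exactly.
#'
#' @param tracks track data frame.
#' @param path CSV file path.
#' @export
write_track_table <- function(tracks, path) {
  df <- as.data.frame(tracks)[, c("track_id", "frame", "x_nm", "y_nm"), drop = FALSE]
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stop("cannot read track table: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_nm", "y_nm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("track table is missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$track_id <- as.integer(df$track_id)
  df$frame <- as.integer(df$frame)
  df$x_nm <- as.numeric(df$x_nm)
  df$y_nm <- as.numeric(df$y_nm)
  if (any(!complete.cases(df))) stop("malformed rows in track table: ", path)
  .as_tracks(df)
}

#' Build tracks from localizations in one call
#'
#' Convenience wrapper: [link_frames()], [close_gaps()], optional
#' [apply_mask()], then [filter_tracks()].
#'
#' @param locs filtered localization data frame.
#' @param p [tracking_params()].
#' @param mask optional logical matrix.
#' @param pixel_size_nm required when `mask` is given.
#' @export
build_tracks <- function(locs, p = tracking_params(), mask = NULL, pixel_size_nm = NULL) {
  tracks <- close_gaps(link_frames(locs, p), p)
  if (!is.null(mask)) {
    if (is.null(pixel_size_nm)) stop("pixel_size_nm is required with a mask")
    tracks <- apply_mask(tracks, mask, pixel_size_nm)
  }
  filter_tracks(tracks, p$min_track_length)
}
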