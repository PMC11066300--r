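# Batch processing: run the complete pipeline over file lists with one
# frozen parameter set and collect per-file summaries plus the full
# parameter snapshot in a single re-readable artifact (FAIR traceability).

#' Describe one batch input
#'
#' @param movie TIFF path (or an in-memory [movie_stack()]).
#' @param dark optional dark-noise TIFF path (or [movie_stack()]) for
#'   camera calibration.
#' @param mask optional mask TIFF path (or logical matrix).
#' @param frame_interval_s optional per-file override of the frame
#'   interval.
#' @export
batch_item <- function(movie, dark = NULL, mask = NULL, frame_interval_s = NA_real_) {
  if (is.character(movie) && !file.exists(movie))
    stop("movie file not found: ", movie)
  structure(list(movie = movie, dark = dark, mask = mask,
                 frame_interval_s = frame_interval_s),
            class = "batch_item")
}

.summary_cols <- c("file", "n_localizations", "n_localizations_filtered",
                   "n_tracks", "n_tracks_min_length", "D_mean_um2_per_s",
                   "peak_logD", "mobile_fraction", "n_clusters",
                   "median_diameter_nm", "clustered_fraction", "qc_flags")

.empty_summary_row <- function(file) {
  data.frame(file = file, n_localizations = NA_integer_,
             n_localizations_filtered = NA_integer_, n_tracks = NA_integer_,
             n_tracks_min_length = NA_integer_, D_mean_um2_per_s = NA_real_,
             peak_logD = NA_real_, mobile_fraction = NA_real_,
             n_clusters = NA_integer_, median_diameter_nm = NA_real_,
             clustered_fraction = NA_real_, qc_flags = "",
             stringsAsFactors = FALSE)
}

#' Run the pipeline on a single file
#'
#' Executes localize -> filter -> track -> mask -> length filter ->
#' mobility -> cluster, honoring the stage toggles in `params$batch`.
#' Failures in any stage produce a `qc_flags` entry and `NA` summary
#' fields instead of an error, so that one bad file cannot abort a batch.
#'
#' @param item a [batch_item()].
#' @param params a [sptpalm_params()].
#' @param out_dir optional directory for per-file CSV artifacts.
#' @return one-row summary data frame (see [run_batch()]); the full
#'   intermediate objects are attached as attribute `artifacts`.
#' @export
run_pipeline_single <- function(item, params = sptpalm_params(), out_dir = NULL) {
  validate_params(params)
  name <- if (is.character(item$movie)) basename(item$movie) else "<memory>"
  row <- .empty_summary_row(if (is.character(item$movie)) item$movie else "<memory>")
  flags <- character(0)
  arts <- list()
  stem <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(out_dir, sub("\\.[^.]+$", "", name))
  } else NULL

  fi <- if (!is.na(item$frame_interval_s)) item$frame_interval_s else
    params$camera$frame_interval_s

  movie <- tryCatch({
    if (inherits(item$movie, "movie_stack")) item$movie else
      read_movie_stack(item$movie, params$camera$pixel_size_nm, fi)
  }, error = function(e) e)
  if (inherits(movie, "error")) {
    row$qc_flags <- paste0("read_error: ", conditionMessage(movie))
    return(row)
  }

  calib <- tryCatch({
    if (is.null(item$dark)) {
      camera_calibration(params$camera$offset_adu, 0,
                         params$camera$e_per_adu, params$camera$qe)
    } else {
      dark <- if (inherits(item$dark, "movie_stack")) item$dark else
        read_movie_stack(item$dark, params$camera$pixel_size_nm, fi)
      calibrate_camera(dark, params$camera$e_per_adu, params$camera$qe)
    }
  }, error = function(e) e)
  if (inherits(calib, "error")) {
    row$qc_flags <- paste0("calibration_error: ", conditionMessage(calib))
    return(row)
  }

  res <- tryCatch({
    locs <- localize_stack(movie, calib, params)
    row$n_localizations <- nrow(locs)
    flocs <- filter_localizations(locs, params$filter$sigma_range_nm,
                                  params$filter$photon_range,
                                  params$filter$precision_max_nm)
    row$n_localizations_filtered <- nrow(flocs)
    arts$localizations <- flocs
    if (!is.null(stem)) write_localization_table(flocs, paste0(stem, "_locs.csv"))
    if (nrow(flocs) == 0) flags <- c(flags, "no_localizations")
    list(row = row, flags = flags, locs = flocs)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    row$qc_flags <- paste0("localization_error: ", conditionMessage(res))
    return(row)
  }
  row <- res$row; flags <- res$flags; flocs <- res$locs

  tracks <- NULL
  if (isTRUE(params$batch$do_tracking) && nrow(flocs) > 0) {
    tr <- tryCatch({
      tp <- tracking_params(params$tracking$max_link_distance_nm,
                            params$tracking$max_gap_frames,
                            params$tracking$max_gap_distance_nm,
                            params$tracking$min_track_length)
      all_tracks <- close_gaps(link_frames(flocs, tp), tp)
      if (!is.null(item$mask)) {
        mask <- if (is.matrix(item$mask)) item$mask else read_region_mask(item$mask)
        all_tracks <- apply_mask(all_tracks, mask, params$camera$pixel_size_nm)
      }
      kept <- filter_tracks(all_tracks, tp$min_track_length)
      list(all = all_tracks, kept = kept)
    }, error = function(e) e)
    if (inherits(tr, "error")) {
      flags <- c(flags, paste0("tracking_error: ", conditionMessage(tr)))
    } else {
      row$n_tracks <- length(unique(tr$all$track_id))
      row$n_tracks_min_length <- length(unique(tr$kept$track_id))
      tracks <- tr$kept
      arts$tracks <- tracks
      if (!is.null(stem)) write_track_table(tracks, paste0(stem, "_tracks.csv"))
      if (nrow(tracks) == 0) flags <- c(flags, "no_tracks")
    }
  }

  if (isTRUE(params$batch$do_mobility) && !is.null(tracks) && nrow(tracks) > 0) {
    mob <- tryCatch(
      mobility_summary(tracks, fi, params$mobility$n_fit_points,
                       params$mobility$max_lag, params$mobility$adj_r2_min,
                       params$mobility$threshold_logD, params$mobility$max_components),
      error = function(e) e)
    if (inherits(mob, "error")) {
      flags <- c(flags, paste0("mobility_error: ", conditionMessage(mob)))
    } else {
      row$D_mean_um2_per_s <- mob$D_mean_um2_per_s
      row$peak_logD <- mob$peak_logD
      row$mobile_fraction <- mob$mobile_fraction
      arts$mobility <- mob
      if (!is.null(stem)) write_mobility_table(mob$per_track, paste0(stem, "_mobility.csv"))
      if (is.null(mob$population)) flags <- c(flags, "too_few_tracks_for_populations")
    }
  }

  if (isTRUE(params$batch$do_clustering) && !is.null(tracks) && nrow(tracks) > 0) {
    clu <- tryCatch({
      cp <- params$clustering
      result <- switch(cp$algorithm,
        nastic = cluster_nastic(make_cluster_input(tracks = tracks, mode = "tracks"),
                                cp$nastic_radius_factor, cp$nastic_min_tracks,
                                cp$nastic_temporal_window_s, fi),
        dbscan = cluster_dbscan(make_cluster_input(locs = flocs, tracks = tracks,
                                                   mode = cp$input_mode),
                                cp$dbscan_eps_nm, cp$dbscan_min_pts),
        voronoi = cluster_voronoi(make_cluster_input(locs = flocs, tracks = tracks,
                                                     mode = cp$input_mode),
                                  cp$voronoi_density_factor, cp$voronoi_min_pts))
      result
    }, error = function(e) e)
    if (inherits(clu, "error")) {
      flags <- c(flags, paste0("clustering_error: ", conditionMessage(clu)))
    } else {
      met <- cluster_metrics(clu)
      row$n_clusters <- met$summary$n_clusters
      row$median_diameter_nm <- met$summary$median_diameter_nm
      row$clustered_fraction <- met$summary$clustered_fraction
      arts$clusters <- clu
      if (!is.null(stem)) write_cluster_result(clu, paste0(stem, "_cluster"))
    }
  }

  row$qc_flags <- paste(flags, collapse = "; ")
  attr(row, "artifacts") <- arts
  row
}

#' Run the pipeline over many files
#'
#' Applies [run_pipeline_single()] to every item with the same frozen
#' parameter set; results keep the input order and one failing file never
#' affects another. The parameter snapshot, software version and
#' timestamp are embedded in the result for traceability.
#'
#' @param items list of [batch_item()]s (>= 1).
#' @param params a [sptpalm_params()].
#' @param out_dir optional directory for per-file artifacts.
#' @param verbose log one line per file to the console.
#' @return list of class `batch_result` with `summary` (one row per
#'   file), `params`, `software_version`, `timestamp`.
#' @export
run_batch <- function(items, params = sptpalm_params(), out_dir = NULL,
                      verbose = FALSE) {
  if (length(items) == 0) stop("batch needs at least one input item")
  if (inherits(items, "batch_item")) items <- list(items)
  validate_params(params)
  hash <- params_hash(params)
  rows <- lapply(seq_along(items), function(i) {
    row <- run_pipeline_single(items[[i]], params, out_dir)
    if (verbose)
      message(sprintf("[sptpalm %s] file %d/%d: %s (%s)", hash, i, length(items),
                      row$file, if (nzchar(row$qc_flags)) row$qc_flags else "ok"))
    attr(row, "artifacts") <- NULL
    row
  })
  structure(list(summary = do.call(rbind, rows), params = params,
                 software_version = .sptpalm_version(),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("sptpalm batch_result: %d file(s), parameters %s\n",
              nrow(x$summary), params_hash(x$params)))
  print(x$summary[, c("file", "n_localizations_filtered", "n_tracks_min_length",
                      "D_mean_um2_per_s", "mobile_fraction", "n_clusters", "qc_flags")])
  invisible(x)
}

# flatten a nested parameter list to dotted keys with JSON-encoded values
.flatten_params <- function(params) {
  out <- list()
  rec <- function(x, prefix) {
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(x[[nm]])) rec(x[[nm]], key)
      else out[[key]] <<- as.character(jsonlite::toJSON(x[[nm]], auto_unbox = TRUE,
                                                        digits = NA, na = "null"))
    }
  }
  rec(.params_to_json_ready(unclass(params)), "")
  out
}

#' Write and read the batch results workbook
#'
#' A single multi-section CSV: section `[parameters]` holds the complete
#' key/value parameter dump (so every analysis step can be traced back),
#' section `[summary]` the per-file result table with numbers at 6
#' significant digits. `read_results_workbook()` restores both; the
#' restored parameter set equals the one used.
#'
#' @param result a `batch_result`.
#' @param path output file path.
#' @export
write_results_workbook <- function(result, path) {
  stopifnot(inherits(result, "batch_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sptpalm batch results",
               paste0("# software_version,", result$software_version),
               paste0("# timestamp,", result$timestamp),
               "[parameters]", "key,value"), con)
  fp <- .flatten_params(result$params)
  vals <- vapply(fp, function(v) paste0('"', gsub('"', '""', v), '"'), "")
  writeLines(paste(names(fp), vals, sep = ","), con)
  writeLines("[summary]", con)
  df <- result$summary
  for (col in names(df)) if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], 6)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_results_workbook
#' @export
read_results_workbook <- function(path) {
  lines <- readLines(path)
  ip <- which(lines == "[parameters]")
  is <- which(lines == "[summary]")
  if (length(ip) != 1 || length(is) != 1) stop("not a results workbook: ", path)
  kv <- read.csv(textConnection(lines[(ip + 1):(is - 1)]), stringsAsFactors = FALSE,
                 colClasses = "character")
  flat <- setNames(kv$value, kv$key)
  params <- .param_defaults()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- jsonlite::fromJSON(flat[[key]], simplifyVector = TRUE)
    if (length(parts) == 1) params[[parts[1]]] <- val
    else params[[parts[1]]][[parts[2]]] <- if (is.null(val)) NA else val
  }
  params <- .params_from_json(params)
  version <- sub("^# software_version,", "", lines[startsWith(lines, "# software_version,")])
  summary <- read.csv(textConnection(lines[(is + 1):length(lines)]),
                      stringsAsFactors = FALSE)
  list(params = params, summary = summary, software_version = version)
}
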