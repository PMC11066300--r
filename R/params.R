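# Parameter sets: one block per pipeline stage, serialized to/from JSON.
# Every numeric key carries its unit in its name. Unknown keys are rejected
# so that archived parameter files remain unambiguous.

.param_defaults <- function() {
  list(
    version = 1L,
    camera = list(
      pixel_size_nm = 100,
      frame_interval_s = 0.05,
      offset_adu = 100,
      e_per_adu = 0.5,
      qe = 1.0
    ),
    detection = list(
      dog_sigma_small_px = 1.0,
      dog_sigma_large_px = 2.5,
      threshold_factor = 4.0,
      roi_halfsize_px = 3L
    ),
    fit = list(
      initial_sigma_px = 1.3,
      max_iterations = 30L,
      tol = 1e-6,
      use_scmos = TRUE
    ),
    filter = list(
      sigma_range_nm = c(80, 250),
      photon_range = c(100, Inf),
      precision_max_nm = 50
    ),
    tracking = list(
      max_link_distance_nm = 500,
      max_gap_frames = 1L,
      max_gap_distance_nm = 500,
      min_track_length = 8L
    ),
    mobility = list(
      n_fit_points = 4L,
      max_lag = 10L,
      adj_r2_min = 0.7,
      threshold_logD = -2,
      max_components = 2L
    ),
    clustering = list(
      algorithm = "nastic",
      input_mode = "tracks",
      dbscan_eps_nm = 50,
      dbscan_min_pts = 5L,
      voronoi_density_factor = 2,
      voronoi_min_pts = 5L,
      nastic_radius_factor = 1.2,
      nastic_min_tracks = 3L,
      nastic_temporal_window_s = NA_real_
    ),
    batch = list(
      do_tracking = TRUE,
      do_mobility = TRUE,
      do_clustering = TRUE
    )
  )
}

#' Build a pipeline parameter set
#'
#' Returns the full nested parameter list used by every pipeline stage,
#' populated with documented defaults. Overrides are given per stage, e.g.
#' `sptpalm_params(tracking = list(max_link_distance_nm = 400))`. Unknown
#' stages or keys are an error: parameter files are part of the analysis
#' record and must not silently carry typos.
#'
#' Stages and defaults:
#' * `camera`: pixel size 100 nm, frame interval 0.05 s (20 Hz), offset
#'   100 ADU, 0.5 electrons/ADU, quantum efficiency 1.
#' * `detection`: difference-of-Gaussians sigmas 1.0/2.5 px, threshold
#'   4 robust noise SDs, ROI half-size 3 px (7x7 fit window).
#' * `fit`: initial PSF sigma 1.3 px, at most 30 damped Fisher-scoring
#'   iterations, relative tolerance 1e-6, sCMOS variance handling on.
#' * `filter`: PSF sigma in [80, 250] nm, photons >= 100, precision
#'   <= 50 nm.
#' * `tracking`: maximum link distance 500 nm, bridge up to 1 missed
#'   frame over at most 500 nm, minimum track length 8 localizations.
#' * `mobility`: fit the first 4 MSD points, compute lags up to 10 frames,
#'   accept fits with adjusted R^2 >= 0.7, mobile/immobile threshold
#'   log10(D) = -2, at most 2 mixture components.
#' * `clustering`: algorithm (`"nastic"`, `"dbscan"` or `"voronoi"`) and
#'   its parameters; `input_mode` one of `"tracks"`, `"centroids"`,
#'   `"locs"`.
#' * `batch`: stage toggles for the batch driver.
#'
#' @param ... named stage overrides, each a named list of keys to replace.
#' @return a named nested list of class `sptpalm_params`.
#' @export
sptpalm_params <- function(...) {
  params <- .param_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("stage overrides must be named")
  for (stage in names(over)) {
    if (!stage %in% names(params))
      stop("unknown parameter stage: ", stage)
    if (stage == "version") { params$version <- as.integer(over[[stage]]); next }
    block <- over[[stage]]
    if (!is.list(block)) stop("override for stage '", stage, "' must be a list")
    for (key in names(block)) {
      if (!key %in% names(params[[stage]]))
        stop("unknown parameter key: ", stage, "$", key)
      params[[stage]][[key]] <- block[[key]]
    }
  }
  class(params) <- c("sptpalm_params", "list")
  validate_params(params)
  params
}

#' @rdname sptpalm_params
#' @param params a parameter list to validate.
#' @export
validate_params <- function(params) {
  stopifnot(is.list(params))
  def <- .param_defaults()
  extra <- setdiff(names(params), names(def))
  if (length(extra) > 0) stop("unknown parameter stage(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(names(def), names(params))
  if (length(missing) > 0) stop("missing parameter stage(s): ", paste(missing, collapse = ", "))
  for (stage in setdiff(names(def), "version")) {
    extra <- setdiff(names(params[[stage]]), names(def[[stage]]))
    if (length(extra) > 0)
      stop("unknown parameter key(s) in ", stage, ": ", paste(extra, collapse = ", "))
    missing <- setdiff(names(def[[stage]]), names(params[[stage]]))
    if (length(missing) > 0)
      stop("missing parameter key(s) in ", stage, ": ", paste(missing, collapse = ", "))
  }
  p <- params
  .chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid parameter: ", what)
  .chk(p$camera$pixel_size_nm > 0, "camera$pixel_size_nm must be > 0")
  .chk(p$camera$frame_interval_s > 0, "camera$frame_interval_s must be > 0")
  .chk(p$camera$e_per_adu > 0, "camera$e_per_adu must be > 0")
  .chk(p$camera$qe > 0 && p$camera$qe <= 1, "camera$qe must be in (0, 1]")
  .chk(p$detection$dog_sigma_small_px > 0 && p$detection$dog_sigma_large_px > p$detection$dog_sigma_small_px,
       "detection sigmas must satisfy 0 < small < large")
  .chk(p$detection$threshold_factor > 0, "detection$threshold_factor must be > 0")
  .chk(p$detection$roi_halfsize_px >= 1, "detection$roi_halfsize_px must be >= 1")
  .chk(p$fit$initial_sigma_px > 0, "fit$initial_sigma_px must be > 0")
  .chk(p$fit$max_iterations >= 1, "fit$max_iterations must be >= 1")
  .chk(p$fit$tol > 0, "fit$tol must be > 0")
  .chk(p$filter$sigma_range_nm[1] <= p$filter$sigma_range_nm[2], "filter$sigma_range_nm inverted")
  .chk(p$filter$photon_range[1] <= p$filter$photon_range[2], "filter$photon_range inverted")
  .chk(p$tracking$max_link_distance_nm > 0, "tracking$max_link_distance_nm must be > 0")
  .chk(p$tracking$max_gap_distance_nm > 0, "tracking$max_gap_distance_nm must be > 0")
  .chk(p$tracking$max_gap_frames >= 0, "tracking$max_gap_frames must be >= 0")
  .chk(p$tracking$min_track_length >= 2, "tracking$min_track_length must be >= 2")
  .chk(p$mobility$n_fit_points >= 2, "mobility$n_fit_points must be >= 2")
  .chk(p$mobility$max_lag >= p$mobility$n_fit_points, "mobility$max_lag must be >= n_fit_points")
  .chk(p$clustering$algorithm %in% c("nastic", "dbscan", "voronoi"), "clustering$algorithm unknown")
  .chk(p$clustering$input_mode %in% c("tracks", "centroids", "locs"), "clustering$input_mode unknown")
  invisible(params)
}

# JSON cannot represent Inf; encode as null and restore on read.
.params_to_json_ready <- function(x) {
  rapply(x, function(v) {
    if (is.numeric(v)) ifelse(is.infinite(v), NA, v) else v
  }, how = "replace")
}

.params_from_json <- function(x) {
  # restore leaf types from the defaults template; null-coded range bounds
  # come back as NA and are mapped to Inf in the filter stage
  def <- .param_defaults()
  x$version <- as.integer(x$version)
  for (stage in setdiff(names(def), "version")) {
    for (key in names(def[[stage]])) {
      v <- x[[stage]][[key]]
      d <- def[[stage]][[key]]
      if (is.null(v)) v <- NA
      v <- if (is.integer(d)) as.integer(v)
      else if (is.numeric(d)) as.numeric(v)
      else if (is.logical(d)) as.logical(v)
      else as.character(v)
      x[[stage]][[key]] <- v
    }
  }
  x$filter$photon_range[is.na(x$filter$photon_range)] <- Inf
  x$filter$sigma_range_nm[is.na(x$filter$sigma_range_nm)] <- Inf
  x$filter$precision_max_nm[is.na(x$filter$precision_max_nm)] <- Inf
  class(x) <- c("sptpalm_params", "list")
  x
}

#' Read and write parameter files
#'
#' Parameter sets are stored as plain JSON with a fixed schema (see
#' [sptpalm_params()]). `read_params(write_params(p)) == p` holds exactly;
#' infinite range bounds are encoded as JSON `null`.
#'
#' @param params a `sptpalm_params` object.
#' @param path file path of the JSON document.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(.params_to_json_ready(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- .params_from_json(x)
  validate_params(params)
  params
}

# Small stable content hash (FNV-1a over the JSON encoding); used only to
# tag outputs with the parameter set they came from.
params_hash <- function(params) {
  s <- jsonlite::toJSON(.params_to_json_ready(unclass(params)),
                        auto_unbox = TRUE, digits = NA, na = "null")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, kept exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' @export
print.sptpalm_params <- function(x, ...) {
  cat("sptpalm parameter set (version ", x$version, ", hash ", params_hash(x), ")\n", sep = "")
  for (stage in setdiff(names(x), "version")) {
    vals <- vapply(x[[stage]], function(v) paste(format(v, digits = 6), collapse = ","), "")
    cat("  ", stage, ": ", paste(names(vals), vals, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
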