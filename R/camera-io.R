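# Movie stacks, camera calibration and tabular I/O.
#
# Coordinate convention used throughout: the origin is the top-left corner
# of the top-left pixel; the continuous position of pixel (row i, col j)
# (1-based) has x = (j - 0.5) * pixel_size_nm, y = (i - 0.5) * pixel_size_nm.
# Frames are 1-based in all tables.

#' Create a movie stack
#'
#' Container for raw camera frames (ADU) plus the acquisition metadata the
#' pipeline needs. Frames are stored as a 3-D array indexed
#' `[row, col, frame]`.
#'
#' @param frames numeric matrix (one frame) or 3-D array `[row, col, frame]`.
#' @param pixel_size_nm physical length of one camera pixel in the sample
#'   plane, nm.
#' @param frame_interval_s time between consecutive frames, seconds.
#' @param source text identifier (file path or `"<memory>"`).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size_nm, frame_interval_s, source = "<memory>") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a matrix or a 3-D array [row, col, frame]")
  if (dim(frames)[3] < 1L) stop("movie must contain at least one frame")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s, source = source),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames of %dx%d px, %.3g nm/px, %.4g s/frame (%s)\n",
              d[3], d[1], d[2], x$pixel_size_nm, x$frame_interval_s, x$source))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$frames)

n_frames <- function(movie) dim(movie$frames)[3]

#' Read a TIFF movie stack
#'
#' Reads a single- or multi-page grayscale TIFF in acquisition order. TIFF
#' metadata is deliberately ignored: pixel size and frame interval always
#' come from the caller (they are set at the microscope, not reliably
#' stored in the file).
#'
#' @param path TIFF file path.
#' @inheritParams movie_stack
#' @return a [movie_stack()].
#' @export
read_movie_stack <- function(path, pixel_size_nm, frame_interval_s) {
  if (!file.exists(path)) stop("cannot read movie: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("TIFF has no pages: ", path)
  for (p in pages) {
    if (!is.matrix(p))
      stop("unsupported TIFF: pages must be single-channel grayscale (", path, ")")
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), TRUE)))
    stop("unsupported TIFF: pages have mixed shapes (", path, ")")
  frames <- array(0, dim = c(d1, length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  movie_stack(frames, pixel_size_nm, frame_interval_s, source = path)
}

#' Write a movie stack as 16-bit TIFF
#'
#' Values are rounded and clipped to `[0, 65535]`.
#'
#' @param movie a [movie_stack()].
#' @param path output file path.
#' @export
write_movie_stack <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  nf <- n_frames(movie)
  pages <- vector("list", nf)
  for (k in seq_len(nf)) {
    fr <- round(movie$frames[, , k])
    fr[fr < 0] <- 0
    fr[fr > 65535] <- 65535
    pages[[k]] <- fr / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Camera calibration
#'
#' Per-pixel (or scalar) dark offset and variance plus the photon
#' conversion constants. The offset/variance maps, when per-pixel, must
#' match the movie frame shape they are applied to.
#'
#' @param offset mean dark signal, ADU (scalar or matrix).
#' @param variance dark variance, ADU^2 (scalar or matrix, >= 0).
#' @param e_per_adu conversion gain, electrons per ADU (> 0).
#' @param qe quantum efficiency in (0, 1].
#' @export
camera_calibration <- function(offset, variance = 0, e_per_adu = 1, qe = 1) {
  if (any(variance < 0)) stop("variance must be >= 0 everywhere")
  if (!is.numeric(e_per_adu) || e_per_adu <= 0) stop("e_per_adu must be > 0")
  if (!is.numeric(qe) || qe <= 0 || qe > 1) stop("qe must be in (0, 1]")
  if (is.matrix(offset) != is.matrix(variance) ||
      (is.matrix(offset) && !identical(dim(offset), dim(variance))))
    stop("offset and variance must both be scalars or matrices of identical shape")
  structure(list(offset = offset, variance = variance,
                 e_per_adu = e_per_adu, qe = qe),
            class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  per_px <- if (is.matrix(x$offset)) sprintf("per-pixel %dx%d", nrow(x$offset), ncol(x$offset)) else "scalar"
  cat(sprintf("camera_calibration (%s): mean offset %.4g ADU, mean variance %.4g ADU^2, %.3g e-/ADU, QE %.3g\n",
              per_px, mean(x$offset), mean(x$variance), x$e_per_adu, x$qe))
  invisible(x)
}

#' Calibrate a camera from a dark-noise stack
#'
#' Computes the per-pixel temporal mean (offset) and unbiased temporal
#' variance of a stack of dark images, as recorded alongside each
#' measurement session. These maps feed both photon conversion and the
#' sCMOS-aware localization fit.
#'
#' @param dark_stack a [movie_stack()] of dark frames (>= 2 frames).
#' @inheritParams camera_calibration
#' @return a [camera_calibration()] with per-pixel maps.
#' @export
calibrate_camera <- function(dark_stack, e_per_adu = 1, qe = 1) {
  stopifnot(inherits(dark_stack, "movie_stack"))
  nf <- n_frames(dark_stack)
  if (nf < 2L) stop("dark stack must contain at least 2 frames (variance undefined)")
  m <- rowMeans(dark_stack$frames, dims = 2L)
  m2 <- rowMeans(dark_stack$frames^2, dims = 2L)
  v <- (m2 - m^2) * nf / (nf - 1)
  v[v < 0] <- 0  # numerical noise on constant pixels
  camera_calibration(offset = m, variance = v, e_per_adu = e_per_adu, qe = qe)
}

# Extract the (row, col)-aligned calibration maps for a sub-region.
.calib_roi <- function(calib, roi_dim, roi_origin) {
  take <- function(map) {
    if (!is.matrix(map)) return(matrix(map, roi_dim[1], roi_dim[2]))
    rows <- roi_origin[1] + seq_len(roi_dim[1]) - 1L
    cols <- roi_origin[2] + seq_len(roi_dim[2]) - 1L
    if (min(rows) < 1L || min(cols) < 1L || max(rows) > nrow(map) || max(cols) > ncol(map))
      stop("calibration maps do not cover the requested region")
    map[rows, cols, drop = FALSE]
  }
  list(offset = take(calib$offset), variance = take(calib$variance))
}

#' Convert camera counts to photons
#'
#' `photons = (ADU - offset) * e_per_adu / qe`. The conversion is affine
#' and invertible; negative values are retained by default because the
#' maximum-likelihood fitter must see unclipped data (set `clip = TRUE`
#' only for display).
#'
#' @param adu 2-D array of camera counts.
#' @param calib a [camera_calibration()].
#' @param roi_origin 1-based (row, col) of `adu`'s top-left pixel in the
#'   full frame (used to index per-pixel maps).
#' @param clip clip below at zero (display only).
#' @return matrix of photons, same shape as `adu`.
#' @export
adu_to_photons <- function(adu, calib, roi_origin = c(1L, 1L), clip = FALSE) {
  stopifnot(inherits(calib, "camera_calibration"), is.matrix(adu))
  maps <- .calib_roi(calib, dim(adu), roi_origin)
  ph <- (adu - maps$offset) * calib$e_per_adu / calib$qe
  if (clip) ph[ph < 0] <- 0
  ph
}

# ---- localization tables -------------------------------------------------

.loc_columns <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons",
                  "background_photons", "precision_nm", "converged")

empty_localizations <- function() {
  df <- data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                   sigma_nm = numeric(), photons = numeric(),
                   background_photons = numeric(), precision_nm = numeric(),
                   converged = logical())
  df
}

#' Read and write localization tables
#'
#' Plain CSV with the fixed header
#' `frame,x_nm,y_nm,sigma_nm,photons,background_photons,precision_nm,converged`;
#' frames 1-based, coordinates in nm (origin at the top-left corner of the
#' top-left pixel). Floats are written with full precision so that
#' `read_localization_table(write_localization_table(x)) == x`.
#'
#' @param locs localization data frame.
#' @param path CSV file path.
#' @export
write_localization_table <- function(locs, path) {
  locs <- as.data.frame(locs)[, .loc_columns, drop = FALSE]
  write.csv(format(locs, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localization_table
#' @export
read_localization_table <- function(path) {
  if (!file.exists(path)) stop("cannot read localization table: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.loc_columns, names(df))
  if (length(missing) > 0)
    stop("localization table is missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[, .loc_columns, drop = FALSE]
  if (nrow(df) == 0) return(empty_localizations())
  df$frame <- as.integer(df$frame)
  for (col in setdiff(.loc_columns, c("frame", "converged"))) df[[col]] <- as.numeric(df[[col]])
  df$converged <- as.logical(df$converged)
  df
}

# ---- region masks --------------------------------------------------------

#' Read and write binary region masks
#'
#' Masks are single-page 8-bit TIFF aligned to the movie frame grid:
#' 0 = excluded, 255 (any nonzero) = analyzed.
#'
#' @param include logical matrix (TRUE = analyze).
#' @param path TIFF file path.
#' @export
write_region_mask <- function(include, path) {
  stopifnot(is.matrix(include), is.logical(include))
  tiff::writeTIFF(matrix(as.numeric(include), nrow(include)), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(m)) m <- m[[1]]
  if (!is.matrix(m)) stop("mask must be a single-channel single-page TIFF: ", path)
  m > 0
}
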