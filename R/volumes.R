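## Volume containers and NIfTI / event-list I/O.
##
## Geometry convention (fixed once for the whole package): voxel indices are
## 1-based in R; the world coordinate (mm) of voxel (i, j, k) is
## origin + (c(i, j, k) - 1) * spacing (voxel-centre convention). External
## CSV event lists use 0-based indices, converted on read/write.

#' 3-D scalar volume with physical geometry
#'
#' The common geometry object of the package: a 3-D array of scalar values
#' (Hounsfield units for CT, activity in uCi for PET) plus the physical
#' voxel spacing and the world position of the first voxel centre.
#'
#' @param values 3-D numeric array.
#' @param spacing voxel spacing in mm, length 3, strictly positive.
#' @param origin world coordinate (mm) of voxel (1, 1, 1), length 3.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ", length(dim(values)), " dims")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' 3-D label volume (integer codes, 0 = background)
#'
#' @param labels 3-D array of non-negative integers (or logical, coerced to
#'   0/1).
#' @inheritParams scalar_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (is.logical(labels)) {
    dm <- dim(labels)
    labels <- array(as.integer(labels), dim = dm)
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  v <- scalar_volume(labels, spacing, origin)
  names(v)[1] <- "labels"
  names(v$labels) <- NULL
  class(v) <- c("label_volume", "scalar_volume")
  v
}

vol_values <- function(x) if (inherits(x, "label_volume")) x$labels else x$values

as_mask <- function(x) {
  if (inherits(x, "scalar_volume")) x <- vol_values(x)
  if (is.logical(x)) return(x)
  array(x != 0, dim = dim(x))
}

#' @export
print.scalar_volume <- function(x, ...) {
  v <- vol_values(x)
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(v), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  values in [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(vol_values(x))

same_geometry <- function(a, b, tol = 1e-6) {
  da <- dim(vol_values(a))[1:3]
  db <- dim(vol_values(b))[1:3]
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert voxel indices to world coordinates (mm)
#'
#' @param vol a `scalar_volume` (only geometry is used).
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  round(sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/")) + 1
}

## ---- NIfTI I/O ---------------------------------------------------------

geom_affine <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Read / write a 3-D volume as NIfTI-1
#'
#' Spacing is carried in `pixdim`, origin in the qform translation; the
#' round trip preserves values, spacing and origin.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `scalar_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3-D volume (", length(dim(img)), " dims)")
  scalar_volume(array(as.numeric(img), dim = dim(img)),
                spacing = RNifti::pixdim(img)[1:3],
                origin = RNifti::xform(img)[1:3, 4])
}

#' @rdname read_volume
#' @param volume a `scalar_volume` or `label_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(vol_values(volume))
  RNifti::pixdim(img) <- volume$spacing
  RNifti::qform(img) <- structure(geom_affine(volume$spacing, volume$origin),
                                  code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- dynamic series ----------------------------------------------------

#' Time-ordered dynamic PET series
#'
#' Frames share a single geometry and carry half-open acquisition windows
#' `[start_s, end_s)`; intervals must be strictly increasing and
#' non-overlapping.
#'
#' @param values 4-D array (x, y, z, frame) of activity (uCi per voxel).
#' @param frame_times n x 2 matrix of frame start/end times in seconds.
#' @inheritParams scalar_volume
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(values, frame_times, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 4L) stop("`values` must be a 4-D array")
  frame_times <- matrix(as.numeric(frame_times), ncol = 2)
  if (nrow(frame_times) != dim(values)[4])
    stop("frame_times rows (", nrow(frame_times),
         ") must match frame count (", dim(values)[4], ")")
  if (any(frame_times[, 2] <= frame_times[, 1]))
    stop("every frame must have end_s > start_s")
  if (nrow(frame_times) > 1 &&
      any(frame_times[-1, 1] < frame_times[-nrow(frame_times), 2]))
    stop("frame intervals must be non-overlapping and increasing")
  geom <- scalar_volume(array(0, dim = c(1, 1, 1)), spacing, origin)
  structure(list(values = values, frame_times = frame_times,
                 spacing = geom$spacing, origin = geom$origin),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %s voxels x %d frames, %g-%g s\n",
              paste(dim(x$values)[1:3], collapse = "x"), n_frames(x),
              x$frame_times[1, 1], x$frame_times[n_frames(x), 2]))
  invisible(x)
}

#' @export
n_frames <- function(series) UseMethod("n_frames")

#' @export
n_frames.dynamic_series <- function(series) dim(series$values)[4]

#' Extract one frame of a dynamic series as a `scalar_volume`
#' @param series a `dynamic_series`.
#' @param f frame index.
#' @export
get_frame <- function(series, f) {
  stopifnot(f >= 1, f <= n_frames(series))
  scalar_volume(series$values[, , , f, drop = TRUE],
                series$spacing, series$origin)
}

#' Frame midpoint times in minutes
#' @param series a `dynamic_series`.
#' @export
frame_midpoints_min <- function(series) {
  rowMeans(series$frame_times) / 60
}

#' Read / write a dynamic series (4-D NIfTI + JSON frame-time sidecar)
#'
#' Frame start/end times (seconds) are stored in a sidecar
#' `<stem>_times.json` next to the image, since NIfTI-1 has no per-frame
#' timing fields.
#'
#' @param path path to the 4-D NIfTI file.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  if (length(dim(img)) != 4L) stop("'", path, "' is not a 4-D series")
  sidecar <- series_sidecar(path)
  if (!file.exists(sidecar))
    stop("missing frame-time sidecar: ", sidecar)
  ft <- jsonlite::fromJSON(sidecar)
  dynamic_series(array(as.numeric(img), dim = dim(img)),
                 cbind(ft$start_s, ft$end_s),
                 spacing = RNifti::pixdim(img)[1:3],
                 origin = RNifti::xform(img)[1:3, 4])
}

#' @rdname read_series
#' @param series a `dynamic_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$values)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::qform(img) <- structure(geom_affine(series$spacing, series$origin),
                                  code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(start_s = series$frame_times[, 1],
                            end_s = series$frame_times[, 2]),
                       series_sidecar(path), digits = NA)
  invisible(path)
}

series_sidecar <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_times.json")
}

## ---- acquisition & events ----------------------------------------------

#' PET acquisition constants
#'
#' Defaults describe a clinical digital PET/CT acquiring 15 min of list-mode
#' data binned into 10-s frames: Ga-68 half-life 68 min, system sensitivity
#' 7.3 cps/kBq, and point-spread FWHM of 5.5 (radial), 4.5 (tangential) and
#' 6 mm (axial).
#'
#' @param frame_duration_s frame duration in seconds.
#' @param total_duration_min total acquisition length in minutes.
#' @param half_life_min isotope half-life in minutes.
#' @param sensitivity_cps_per_kBq scanner sensitivity.
#' @param psf_fwhm_mm length-3 PSF FWHM (radial, tangential, axial) in mm.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_duration_s = 10, total_duration_min = 15,
                             half_life_min = 68,
                             sensitivity_cps_per_kBq = 7.3,
                             psf_fwhm_mm = c(5.5, 4.5, 6)) {
  vals <- c(frame_duration_s, total_duration_min, half_life_min,
            sensitivity_cps_per_kBq, psf_fwhm_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition constants must be positive")
  if (length(psf_fwhm_mm) != 3L) stop("psf_fwhm_mm must have length 3")
  structure(list(frame_duration_s = frame_duration_s,
                 total_duration_min = total_duration_min,
                 half_life_min = half_life_min,
                 sensitivity_cps_per_kBq = sensitivity_cps_per_kBq,
                 psf_fwhm_mm = as.numeric(psf_fwhm_mm)),
            class = "acquisition_spec")
}

#' Timestamped coincidence-event list
#'
#' @param timestamps_s non-negative event times in seconds.
#' @param positions n x 3 matrix of 1-based voxel indices.
#' @return An object of class `event_list`.
#' @export
event_list <- function(timestamps_s, positions) {
  timestamps_s <- as.numeric(timestamps_s)
  positions <- matrix(as.integer(positions), ncol = 3)
  if (nrow(positions) != length(timestamps_s))
    stop("positions must have one row per timestamp")
  if (any(timestamps_s < 0)) stop("timestamps must be non-negative")
  structure(list(timestamps_s = timestamps_s, positions = positions),
            class = "event_list")
}

#' Read / write an event list as CSV
#'
#' Columns `t_s, i, j, k` with 0-based voxel indices in the file (converted
#' to the package's 1-based convention in memory).
#' @param path CSV path.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such event file: ", path)
  d <- read.csv(path)
  need <- c("t_s", "i", "j", "k")
  if (!all(need %in% names(d)))
    stop("event CSV must have columns t_s, i, j, k")
  event_list(d$t_s, as.matrix(d[, c("i", "j", "k")]) + 1L)
}

#' @rdname read_events
#' @param events an `event_list`.
#' @export
write_events <- function(events, path) {
  d <- data.frame(t_s = events$timestamps_s,
                  i = events$positions[, 1] - 1L,
                  j = events$positions[, 2] - 1L,
                  k = events$positions[, 3] - 1L)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Bin timestamped events into fixed-duration frames
#'
#' Frames are half-open `[f * dt, (f + 1) * dt)`: an event exactly on a
#' boundary belongs to the later frame. A trailing partial frame is kept
#' with its true duration. Events at or beyond the total acquisition
#' duration are rejected (their count is reported in a warning).
#'
#' @param events an `event_list`.
#' @param spec an `acquisition_spec` (frame duration and total duration).
#' @param geometry a `scalar_volume` or `label_volume` defining the grid.
#' @param units `"counts"` (default) leaves raw counts per voxel;
#'   `"activity"` divides by frame duration and sensitivity (and 37 kBq/uCi)
#'   to give uCi.
#' @return A `dynamic_series`.
#' @export
bin_events <- function(events, spec = acquisition_spec(), geometry,
                       units = c("counts", "activity")) {
  units <- match.arg(units)
  stopifnot(inherits(events, "event_list"),
            inherits(spec, "acquisition_spec"))
  dm <- dim(vol_values(geometry))
  pos <- events$positions
  if (nrow(pos) &&
      (any(pos < 1L) || any(pos[, 1] > dm[1]) || any(pos[, 2] > dm[2]) ||
       any(pos[, 3] > dm[3])))
    stop("event positions outside the grid")
  total_s <- spec$total_duration_min * 60
  dt <- spec$frame_duration_s
  keep <- events$timestamps_s < total_s
  if (any(!keep))
    warning(sum(!keep), " event(s) at/after ", total_s,
            " s rejected")
  t <- events$timestamps_s[keep]
  pos <- pos[keep, , drop = FALSE]
  nf <- ceiling(total_s / dt)
  starts <- (seq_len(nf) - 1) * dt
  ends <- pmin(starts + dt, total_s)
  nvox <- prod(dm)
  fidx <- floor(t / dt) + 1L
  lin <- (pos[, 1] + (pos[, 2] - 1L) * dm[1] +
            (pos[, 3] - 1L) * dm[1] * dm[2])
  counts <- tabulate(lin + (fidx - 1L) * nvox, nbins = nvox * nf)
  arr <- array(as.numeric(counts), dim = c(dm, nf))
  if (units == "activity") {
    dur <- ends - starts
    scale <- 1 / (dur * spec$sensitivity_cps_per_kBq * 37)
    arr <- sweep(arr, 4, scale, "*")
  }
  dynamic_series(arr, cbind(starts, ends), geometry$spacing, geometry$origin)
}
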