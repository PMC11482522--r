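## Airway centerline: homotopic thinning, longest-path extraction,
## cubic-spline smoothing, pleural extrapolation, and PET sampling in
## perpendicular disks and a distal cylinder ROI.

neighbour_offsets_26 <- function(dm) {
  off <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  off <- off[!(off$a == 0 & off$b == 0 & off$c == 0), ]
  off$a + off$b * dm[1] + off$c * dm[1] * dm[2]
}

#' Extract the main-airway centerline path by 3-D thinning
#'
#' Thins the airway mask to a one-voxel-wide, 26-connected skeleton
#' (homotopic thinning in increasing distance-transform order, so the
#' skeleton stays medial), then returns the longest path from the skeleton
#' voxel nearest the user-supplied proximal seed to the periphery; side
#' branches are pruned. Ties among equally long terminal voxels are broken
#' by the lexicographically smallest (i, j, k).
#'
#' @param airway_mask binary, connected `label_volume`.
#' @param proximal_seed 1-based voxel index (i, j, k) marking the proximal
#'   (tracheal) end.
#' @return A list of class `centerline_path`: `path` (n x 3 matrix of
#'   1-based voxel indices, proximal first), `skeleton` (binary
#'   `label_volume`), plus the grid `spacing` and `origin`.
#' @export
skeletonize <- function(airway_mask, proximal_seed) {
  check_binary(airway_mask)
  m <- as_mask(airway_mask)
  dm <- dim(m)
  comp <- label_components_cpp(as.vector(m), dm, 26L)
  ncomp <- max(comp)
  if (ncomp == 0L) stop("empty airway mask")
  if (ncomp > 1L)
    stop("airway mask has ", ncomp,
         " connected components; expected exactly 1")
  d <- edt_mm(m, airway_mask$spacing)
  skel <- array(thin_skeleton_cpp(as.vector(m), dm, as.vector(d)), dim = dm)

  sv <- which(skel)                       # linear indices of skeleton voxels
  ijk <- arrayInd(sv, dm)
  # start node: skeleton voxel nearest the proximal seed (physical distance)
  seed <- as.numeric(proximal_seed)
  if (length(seed) != 3L) stop("proximal_seed must be (i, j, k)")
  w <- sweep(ijk, 2, seed)
  w <- sweep(w, 2, airway_mask$spacing, "*")
  start <- which.min(rowSums(w^2))

  # 26-adjacency graph over skeleton voxels with Euclidean edge weights
  off <- neighbour_offsets_26(dm)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (o in off) {
    nb <- sv + o
    ok <- nb >= 1 & nb <= prod(dm)
    # guard row/col wraparound: neighbour must differ by <=1 in each index
    cand <- which(ok)
    if (!length(cand)) next
    nb_ijk <- arrayInd(nb[cand], dm)
    good <- rowSums(abs(nb_ijk - ijk[cand, , drop = FALSE]) > 1) == 0
    cand <- cand[good]
    if (!length(cand)) next
    m2 <- match(nb[cand], sv)
    keep <- !is.na(m2)
    if (!any(keep)) next
    cand <- cand[keep]; m2 <- m2[keep]
    from <- c(from, cand); to <- c(to, m2)
    dvox <- (ijk[cand, , drop = FALSE] - ijk[m2, , drop = FALSE])
    wt <- c(wt, sqrt(rowSums(sweep(dvox, 2, airway_mask$spacing, "*")^2)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt),
    directed = FALSE, vertices = data.frame(name = seq_along(sv)))
  dists <- igraph::distances(g, v = start)[1, ]
  dists[!is.finite(dists)] <- -Inf
  far <- which(dists == max(dists))
  if (length(far) > 1) {               # lexicographic tie-break on (i, j, k)
    ord <- do.call(order, as.data.frame(ijk[far, , drop = FALSE]))
    far <- far[ord[1]]
  }
  vpath <- igraph::shortest_paths(g, from = start, to = far)$vpath[[1]]
  path <- ijk[as.integer(igraph::as_ids(vpath)), , drop = FALSE]
  structure(list(path = path,
                 skeleton = label_volume(skel, airway_mask$spacing,
                                         airway_mask$origin),
                 spacing = airway_mask$spacing,
                 origin = airway_mask$origin),
            class = "centerline_path")
}

#' Fit a smoothing cubic spline to a centerline path
#'
#' Fits independent cubic smoothing splines to x(t), y(t), z(t) against the
#' chord-length parameter and re-parameterises by arclength. The smoothing
#' level is raised until the 3-D residual RMS at the input points is at
#' most one voxel spacing (thinning output is noisy at voxel scale).
#' Duplicate consecutive points are dropped.
#'
#' @param path a `centerline_path`, or an n x 3 matrix of world
#'   coordinates (mm).
#' @param spacing voxel spacing in mm (taken from the path object when
#'   available); sets the residual tolerance and sampling density.
#' @param origin world origin (taken from the path object when available).
#' @return An object of class `centerline` with fields `control_points`,
#'   `arclength` (per control point), `fine` (dense arclength-parameterised
#'   samples), `length`, and `extension_start` (NA until extrapolated).
#' @export
fit_centerline_spline <- function(path, spacing = NULL, origin = NULL) {
  if (inherits(path, "centerline_path")) {
    spacing <- path$spacing
    origin <- path$origin
    pts <- sweep(sweep(path$path - 1, 2, spacing, "*"), 2, origin, "+")
  } else {
    pts <- as.matrix(path)
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  # drop duplicate consecutive points
  if (nrow(pts) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
    pts <- pts[!dup, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 distinct path points, got ", n)
  seg <- sqrt(rowSums(diff(pts)^2))
  t <- c(0, cumsum(seg))
  tol <- min(spacing)
  # generalised cross-validation picks the smoothing; if the fit still
  # misses the points by more than a voxel, force more flexibility
  try_fit <- function(df = NULL) {
    fits <- lapply(1:3, function(a) {
      if (is.null(df)) smooth.spline(t, pts[, a], cv = FALSE)
      else smooth.spline(t, pts[, a], df = df, cv = FALSE)
    })
    pred <- vapply(fits, function(f) predict(f, t)$y, numeric(n))
    list(fits = fits, rms = sqrt(mean(rowSums((pred - pts)^2))))
  }
  cand <- try_fit()
  for (df in unique(pmin(n, c(8, 16, 32, 64, n)))) {
    if (cand$rms <= tol) break
    cand <- try_fit(df)
  }
  fits <- cand$fits
  rms <- cand$rms
  # dense resampling for arclength parameterisation
  tt <- seq(0, max(t), length.out = max(200L, 8L * n))
  xyz <- vapply(fits, function(f) predict(f, tt)$y, numeric(length(tt)))
  s <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  arclength <- approx(tt, s, xout = t)$y
  structure(list(control_points = pts, t = t, arclength = arclength,
                 fits = fits,
                 fine = data.frame(s = s, x = xyz[, 1], y = xyz[, 2],
                                   z = xyz[, 3], is_extension = FALSE),
                 length = max(s), extension_start = NA_real_,
                 residual_rms = rms,
                 spacing = spacing, origin = origin),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d control points, length %.2f mm%s\n",
              nrow(x$control_points), x$length,
              if (is.na(x$extension_start)) ""
              else sprintf(" (extension from %.2f mm)", x$extension_start)))
  invisible(x)
}

#' Evaluate a centerline at given arclengths
#'
#' Linear interpolation of the dense arclength-parameterised samples.
#' @param cl a `centerline`.
#' @param s arclength(s) in mm, in `[0, cl$length]`.
#' @return length(s) x 3 matrix of world coordinates.
#' @export
centerline_point <- function(cl, s) {
  cbind(approx(cl$fine$s, cl$fine$x, xout = s)$y,
        approx(cl$fine$s, cl$fine$y, xout = s)$y,
        approx(cl$fine$s, cl$fine$z, xout = s)$y)
}

terminal_tangent <- function(cl) {
  f <- cl$fine
  n <- nrow(f)
  i0 <- max(1, n - 5)
  u <- c(f$x[n] - f$x[i0], f$y[n] - f$y[i0], f$z[n] - f$z[i0])
  u / sqrt(sum(u^2))
}

#' Extrapolate a centerline to the pleural surface
#'
#' Appends a straight segment along the terminal tangent until the ray
#' first leaves the lung mask (or the grid). The arclength at which the
#' extension begins is recorded in `extension_start`.
#'
#' @param cl a `centerline` whose terminal point lies inside the lung.
#' @param lung_mask binary `label_volume`.
#' @return The extended `centerline`.
#' @export
extrapolate_to_pleura <- function(cl, lung_mask) {
  m <- as_mask(lung_mask)
  dm <- dim(m)
  u <- terminal_tangent(cl)
  f <- cl$fine
  p0 <- c(f$x[nrow(f)], f$y[nrow(f)], f$z[nrow(f)])
  step <- 0.25 * min(lung_mask$spacing)
  # march until outside mask; cap at 10x the lung bounding-box diagonal
  bbox <- which(m, arr.ind = TRUE)
  diag_mm <- sqrt(sum(((apply(bbox, 2, max) - apply(bbox, 2, min) + 1) *
                         lung_mask$spacing)^2))
  smax <- 10 * diag_mm
  inside <- function(p) {
    ijk <- round((p - lung_mask$origin) / lung_mask$spacing) + 1
    all(ijk >= 1) && all(ijk <= dm) && m[ijk[1], ijk[2], ijk[3]]
  }
  if (!inside(p0)) {
    cl$extension_start <- cl$length
    return(cl)                          # already on/through the boundary
  }
  s <- 0
  repeat {
    s <- s + step
    if (s > smax)
      stop("terminal tangent never exits the lung mask within ",
           signif(smax, 3), " mm: pathological geometry")
    if (!inside(p0 + s * u)) break
  }
  ext_s <- seq(step, s, by = step)
  ext <- data.frame(s = cl$length + ext_s,
                    x = p0[1] + ext_s * u[1],
                    y = p0[2] + ext_s * u[2],
                    z = p0[3] + ext_s * u[3],
                    is_extension = TRUE)
  cl$extension_start <- cl$length
  cl$fine <- rbind(cl$fine, ext)
  cl$length <- max(cl$fine$s)
  cl
}

## nearest point on the (dense-sampled) curve for a set of world points;
## returns min distance and the arclength of the nearest curve sample
nearest_curve <- function(cl, xyz) {
  f <- cl$fine
  n <- nrow(xyz)
  best <- rep(Inf, n)
  arg <- numeric(n)
  for (i in seq_len(nrow(f))) {
    d2 <- (xyz[, 1] - f$x[i])^2 + (xyz[, 2] - f$y[i])^2 +
      (xyz[, 3] - f$z[i])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    arg[upd] <- f$s[i]
  }
  list(dist = sqrt(best), s = arg)
}

grid_world_coords <- function(vol, sub = NULL) {
  dm <- dim(vol_values(vol))
  if (is.null(sub)) sub <- arrayInd(seq_len(prod(dm)), dm)
  sweep(sweep(sub - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

## voxels of `vol` inside the bounding box of the curve inflated by margin
curve_bbox_voxels <- function(cl, vol, margin_mm) {
  dm <- dim(vol_values(vol))
  f <- cl$fine
  lo <- c(min(f$x), min(f$y), min(f$z)) - margin_mm
  hi <- c(max(f$x), max(f$y), max(f$z)) + margin_mm
  lo_i <- pmax(1, floor((lo - vol$origin) / vol$spacing) + 1)
  hi_i <- pmin(dm, ceiling((hi - vol$origin) / vol$spacing) + 1)
  if (any(lo_i > hi_i)) return(NULL)
  sub <- as.matrix(expand.grid(i = lo_i[1]:hi_i[1], j = lo_i[2]:hi_i[2],
                               k = lo_i[3]:hi_i[3]))
  colnames(sub) <- NULL
  sub
}

#' Sample PET activity in perpendicular disks along a centerline
#'
#' Disk centres are uniformly spaced by arclength; every PET voxel within
#' `radius_mm` of the curve is assigned to the nearest disk plane
#' (half-open along arclength, ties to the more distal disk), so the disks
#' partition the swept cylinder and their activities sum to its total.
#' The distance to the pleura of a disk is the remaining arclength to the
#' distal end of the (extrapolated) centerline.
#'
#' @param cl a `centerline`.
#' @param pet_frame a `scalar_volume` of activity (uCi per voxel).
#' @param spacing_mm arclength spacing between disk centres.
#' @param radius_mm disk radius; if smaller than one voxel the sampling
#'   degenerates to a nearest-voxel tube (with a warning).
#' @return A data.frame with one row per disk: centre coordinates, normal,
#'   thickness, radius, summed activity (uCi) and distance to pleura (mm).
#' @export
sample_disks <- function(cl, pet_frame, spacing_mm, radius_mm) {
  stopifnot(inherits(cl, "centerline"), spacing_mm > 0)
  radius_eff <- radius_mm
  if (radius_mm < max(pet_frame$spacing)) {
    warning("disk radius ", radius_mm,
            " mm below voxel size: using nearest-voxel sampling")
    radius_eff <- 0.5 * sqrt(sum(pet_frame$spacing^2))
  }
  sub <- curve_bbox_voxels(cl, pet_frame, radius_eff + max(pet_frame$spacing))
  v <- vol_values(pet_frame)
  xyz <- grid_world_coords(pet_frame, sub)
  nc <- nearest_curve(cl, xyz)
  inside <- nc$dist <= radius_eff
  centres_s <- seq(0, cl$length, by = spacing_mm)
  disk <- pmin(floor(nc$s[inside] / spacing_mm + 0.5), length(centres_s) - 1)
  act <- v[sub[inside, , drop = FALSE]]
  activity <- vapply(seq_along(centres_s) - 1L,
                     function(j) sum(act[disk == j]), numeric(1))
  ctr <- centerline_point(cl, centres_s)
  nrm <- t(vapply(centres_s, function(s) {
    p1 <- centerline_point(cl, max(0, s - 0.5))
    p2 <- centerline_point(cl, min(cl$length, s + 0.5))
    u <- as.numeric(p2 - p1)
    u / sqrt(sum(u^2))
  }, numeric(3)))
  data.frame(s_mm = centres_s, x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
             nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
             thickness_mm = spacing_mm, radius_mm = radius_mm,
             activity_uCi = activity,
             distance_to_pleura_mm = cl$length - centres_s)
}

#' Distal cylinder ROI along the extrapolated centerline
#'
#' Voxels whose centres lie within `diameter_mm / 2` of the centerline
#' (including the straight pleural extension), clipped to the lung mask and
#' restricted to arclengths at or beyond `from_arclength` (default: where
#' the extension begins, i.e. the last CT-resolvable airway point).
#'
#' @param cl an extrapolated `centerline`.
#' @param diameter_mm cylinder diameter (default 2 mm).
#' @param lung_mask binary `label_volume`.
#' @param from_arclength arclength (mm) at which the ROI starts.
#' @return A binary `label_volume`.
#' @export
cylinder_roi <- function(cl, diameter_mm = 2, lung_mask,
                         from_arclength = cl$extension_start) {
  stopifnot(inherits(cl, "centerline"))
  if (is.na(from_arclength))
    stop("centerline has no extension; run extrapolate_to_pleura() or ",
         "give from_arclength")
  radius <- diameter_mm / 2
  if (diameter_mm < max(lung_mask$spacing)) {
    warning("cylinder diameter ", diameter_mm,
            " mm below voxel size: nearest-voxel tube")
    radius <- 0.5 * sqrt(sum(lung_mask$spacing^2))
  }
  m <- as_mask(lung_mask)
  dm <- dim(m)
  sub <- curve_bbox_voxels(cl, lung_mask, radius + max(lung_mask$spacing))
  xyz <- grid_world_coords(lung_mask, sub)
  nc <- nearest_curve(cl, xyz)
  inside <- nc$dist <= radius & nc$s >= from_arclength
  out <- array(FALSE, dim = dm)
  sel <- sub[inside, , drop = FALSE]
  keep <- m[sel]
  out[sel[keep, , drop = FALSE]] <- TRUE
  if (!any(out)) stop("cylinder ROI is empty (outside the lung mask?)")
  label_volume(out, lung_mask$spacing, lung_mask$origin)
}

#' Export a centerline as CSV
#'
#' Columns: x_mm, y_mm, z_mm, arclength_mm, is_extension.
#' @param cl a `centerline`.
#' @param path output CSV path.
#' @export
write_centerline <- function(cl, path) {
  f <- cl$fine
  write.csv(data.frame(x_mm = f$x, y_mm = f$y, z_mm = f$z,
                       arclength_mm = f$s, is_extension = f$is_extension),
            path, row.names = FALSE)
  invisible(path)
}
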