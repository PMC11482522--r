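## CT segmentation and peripheral-shell geometry.
##
## The shell is defined by the inward Euclidean distance map rather than by
## erosion iterations, so its physical thickness does not depend on voxel
## spacing; d(v) is the distance from a voxel centre to the nearest voxel
## centre outside the mask.

#' Segmentation parameters
#'
#' Defaults follow the standard thresholds for air-filled lumen and
#' aerated parenchyma on CT (HU < -700 and HU < -200), a peripheral shell
#' 1.5 mm thick, and a small-airway diameter cutoff of 200 um. The
#' `enclosure_fraction` quantifies "most of the small airways" as the 0.95
#' quantile of their pleural depth.
#'
#' @param hu_airway HU threshold below which a voxel can be airway lumen.
#' @param hu_parenchyma HU threshold below which a voxel can be lung.
#' @param closing_radius_mm ball radius for morphological closing.
#' @param shell_thickness_mm physical thickness of the peripheral shell.
#' @param small_airway_diameter_um diameter cutoff defining small airways.
#' @param enclosure_fraction fraction of small-airway skeleton voxels the
#'   reported shell depth must enclose, in (0, 1].
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(hu_airway = -700, hu_parenchyma = -200,
                                closing_radius_mm = 2,
                                shell_thickness_mm = 1.5,
                                small_airway_diameter_um = 200,
                                enclosure_fraction = 0.95) {
  if (hu_airway >= hu_parenchyma)
    stop("hu_airway must be below hu_parenchyma")
  if (shell_thickness_mm <= 0 || closing_radius_mm < 0)
    stop("thickness/radius must be positive")
  if (enclosure_fraction <= 0 || enclosure_fraction > 1)
    stop("enclosure_fraction must be in (0, 1]")
  structure(list(hu_airway = hu_airway, hu_parenchyma = hu_parenchyma,
                 closing_radius_mm = closing_radius_mm,
                 shell_thickness_mm = shell_thickness_mm,
                 small_airway_diameter_um = small_airway_diameter_um,
                 enclosure_fraction = enclosure_fraction),
            class = "segmentation_params")
}

check_binary <- function(mask) {
  v <- vol_values(mask)
  u <- unique(as.vector(v))
  if (!all(u %in% c(0L, 1L, TRUE, FALSE)))
    stop("mask must be binary (0/1)")
  invisible(TRUE)
}

seed_linear <- function(seed, dm) {
  seed <- as.integer(seed)
  if (length(seed) != 3L) stop("seed must be a voxel index (i, j, k)")
  if (any(seed < 1L) || any(seed > dm))
    stop("seed voxel ", paste(seed, collapse = ","),
         " is outside the grid")
  seed[1] + (seed[2] - 1) * dm[1] + (seed[3] - 1) * dm[1] * dm[2]
}

#' Threshold region growing
#'
#' Returns the 26-connected component of `{v : HU(v) < hu_max}` that
#' contains the seed voxel, as a binary label map. This reproduces the
#' usual "region growing thresholding" workflow used to segment airway
#' lumen (HU < -700) and lung parenchyma (HU < -200) from chest CT.
#'
#' @param ct a `scalar_volume` of Hounsfield units.
#' @param seed 1-based voxel index (i, j, k) inside the target region.
#' @param hu_max upper HU threshold (exclusive).
#' @return A binary `label_volume`.
#' @export
threshold_region_grow <- function(ct, seed, hu_max) {
  stopifnot(inherits(ct, "scalar_volume"))
  v <- vol_values(ct)
  dm <- dim(v)
  sl <- seed_linear(seed, dm)
  if (!(v[sl] < hu_max))
    stop("seed voxel has HU ", v[sl], ", not below threshold ", hu_max)
  grown <- flood_from_seed_cpp(as.vector(v < hu_max), dim(v), sl, 26L)
  label_volume(array(grown, dim = dm), ct$spacing, ct$origin)
}

edt_mm <- function(mask_arr, spacing) {
  array(edt_cpp(as.vector(mask_arr), dim(mask_arr), spacing),
        dim = dim(mask_arr))
}

#' Morphological closing plus cavity filling
#'
#' Closes a binary mask with a Euclidean ball of physical radius
#' `radius_mm` (dilation then erosion, both defined through the distance
#' transform) and then fills any background cavity that is not 6-connected
#' to the grid border. The result is always a superset of the input.
#'
#' @param mask binary `label_volume`.
#' @param radius_mm ball radius in mm.
#' @return A binary `label_volume`.
#' @export
close_mask <- function(mask, radius_mm) {
  check_binary(mask)
  m <- as_mask(mask)
  if (radius_mm > 0) {
    # dilation: voxels within radius of the mask
    d_to_fg <- edt_mm(!m, mask$spacing)
    dil <- m | (d_to_fg <= radius_mm)
    # erosion of the dilation
    d_to_bg <- edt_mm(dil, mask$spacing)
    m <- dil & (d_to_bg > radius_mm)
  }
  filled <- fill_holes_cpp(as.vector(m), dim(m))
  label_volume(array(filled, dim = dim(m)), mask$spacing, mask$origin)
}

#' Inward distance from the pleural surface
#'
#' Per-voxel Euclidean distance (mm) from the voxel centre to the nearest
#' voxel centre outside the lung mask; 0 outside the mask. Voxels beyond
#' the grid edge do not count as background.
#'
#' @param lung_mask binary, closed `label_volume` of the lung.
#' @return A `scalar_volume` of depths in mm.
#' @export
depth_from_pleura <- function(lung_mask) {
  check_binary(lung_mask)
  m <- as_mask(lung_mask)
  if (!any(m)) warning("empty lung mask: depth map is all zero")
  d <- edt_mm(m, lung_mask$spacing)
  d[!is.finite(d)] <- 0  # no background at all: degenerate, treat as interior 0-depth? keep finite
  scalar_volume(d, lung_mask$spacing, lung_mask$origin)
}

#' Peripheral 3-D shell of fixed physical thickness
#'
#' The shell is the set of mask voxels whose depth from the pleural
#' surface is at most `thickness_mm`; the rest of the mask is the core.
#' Shell and core partition the mask.
#'
#' @param lung_mask binary, closed `label_volume`.
#' @param thickness_mm shell thickness in mm (default 1.5).
#' @return A binary `label_volume` (the shell).
#' @export
hollow_shell <- function(lung_mask, thickness_mm = 1.5) {
  check_binary(lung_mask)
  m <- as_mask(lung_mask)
  if (!any(m)) {
    warning("empty lung mask: shell is empty")
    return(label_volume(array(FALSE, dim = dim(m)), lung_mask$spacing,
                        lung_mask$origin))
  }
  d <- edt_mm(m, lung_mask$spacing)
  shell <- m & d <= thickness_mm
  label_volume(shell, lung_mask$spacing, lung_mask$origin)
}

#' Shell depth enclosing most small airways
#'
#' Estimates the local airway diameter at each skeleton voxel as twice the
#' inward distance to the airway wall, selects skeleton voxels whose
#' diameter is below `small_airway_diameter_um`, and returns the smallest
#' depth D such that at least `enclosure_fraction` of those voxels lie
#' within depth D of the pleura. Intended for micro-CT-scale data where
#' sub-200-um airways are resolved.
#'
#' @param airway_mask binary `label_volume` of the airway lumen (subset of
#'   the lung).
#' @param lung_mask binary, closed `label_volume` of the lung.
#' @param params a `segmentation_params`.
#' @return The enclosing depth D in mm, with attribute `"depths"` holding
#'   the per-voxel pleural depths of the selected small-airway skeleton
#'   voxels.
#' @export
shell_depth_enclosing <- function(airway_mask, lung_mask,
                                  params = segmentation_params()) {
  check_binary(airway_mask)
  check_binary(lung_mask)
  a <- as_mask(airway_mask)
  if (!any(a)) stop("empty airway mask")
  d_air <- edt_mm(a, airway_mask$spacing)
  skel <- array(thin_skeleton_cpp(as.vector(a), dim(a), as.vector(d_air)),
                dim = dim(a))
  diam_mm <- 2 * d_air[skel]
  sel <- diam_mm < params$small_airway_diameter_um / 1000
  if (!any(sel))
    stop("no small airways resolved below ",
         params$small_airway_diameter_um, " um at this voxel spacing")
  depth <- depth_from_pleura(lung_mask)$values[skel][sel]
  depth <- sort(depth)
  D <- depth[ceiling(params$enclosure_fraction * length(depth))]
  attr(D, "depths") <- depth
  D
}

#' Compose a coded label map
#'
#' Combines parenchyma, airway and shell masks into one integer label map
#' with codes 0 = background, 1 = parenchyma, 2 = airway, 3 = shell
#' (later codes take precedence).
#'
#' @param parenchyma,airway,shell binary `label_volume`s on one geometry
#'   (any may be NULL).
#' @return A `label_volume` with codes 0-3.
#' @export
compose_label_map <- function(parenchyma = NULL, airway = NULL,
                              shell = NULL) {
  ref <- Filter(Negate(is.null), list(parenchyma, airway, shell))
  if (!length(ref)) stop("at least one mask required")
  ref <- ref[[1]]
  out <- array(0L, dim = dim(vol_values(ref)))
  if (!is.null(parenchyma)) out[as_mask(parenchyma)] <- 1L
  if (!is.null(airway)) out[as_mask(airway)] <- 2L
  if (!is.null(shell)) out[as_mask(shell)] <- 3L
  label_volume(out, ref$spacing, ref$origin)
}
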