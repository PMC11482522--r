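# Brute-force geometric oracles and small fixture builders. The oracles
# are deliberately naive (all-pairs distances, explicit dilation/erosion)
# and independent of the package's distance-transform code paths.

# distance from every TRUE voxel centre to the nearest FALSE voxel centre
# (mm); 0 on FALSE voxels. All-pairs, chunked.
brute_edt <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  out <- array(0, dm)
  fg <- which(mask)
  bg <- which(!mask)
  if (!length(fg)) return(out)
  if (!length(bg)) { out[fg] <- Inf; return(out) }
  fg_ijk <- sweep(arrayInd(fg, dm), 2, spacing, "*")
  bg_ijk <- sweep(arrayInd(bg, dm), 2, spacing, "*")
  step <- 2000L
  for (s in seq(1, length(fg), by = step)) {
    e <- min(s + step - 1L, length(fg))
    blk <- fg_ijk[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(bg_ijk^2), "+") -
      2 * blk %*% t(bg_ijk)
    out[fg[s:e]] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# brute-force morphological ball closing (dilate then erode, Euclidean
# voxel-centre distances), no hole filling
brute_close <- function(mask, radius, spacing = c(1, 1, 1)) {
  d_to_fg <- brute_edt(!mask, spacing)
  dil <- mask | (d_to_fg <= radius)
  d_to_bg <- brute_edt(dil, spacing)
  dil & (d_to_bg > radius)
}

# random blobby mask: union of a few random balls, clipped to the grid
random_blob_mask <- function(dims, n_balls = 3, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dims)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 2, dims - 1)
    r <- runif(1, 2, max(2, min(dims) / 3))
    d2 <- (idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2 + (idx[, 3] - c0[3])^2
    m[d2 <= r^2] <- TRUE
  }
  m
}

make_cube_mask <- function(n = 20, pad = 2, spacing = c(1, 1, 1)) {
  dm <- rep(n + 2 * pad, 3)
  m <- array(FALSE, dm)
  m[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- TRUE
  label_volume(m, spacing)
}

make_cylinder_mask <- function(radius_vox = 3, length_vox = 40, axis = 3,
                               pad = 4, spacing = c(1, 1, 1)) {
  side <- 2 * (radius_vox + pad) + 1
  dm <- c(side, side, length_vox + 2 * pad)
  ctr <- (side + 1) / 2
  m <- array(FALSE, dm)
  for (z in (pad + 1):(pad + length_vox))
    for (i in 1:side) for (j in 1:side)
      if ((i - ctr)^2 + (j - ctr)^2 <= radius_vox^2) m[i, j, z] <- TRUE
  perm <- switch(axis, `1` = c(3, 1, 2), `2` = c(2, 3, 1), `3` = c(1, 2, 3))
  label_volume(aperm(m, perm), spacing)
}

# small desk phantom shared by the slower end-to-end tests
small_phantom <- function(seed = 7, generations = 4) {
  spec <- phantom_spec(dims = c(48, 48, 48),
                       lung_semiaxes_mm = c(17, 15, 20),
                       tree = airway_tree_spec(generations = generations,
                                               root_length_mm = 10,
                                               root_radius_mm = 2),
                       acquisition = acquisition_spec(),
                       seed = seed)
  suppressWarnings(rasterize_ct(generate_airway_tree(spec), spec))
}

as_mask_arr <- function(lv) array(lv$labels != 0, dim(lv$labels))

phantom_seeds <- function(ph) {
  list(airway = petmcc:::phantom_airway_seed(ph),
       lung = petmcc:::phantom_lung_seed(ph))
}
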