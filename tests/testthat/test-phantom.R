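roomy_spec <- function(generations = 6, seed = 11) {
  # lung large relative to the tree so no branch is truncated
  phantom_spec(dims = c(72, 72, 72),
               lung_semiaxes_mm = c(30, 28, 34),
               tree = airway_tree_spec(generations = generations,
                                       root_length_mm = 9,
                                       root_radius_mm = 2,
                                       branch_length_ratio = 0.65),
               seed = seed)
}

test_that("the dichotomous tree has 2^g branches per generation", {
  tree <- generate_airway_tree(roomy_spec())
  expect_equal(unname(table(tree$generation)), 2^(0:6),
               ignore_attr = TRUE)
  expect_false(any(tree$truncated))
  # child radius scales by the radius ratio each generation
  expect_equal(unique(tree$radius_mm[tree$generation == 6]), 2 * 0.7^6)
})

test_that("a 1.5 mm root at ratio 0.7 tapers to the small-airway scale", {
  sp <- roomy_spec()
  sp$tree$root_radius_mm <- 1.5
  tree <- generate_airway_tree(sp)
  gen6_radius_um <- unique(tree$radius_mm[tree$generation == 6]) * 1000
  expect_equal(gen6_radius_um, 1.5 * 0.7^6 * 1000, tolerance = 1e-12)
  expect_lt(gen6_radius_um, 200)
})

test_that("tree generation is deterministic in the seed", {
  t1 <- generate_airway_tree(roomy_spec(seed = 5))
  t2 <- generate_airway_tree(roomy_spec(seed = 5))
  t3 <- generate_airway_tree(roomy_spec(seed = 6))
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$x1, t3$x1)))
})

test_that("branches leaving the lung are truncated with a warning", {
  sp <- phantom_spec(dims = c(40, 40, 40), lung_semiaxes_mm = c(10, 10, 12),
                     tree = airway_tree_spec(generations = 3,
                                             root_length_mm = 14,
                                             root_radius_mm = 2))
  expect_warning(tree <- generate_airway_tree(sp), "truncated")
  expect_true(any(tree$truncated))
})

test_that("rasterized HU classes straddle the segmentation thresholds", {
  sp <- roomy_spec(generations = 3)
  ph <- rasterize_ct(generate_airway_tree(sp), sp)
  v <- ph$ct$values
  lum <- as_mask_arr(ph$lumen)
  lng <- as_mask_arr(ph$lung)
  expect_true(all(v[lum] < -700))
  expect_true(all(v[lng & !lum] > -700 & v[lng & !lum] < -200))
  expect_true(all(!lum | lng))         # no airway voxel outside the lung
  # region-growing recovers nearly all rasterized lumen voxels
  seed <- petmcc:::phantom_airway_seed(ph)
  got <- threshold_region_grow(ph$ct, seed, -700)
  expect_gte(sum(got$labels & ph$lumen$labels) / sum(ph$lumen$labels), 0.95)
})

test_that("rasterized lumen volume approximates the analytic capsule volume", {
  sp <- phantom_spec(dims = c(96, 96, 96), spacing = rep(0.5, 3),
                     lung_semiaxes_mm = c(21, 20, 23),
                     tree = airway_tree_spec(generations = 2,
                                             root_length_mm = 8,
                                             root_radius_mm = 2,
                                             branch_length_ratio = 0.7),
                     seed = 3)
  tree <- generate_airway_tree(sp)
  ph <- rasterize_ct(tree, sp)
  L <- sqrt((tree$x1 - tree$x0)^2 + (tree$y1 - tree$y0)^2 +
              (tree$z1 - tree$z0)^2)
  analytic <- sum(pi * tree$radius_mm^2 * L)
  voxvol <- sum(ph$lumen$labels) * prod(sp$spacing)
  # overlap at bifurcations makes the voxel count slightly smaller
  expect_lt(abs(voxvol - analytic) / analytic, 0.15)
})

test_that("spacing too coarse for the root airway is refused", {
  sp <- roomy_spec()
  sp$spacing <- c(2, 2, 2)
  expect_error(rasterize_ct(generate_airway_tree(sp), sp), "coarse")
})

small_dynamics <- function(kin = kinetics_spec(0, 0, 0), ...) {
  sp <- phantom_spec(dims = c(40, 40, 40), lung_semiaxes_mm = c(14, 13, 16),
                     tree = airway_tree_spec(generations = 2,
                                             root_length_mm = 8,
                                             root_radius_mm = 2),
                     acquisition = acquisition_spec(frame_duration_s = 30,
                                                    total_duration_min = 5),
                     seed = 21)
  ph <- rasterize_ct(generate_airway_tree(sp), sp)
  list(ph = ph, dyn = simulate_dynamics(ph, kin, ...))
}

test_that("a static phantom with everything off gives identical frames", {
  d <- small_dynamics(kinetics_spec(0, 0, 0), psf = FALSE, noise = FALSE,
                      decay = FALSE)
  v <- d$dyn$series$values
  for (fr in 2:dim(v)[4]) expect_identical(v[, , , fr], v[, , , 1])
  expect_true(all(d$dyn$truth$pct_true == 0))
})

test_that("decay-only kinetics follow the pure decay law exactly", {
  d <- small_dynamics(kinetics_spec(0, 0, 0), psf = FALSE, noise = FALSE,
                      decay = TRUE)
  tac <- extract_tac(d$dyn$series, label_volume(
    array(TRUE, dim(d$ph$ct$values)), d$ph$ct$spacing, d$ph$ct$origin))
  A0 <- d$dyn$truth$A0_uCi
  expect_equal(tac$activity_uCi, A0 * 2^(-tac$times_min / 68),
               tolerance = 1e-12)
  # decay correction flattens it
  cor <- decay_correct(tac, 68, t_ref_min = 0)
  expect_equal(cor$activity_uCi, rep(A0, length(cor$activity_uCi)),
               tolerance = 1e-10)
})

test_that("PSF blur preserves total activity away from the edges", {
  # interior source: conservation to well under 0.1%
  arr <- array(0, c(48, 48, 48))
  arr[20:28, 20:28, 20:28] <- 1
  blurred <- petmcc:::gaussian_blur_3d(arr, c(5.5, 4.5, 6) / 2.3548,
                                       c(1, 1, 1))
  expect_lt(abs(sum(blurred) - sum(arr)) / sum(arr), 1e-4)
  # peripheral-shell source sits nearer the grid edge: still within 1%
  d <- small_dynamics(kinetics_spec(0.18, 0.8, 0.008), psf = TRUE,
                      noise = FALSE, decay = FALSE, open_system = FALSE)
  tot <- apply(d$dyn$series$values, 4, sum)
  A0 <- d$dyn$truth$A0_uCi
  expect_true(all(abs(tot - A0) / A0 < 0.01))
})

test_that("closed-system decay-corrected activity is conserved", {
  d <- small_dynamics(kinetics_spec(0.3, 0.5, 0.01), psf = FALSE,
                      noise = FALSE, decay = TRUE, open_system = FALSE)
  tac <- extract_tac(d$dyn$series, label_volume(
    array(TRUE, dim(d$ph$ct$values)), d$ph$ct$spacing, d$ph$ct$origin))
  cor <- decay_correct(tac, 68, t_ref_min = 0)
  expect_equal(cor$activity_uCi,
               rep(d$dyn$truth$A0_uCi, length(cor$activity_uCi)),
               tolerance = 1e-10)
})

test_that("noisy simulation is reproducible from its seed", {
  d1 <- small_dynamics(kinetics_spec(0.3, 0.5, 0.01), psf = TRUE,
                       noise = TRUE, decay = TRUE, seed = 77)
  d2 <- small_dynamics(kinetics_spec(0.3, 0.5, 0.01), psf = TRUE,
                       noise = TRUE, decay = TRUE, seed = 77)
  expect_identical(d1$dyn$series$values, d2$dyn$series$values)
  d3 <- small_dynamics(kinetics_spec(0.3, 0.5, 0.01), psf = TRUE,
                       noise = TRUE, decay = TRUE, seed = 78)
  expect_false(identical(d1$dyn$series$values, d3$dyn$series$values))
})

test_that("Poisson decoding is unbiased for the whole-volume count rate", {
  d <- small_dynamics(kinetics_spec(0, 0, 0), psf = FALSE, noise = TRUE,
                      decay = FALSE, seed = 5)
  tot <- apply(d$dyn$series$values, 4, sum)
  A0 <- d$dyn$truth$A0_uCi
  # relative Poisson SE of a 30-s whole-volume frame at A0 = 100 uCi
  lam <- A0 * 37 * 7.3 * 30
  se <- A0 / sqrt(lam)
  expect_lt(abs(mean(tot) - A0), 4 * se / sqrt(length(tot)))
})

test_that("cohorts have the requested structure, jitter and manifest", {
  sp <- phantom_spec(dims = c(40, 40, 40), lung_semiaxes_mm = c(14, 13, 16),
                     tree = airway_tree_spec(generations = 2,
                                             root_length_mm = 8,
                                             root_radius_mm = 2),
                     acquisition = acquisition_spec(frame_duration_s = 60,
                                                    total_duration_min = 3),
                     seed = 2)
  kin <- kinetics_presets()[c("non-CF", "CF")]
  co <- make_cohort(kin, n_per_group = 3, spec = sp, jitter_sigma = 0.1,
                    psf = FALSE, noise = FALSE)
  expect_equal(nrow(co$manifest), 6)
  expect_equal(table(co$manifest$group),
               table(rep(c("CF", "non-CF"), each = 3)))
  expect_equal(length(co$dynamics), 6)
  # sigma = 0 makes all subjects in a group identical
  co0 <- make_cohort(kin, n_per_group = 2, spec = sp, jitter_sigma = 0,
                     psf = FALSE, noise = FALSE)
  m <- co0$manifest
  expect_equal(m$f[m$group == "CF"][1], m$f[m$group == "CF"][2])
  expect_equal(m$k_fast[m$group == "non-CF"][1],
               m$k_fast[m$group == "non-CF"][2])
})

test_that("written cohorts round-trip through the manifest and NIfTI", {
  sp <- phantom_spec(dims = c(32, 32, 32), lung_semiaxes_mm = c(11, 10, 12),
                     tree = airway_tree_spec(generations = 1,
                                             root_length_mm = 6,
                                             root_radius_mm = 2),
                     acquisition = acquisition_spec(frame_duration_s = 60,
                                                    total_duration_min = 2),
                     seed = 9)
  dir <- withr::local_tempdir()
  co <- make_cohort(kinetics_presets()["CF"], n_per_group = 2, spec = sp,
                    dir = dir, psf = FALSE, noise = FALSE)
  expect_true(file.exists(file.path(dir, "ct.nii.gz")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "CF_01", "pet_4d.nii.gz")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$subjects$subject_id, c("CF_01", "CF_02"))
  ser <- read_series(file.path(dir, "CF_01", "pet_4d.nii.gz"))
  expect_equal(ser$values, co$dynamics$CF_01$series$values,
               tolerance = 1e-6)
})

test_that("ground-truth %Cleared from the record matches a clean pipeline run", {
  d <- small_dynamics(kinetics_spec(0.4, 0.6, 0.01), psf = FALSE,
                      noise = FALSE, decay = TRUE)
  sh <- hollow_shell(d$ph$lung, 1.5)
  tac <- decay_correct(extract_tac(d$dyn$series, sh), 68)
  cc <- percent_cleared(tac)
  expect_equal(cc$pct_cleared, d$dyn$truth$pct_true_frame,
               tolerance = 1e-10)
})

test_that("curve-level cohort simulation is seeded and labelled", {
  cu <- simulate_cohort_curves(kinetics_presets()[c("non-CF", "CF")],
                               n_per_group = 2, seed = 4)
  expect_length(cu, 4)
  expect_equal(unname(vapply(cu, `[[`, character(1), "group")),
               rep(c("non-CF", "CF"), each = 2))
  cu2 <- simulate_cohort_curves(kinetics_presets()[c("non-CF", "CF")],
                                n_per_group = 2, seed = 4)
  expect_identical(cu[[1]]$pct_cleared, cu2[[1]]$pct_cleared)
})
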