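## Digital newborn-pig thorax phantom: a dichotomously branching airway
## tree inside an ellipsoidal lung, rasterized into HU classes that
## straddle the segmentation thresholds, overlaid with a dynamic tracer
## distribution following two-phase clearance kinetics, radioactive decay,
## scanner PSF blur and Poisson counting.

#' Airway-tree generative parameters
#'
#' A binary (dichotomous) tree: each parent splits into two shorter,
#' narrower daughters. Desk-scale default is 6 generations (anatomical
#' airways branch for ~22). With the default radius ratio 0.7 the
#' generation-6 branches are below the 200-um small-airway cutoff when the
#' root radius is 1.5 mm or less.
#'
#' @param generations number of branching generations (>= 1).
#' @param root_radius_mm radius of the root (main bronchus) branch.
#' @param root_length_mm length of the root branch.
#' @param branch_length_ratio daughter/parent length ratio in (0, 1].
#' @param branch_radius_ratio daughter/parent radius ratio in (0, 1].
#' @param branching_angle_deg half-angle between daughters and the parent
#'   axis.
#' @param angle_jitter_deg uniform jitter applied to branching and
#'   azimuthal angles.
#' @return An object of class `airway_tree_spec`.
#' @export
airway_tree_spec <- function(generations = 6, root_radius_mm = 2,
                             root_length_mm = 18,
                             branch_length_ratio = 0.72,
                             branch_radius_ratio = 0.7,
                             branching_angle_deg = 35,
                             angle_jitter_deg = 5) {
  if (generations < 1) stop("generations must be >= 1")
  if (branch_length_ratio <= 0 || branch_length_ratio > 1 ||
      branch_radius_ratio <= 0 || branch_radius_ratio > 1)
    stop("ratios must lie in (0, 1]")
  if (root_radius_mm <= 0 || root_length_mm <= 0)
    stop("root dimensions must be positive")
  structure(list(generations = as.integer(generations),
                 root_radius_mm = root_radius_mm,
                 root_length_mm = root_length_mm,
                 branch_length_ratio = branch_length_ratio,
                 branch_radius_ratio = branch_radius_ratio,
                 branching_angle_deg = branching_angle_deg,
                 angle_jitter_deg = angle_jitter_deg),
            class = "airway_tree_spec")
}

#' Ground-truth clearance kinetics for one group/region
#'
#' @param f fast fraction in [0, 1].
#' @param k_fast,k_slow clearance rate constants (1/min),
#'   `k_fast >= k_slow >= 0`.
#' @param A0_uCi initially deposited activity (uCi).
#' @param group group label.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(f, k_fast, k_slow, A0_uCi = 100,
                          group = NA_character_) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (k_fast < k_slow || k_slow < 0) stop("need k_fast >= k_slow >= 0")
  if (A0_uCi < 0) stop("activity must be non-negative")
  structure(list(f = f, k_fast = k_fast, k_slow = k_slow,
                 A0_uCi = A0_uCi, group = group),
            class = "kinetics_spec")
}

#' Default group kinetics
#'
#' Two-phase parameter triples whose true 12-min %Cleared sits near the
#' group means observed in vivo for peripheral-shell clearance in newborn
#' pigs (non-CF ~25%, CF ~15%, non-CF+UTP ~21%, CF+UTP ~13%), with a fast
#' phase over in the first ~5 min and a much slower late phase.
#'
#' @return Named list of `kinetics_spec` objects.
#' @export
kinetics_presets <- function() {
  list(
    "non-CF"     = kinetics_spec(0.18, 0.8, 0.0080, group = "non-CF"),
    "CF"         = kinetics_spec(0.10, 0.6, 0.0045, group = "CF"),
    "non-CF+UTP" = kinetics_spec(0.15, 0.7, 0.0060, group = "non-CF+UTP"),
    "CF+UTP"     = kinetics_spec(0.09, 0.6, 0.0037, group = "CF+UTP"))
}

#' Full phantom description
#'
#' @param dims grid dimensions (default 96^3 voxels).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param origin world origin in mm.
#' @param lung_semiaxes_mm ellipsoid semi-axes of the lung.
#' @param body_margin_mm soft-tissue margin added around the lung
#'   ellipsoid to form the body.
#' @param hu HU values for the four classes; they must straddle the
#'   segmentation thresholds (lumen < -700 < parenchyma < -200 <
#'   soft tissue).
#' @param tree an `airway_tree_spec`.
#' @param acquisition an `acquisition_spec`.
#' @param seed integer seed driving all stochastic draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(96, 96, 96), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0),
                         lung_semiaxes_mm = c(32, 28, 40),
                         body_margin_mm = 6,
                         hu = list(lumen = -1000, parenchyma = -500,
                                   soft_tissue = 50, background = -1000),
                         tree = airway_tree_spec(),
                         acquisition = acquisition_spec(), seed = 1L) {
  if (!(hu$lumen < -700 && -700 < hu$parenchyma && hu$parenchyma < -200 &&
        -200 < hu$soft_tissue))
    stop("HU classes must straddle the -700/-200 thresholds")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 lung_semiaxes_mm = as.numeric(lung_semiaxes_mm),
                 body_margin_mm = body_margin_mm, hu = hu, tree = tree,
                 acquisition = acquisition, seed = as.integer(seed)),
            class = "phantom_spec")
}

rotate_about <- function(u, theta, phi, e1, e2) {
  cos(theta) * u + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
}

perp_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

## first t in (0, 1] at which p + t*v leaves the ellipsoid (centre c, semi s)
ellipsoid_exit <- function(p, v, centre, semi) {
  a <- sum((v / semi)^2)
  b <- 2 * sum((p - centre) * v / semi^2)
  cc <- sum(((p - centre) / semi)^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  t <- (-b + sqrt(disc)) / (2 * a)
  if (t < 0 || t > 1) NA_real_ else t
}

#' Generate a dichotomous airway tree
#'
#' Builds the branch list recursively: generation g holds 2^g branches,
#' each daughter scaled from its parent by the length and radius ratios
#' and rotated off the parent axis by the branching angle (with jitter);
#' the azimuthal plane rotates ~90 degrees between generations, as in real
#' airway trees. Branches that would exit the lung ellipsoid are truncated
#' at the surface (with a warning) and spawn no daughters. Deterministic
#' given the seed.
#'
#' @param spec a `phantom_spec` (tree, lung geometry and seed) or an
#'   `airway_tree_spec` (then lung centre/semi-axes are taken from
#'   `phantom_spec()` defaults).
#' @param seed overrides the seed stored in the phantom description.
#' @return data.frame of class `airway_tree`: one row per branch with
#'   start/end coordinates (mm), radius, generation, parent index and
#'   truncation flag.
#' @export
generate_airway_tree <- function(spec = phantom_spec(), seed = NULL) {
  if (inherits(spec, "airway_tree_spec"))
    spec <- phantom_spec(tree = spec)
  ts <- spec$tree
  if (is.null(seed)) seed <- spec$seed
  centre <- spec$origin + (spec$dims - 1) * spec$spacing / 2
  semi <- spec$lung_semiaxes_mm
  with_seed(seed, {
    rows <- list()
    n_trunc <- 0L
    recurse <- function(p, u, phi, len, rad, gen, parent) {
      v <- len * u
      te <- ellipsoid_exit(p, v, centre, semi)
      trunc <- !is.na(te)
      q <- if (trunc) p + te * v else p + v
      rows[[length(rows) + 1L]] <<- data.frame(
        id = length(rows) + 1L, parent = parent, generation = gen,
        x0 = p[1], y0 = p[2], z0 = p[3], x1 = q[1], y1 = q[2], z1 = q[3],
        radius_mm = rad, truncated = trunc)
      my_id <- length(rows)
      if (trunc) {
        n_trunc <<- n_trunc + 1L
        return(invisible())
      }
      if (gen >= ts$generations) return(invisible())
      jit <- function() runif(1, -ts$angle_jitter_deg, ts$angle_jitter_deg)
      theta <- (ts$branching_angle_deg + jit()) * pi / 180
      phi_new <- phi + pi / 2 + jit() * pi / 180
      b <- perp_basis(u)
      for (side in c(0, pi)) {
        d <- rotate_about(u, theta, phi_new + side, b$e1, b$e2)
        d <- d / sqrt(sum(d^2))
        recurse(q, d, phi_new, len * ts$branch_length_ratio,
                rad * ts$branch_radius_ratio, gen + 1L, my_id)
      }
    }
    root_p <- centre + c(0, 0, 0.85 * semi[3])
    recurse(root_p, c(0, 0, -1), 0, ts$root_length_mm, ts$root_radius_mm,
            0L, NA_integer_)
    if (n_trunc > 0)
      warning(n_trunc, " branch(es) truncated at the lung surface")
    tree <- do.call(rbind, rows)
    class(tree) <- c("airway_tree", "data.frame")
    attr(tree, "spec") <- spec
    tree
  })
}

ellipsoid_mask <- function(dims, spacing, origin, centre, semi) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  qx <- ((xs - centre[1]) / semi[1])^2
  qy <- ((ys - centre[2]) / semi[2])^2
  qz <- ((zs - centre[3]) / semi[3])^2
  array(outer(outer(qx, qy, "+"), qz, "+") <= 1, dim = dims)
}

## voxels within `radius` of segment p-q (capsule), restricted to a
## bounding subgrid; returns linear indices
capsule_voxels <- function(p, q, radius, dims, spacing, origin) {
  lo <- pmax(1, floor((pmin(p, q) - radius - origin) / spacing) + 1)
  hi <- pmin(dims, ceiling((pmax(p, q) + radius - origin) / spacing) + 1)
  if (any(lo > hi)) return(integer(0))
  sub <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  xyz <- sweep(sweep(sub - 1, 2, spacing, "*"), 2, origin, "+")
  v <- q - p
  L2 <- sum(v^2)
  w <- sweep(xyz, 2, p)
  t <- if (L2 > 0) pmin(1, pmax(0, (w %*% v) / L2)) else matrix(0, nrow(w))
  d2 <- rowSums((w - t %*% t(v))^2)
  sel <- d2 <= radius^2
  sub <- sub[sel, , drop = FALSE]
  sub[, 1] + (sub[, 2] - 1) * dims[1] + (sub[, 3] - 1) * dims[1] * dims[2]
}

#' Rasterize the phantom CT
#'
#' Voxelizes the airway tree and lung ellipsoid into HU classes: airway
#' lumen below -700, parenchyma between -700 and -200, soft tissue above
#' -200, background air outside the body. Errors if the voxel spacing
#' does not put at least 4 voxels across the root airway diameter.
#'
#' @param tree an `airway_tree` from [generate_airway_tree()].
#' @param spec the `phantom_spec` (defaults to the one stored on the
#'   tree).
#' @return A list of class `ct_phantom`: `ct` (`scalar_volume`), plus
#'   ground-truth masks `lumen`, `lung`, `body` (`label_volume`s) and the
#'   per-branch voxel lists.
#' @export
rasterize_ct <- function(tree, spec = attr(tree, "spec")) {
  stopifnot(inherits(tree, "airway_tree"), inherits(spec, "phantom_spec"))
  if (2 * spec$tree$root_radius_mm / max(spec$spacing) < 4)
    stop("voxel spacing too coarse: need >= 4 voxels across the root ",
         "airway diameter")
  dims <- spec$dims
  centre <- spec$origin + (dims - 1) * spec$spacing / 2
  lung <- ellipsoid_mask(dims, spec$spacing, spec$origin, centre,
                         spec$lung_semiaxes_mm)
  body <- ellipsoid_mask(dims, spec$spacing, spec$origin, centre,
                         spec$lung_semiaxes_mm + spec$body_margin_mm)
  lumen <- array(FALSE, dim = dims)
  branch_vox <- vector("list", nrow(tree))
  for (b in seq_len(nrow(tree))) {
    idx <- capsule_voxels(c(tree$x0[b], tree$y0[b], tree$z0[b]),
                          c(tree$x1[b], tree$y1[b], tree$z1[b]),
                          tree$radius_mm[b], dims, spec$spacing,
                          spec$origin)
    idx <- idx[lung[idx]]               # no airway voxel outside the lung
    branch_vox[[b]] <- idx
    lumen[idx] <- TRUE
  }
  ct <- array(spec$hu$background, dim = dims)
  ct[body] <- spec$hu$soft_tissue
  ct[lung] <- spec$hu$parenchyma
  ct[lumen] <- spec$hu$lumen
  structure(list(ct = scalar_volume(ct, spec$spacing, spec$origin),
                 lumen = label_volume(lumen, spec$spacing, spec$origin),
                 lung = label_volume(lung, spec$spacing, spec$origin),
                 body = label_volume(body, spec$spacing, spec$origin),
                 branch_voxels = branch_vox, tree = tree, spec = spec),
            class = "ct_phantom")
}

## separable Gaussian blur; kernel normalized to unit mass so total
## activity is preserved away from grid edges
gaussian_blur_3d <- function(arr, sigma_mm, spacing) {
  dm <- dim(arr)
  for (ax in 1:3) {
    sig <- sigma_mm[ax] / spacing[ax]
    if (sig <= 0) next
    R <- max(1L, ceiling(4 * sig))
    g <- dnorm(-R:R, sd = sig)
    g <- g / sum(g)
    n <- dm[ax]
    K <- matrix(0, n, n)
    for (o in -R:R) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- g[o + R + 1]
    }
    if (ax == 1) {
      arr <- array(K %*% matrix(arr, dm[1]), dim = dm)
    } else if (ax == 2) {
      a <- aperm(arr, c(2, 1, 3))
      a <- array(K %*% matrix(a, dm[2]), dim = dm[c(2, 1, 3)])
      arr <- aperm(a, c(2, 1, 3))
    } else {
      a <- aperm(arr, c(3, 1, 2))
      a <- array(K %*% matrix(a, dm[3]), dim = dm[c(3, 1, 2)])
      arr <- aperm(a, c(3, 1, 2))
    }
  }
  arr
}

#' Simulate the dynamic PET series of a phantom
#'
#' Tracer is deposited in a distal region (default: the peripheral shell
#' of the lung, standing in for small-airway deposition) and cleared with
#' two-phase kinetics; cleared activity is re-deposited uniformly along
#' the proximal airway lumen (generations 0-1) in closed-system mode, or
#' removed from the body in open-system mode (the default, mimicking
#' transport out of the lungs). Regional activity at the frame midpoint t
#' (minutes) is `A0 * (1 - pct(t)/100) * 2^(-t / half_life)`; frames are
#' then blurred with the anisotropic Gaussian PSF and Poisson counting
#' noise is applied at rate `activity x sensitivity x duration` before
#' decoding back to activity units.
#'
#' @param phantom a `ct_phantom`.
#' @param kinetics a `kinetics_spec`.
#' @param acquisition an `acquisition_spec`; defaults to the phantom's.
#' @param deposit `"shell"` (peripheral shell of the lung, default) or
#'   `"terminal"` (lumen of the deepest rasterized branch generation).
#' @param shell_thickness_mm deposition shell thickness when
#'   `deposit = "shell"`.
#' @param psf,noise,decay logical switches for PSF blur, Poisson noise and
#'   radioactive decay.
#' @param open_system remove cleared activity (TRUE) or move it to the
#'   proximal airway (FALSE).
#' @param seed RNG seed for the Poisson draws (defaults to the phantom
#'   spec seed); mandatory when `noise = TRUE`.
#' @return A list of class `phantom_dynamics`: `series` (a
#'   `dynamic_series`), `truth` (times, true %Cleared, A0, kinetics,
#'   deposition/proximal voxel indices).
#' @export
simulate_dynamics <- function(phantom, kinetics,
                              acquisition = phantom$spec$acquisition,
                              deposit = c("shell", "terminal"),
                              shell_thickness_mm = 1.5,
                              psf = TRUE, noise = TRUE, decay = TRUE,
                              open_system = TRUE, seed = phantom$spec$seed) {
  stopifnot(inherits(phantom, "ct_phantom"),
            inherits(kinetics, "kinetics_spec"))
  deposit <- match.arg(deposit)
  if (noise && is.null(seed)) stop("a seed is required when noise is on")
  dims <- dim(phantom$ct$values)
  spacing <- phantom$ct$spacing
  if (deposit == "shell") {
    sh <- hollow_shell(phantom$lung, shell_thickness_mm)
    dep_idx <- which(as_mask(sh))
  } else {
    gen <- phantom$tree$generation
    nvox <- vapply(phantom$branch_voxels, length, integer(1))
    gmax <- max(gen[nvox > 0])
    dep_idx <- unique(unlist(phantom$branch_voxels[gen == gmax]))
  }
  if (!length(dep_idx)) stop("empty deposition region")
  prox_idx <- unique(unlist(
    phantom$branch_voxels[phantom$tree$generation <= 1]))

  dt <- acquisition$frame_duration_s
  total_s <- acquisition$total_duration_min * 60
  nf <- ceiling(total_s / dt)
  starts <- (seq_len(nf) - 1) * dt
  ends <- pmin(starts + dt, total_s)
  mid_min <- (starts + ends) / 2 / 60
  pct <- two_phase_pct(mid_min, kinetics$f, kinetics$k_fast,
                       kinetics$k_slow)
  dk <- if (decay) 2^(-mid_min / acquisition$half_life_min) else rep(1, nf)

  A0 <- kinetics$A0_uCi
  sigma <- acquisition$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  vals <- array(0, dim = c(dims, nf))
  sim <- function() {
    for (fr in seq_len(nf)) {
      vol <- array(0, dim = dims)
      vol[dep_idx] <- A0 * (1 - pct[fr] / 100) / length(dep_idx)
      if (!open_system)
        vol[prox_idx] <- vol[prox_idx] +
          A0 * (pct[fr] / 100) / length(prox_idx)
      vol <- vol * dk[fr]
      if (psf) vol <- gaussian_blur_3d(vol, sigma, spacing)
      if (noise) {
        dur <- ends[fr] - starts[fr]
        lambda <- vol * 37 * acquisition$sensitivity_cps_per_kBq * dur
        counts <- rpois(length(lambda), as.vector(lambda))
        vol <- array(counts / (37 * acquisition$sensitivity_cps_per_kBq *
                                 dur), dim = dims)
      }
      vals[, , , fr] <<- vol
    }
  }
  if (noise) with_seed(seed, sim()) else sim()
  series <- dynamic_series(vals, cbind(starts, ends), spacing,
                           phantom$ct$origin)
  # the pipeline references %Cleared to the first post-delivery frame, so
  # record the truth in that convention too (pct_true is referenced to t=0)
  pct_frame <- 100 * (1 - (1 - pct / 100) / (1 - pct[1] / 100))
  structure(list(series = series,
                 truth = list(times_min = mid_min, pct_true = pct,
                              pct_true_frame = pct_frame,
                              A0_uCi = A0, kinetics = kinetics,
                              deposit_idx = dep_idx, prox_idx = prox_idx,
                              open_system = open_system, psf = psf,
                              noise = noise, decay = decay, seed = seed)),
            class = "phantom_dynamics")
}

jitter_kinetics <- function(k, sigma) {
  if (sigma <= 0) return(k)
  logit <- function(p) log(p / (1 - p))
  f <- 1 / (1 + exp(-(logit(min(max(k$f, 1e-6), 1 - 1e-6)) +
                        rnorm(1, 0, sigma))))
  kf <- k$k_fast * exp(rnorm(1, 0, sigma))
  ks <- k$k_slow * exp(rnorm(1, 0, sigma))
  kinetics_spec(f, max(kf, ks), min(kf, ks), k$A0_uCi, k$group)
}

#' Simulate a cohort of phantom subjects
#'
#' One phantom CT is shared by all subjects; each subject gets its own
#' clearance kinetics (group truth plus multiplicative log-normal jitter
#' on the rate constants and logit-normal jitter on the fast fraction)
#' and its own seeded noise realisation. Subject s of group g draws from
#' the stream `seed + 1000 * g + s`. Optionally writes each dataset to
#' `dir` as NIfTI plus a `manifest.json` recording every true parameter.
#'
#' @param group_kinetics named list of `kinetics_spec` (one per group).
#' @param n_per_group subjects per group (recycled over groups).
#' @param spec a `phantom_spec`.
#' @param jitter_sigma per-subject biological variability (log/logit SD).
#' @param dir output directory; NULL (default) keeps everything in
#'   memory.
#' @param seed master seed.
#' @param ... passed to [simulate_dynamics()] (psf, noise, deposit, ...).
#' @return A list of class `phantom_cohort`: `manifest` (data.frame of
#'   subject ids, groups and true parameters), `phantom` (the shared
#'   `ct_phantom`), `dynamics` (per-subject `phantom_dynamics`), `dir`.
#' @export
make_cohort <- function(group_kinetics, n_per_group = 3,
                        spec = phantom_spec(), jitter_sigma = 0.1,
                        dir = NULL, seed = spec$seed, ...) {
  stopifnot(length(group_kinetics) >= 1)
  if (is.null(names(group_kinetics)))
    names(group_kinetics) <- vapply(group_kinetics, `[[`, character(1),
                                    "group")
  n_per_group <- rep_len(n_per_group, length(group_kinetics))
  tree <- generate_airway_tree(spec, seed = seed)
  phantom <- rasterize_ct(tree, spec)
  subjects <- list()
  rows <- list()
  for (g in seq_along(group_kinetics)) {
    for (s in seq_len(n_per_group[g])) {
      sid <- sprintf("%s_%02d", names(group_kinetics)[g], s)
      if (sid %in% names(subjects)) stop("duplicate subject id: ", sid)
      sseed <- seed + 1000L * g + s
      k <- with_seed(sseed, jitter_kinetics(group_kinetics[[g]],
                                            jitter_sigma))
      dyn <- simulate_dynamics(phantom, k, seed = sseed, ...)
      subjects[[sid]] <- dyn
      rows[[sid]] <- data.frame(
        subject_id = sid, group = names(group_kinetics)[g], seed = sseed,
        f = k$f, k_fast = k$k_fast, k_slow = k$k_slow, A0_uCi = k$A0_uCi,
        pct_true_12min = two_phase_pct(12, k$f, k$k_fast, k$k_slow),
        pct_true_frame_12min = approx(dyn$truth$times_min,
                                      dyn$truth$pct_true_frame,
                                      xout = 12)$y)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  out <- structure(list(manifest = manifest, phantom = phantom,
                        dynamics = subjects, dir = dir),
                   class = "phantom_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
    for (sid in names(subjects)) {
      sdir <- file.path(dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      write_series(subjects[[sid]]$series,
                   file.path(sdir, "pet_4d.nii.gz"))
    }
    jsonlite::write_json(
      list(seed = seed, groups = names(group_kinetics),
           subjects = manifest),
      file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  }
  out
}

#' Simulate clearance curves without the imaging chain
#'
#' A light-weight cohort generator used for statistical calibration: each
#' subject's true %Cleared curve (group kinetics plus the same jitter
#' model as [make_cohort()]) is sampled on a frame-midpoint time grid with
#' additive Gaussian noise.
#'
#' @param group_kinetics named list of `kinetics_spec`.
#' @param n_per_group subjects per group.
#' @param times_min sampling times (default: 10-s frame midpoints over
#'   the 15-min acquisition).
#' @param noise_sd_pct Gaussian noise SD in %Cleared units.
#' @param jitter_sigma per-subject kinetic variability.
#' @param seed master seed.
#' @return List of `clearance_curve`s with group labels and a
#'   `"manifest"` attribute of true parameters.
#' @export
simulate_cohort_curves <- function(group_kinetics, n_per_group = 6,
                                   times_min = seq(5, 900, by = 10) / 60,
                                   noise_sd_pct = 1, jitter_sigma = 0.1,
                                   seed = 1L) {
  if (is.null(names(group_kinetics)))
    names(group_kinetics) <- vapply(group_kinetics, `[[`, character(1),
                                    "group")
  n_per_group <- rep_len(n_per_group, length(group_kinetics))
  curves <- list()
  rows <- list()
  with_seed(seed, {
    for (g in seq_along(group_kinetics)) {
      for (s in seq_len(n_per_group[g])) {
        k <- jitter_kinetics(group_kinetics[[g]], jitter_sigma)
        pct <- two_phase_pct(times_min, k$f, k$k_fast, k$k_slow) +
          rnorm(length(times_min), 0, noise_sd_pct)
        sid <- sprintf("%s_%02d", names(group_kinetics)[g], s)
        curves[[sid]] <- clearance_curve(times_min, pct, subject_id = sid,
                                         group = names(group_kinetics)[g])
        rows[[sid]] <- data.frame(subject_id = sid,
                                  group = names(group_kinetics)[g],
                                  f = k$f, k_fast = k$k_fast,
                                  k_slow = k$k_slow)
      }
    }
  })
  attr(curves, "manifest") <- do.call(rbind, rows)
  curves
}
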