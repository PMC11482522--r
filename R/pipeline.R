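## End-to-end orchestration: phantom or real data -> segmentation -> ROI
## schemes -> %Cleared curves -> group statistics, with a JSON/CSV report.
## Every number in the report is reproducible by calling the module
## functions directly; the pipeline adds no computation of its own.

#' Pipeline configuration
#'
#' Assembles all tunables with the package defaults: segmentation
#' thresholds and shell thickness, acquisition constants, the analysis
#' scheme(s), and the endpoint/threshold of the responder classification.
#'
#' @param scheme one of "shell", "cylinder", "disks", "all".
#' @param params a `segmentation_params`.
#' @param acquisition an `acquisition_spec`.
#' @param endpoint_min endpoint for responder classification (min).
#' @param threshold_pct responder threshold (%Cleared, strict `>`).
#' @param cylinder_diameter_mm diameter of the distal cylinder ROI.
#' @param disk_spacing_mm arclength spacing of perpendicular disks.
#' @param disk_radius_mm radius of perpendicular disks.
#' @param alpha significance level flagged in reports.
#' @param out_dir output directory (NULL: nothing written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = c("shell", "cylinder", "disks", "all"),
                            params = segmentation_params(),
                            acquisition = acquisition_spec(),
                            endpoint_min = 12, threshold_pct = 20,
                            cylinder_diameter_mm = 2,
                            disk_spacing_mm = 2, disk_radius_mm = 3,
                            alpha = 0.01, out_dir = NULL) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, params = params,
                 acquisition = acquisition, endpoint_min = endpoint_min,
                 threshold_pct = threshold_pct,
                 cylinder_diameter_mm = cylinder_diameter_mm,
                 disk_spacing_mm = disk_spacing_mm,
                 disk_radius_mm = disk_radius_mm, alpha = alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `scheme`, `endpoint_min`, `threshold_pct`,
#' `cylinder_diameter_mm`, `disk_spacing_mm`, `disk_radius_mm`, `alpha`,
#' `out_dir`, plus nested `segmentation:` and `acquisition:` blocks whose
#' entries override the corresponding parameter defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  acq <- do.call(acquisition_spec, y$acquisition %||% list())
  args <- y[setdiff(names(y), c("segmentation", "acquisition"))]
  do.call(pipeline_config, c(args, list(params = seg, acquisition = acq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, subject_id, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for subject '", subject_id, "': ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full analysis for one subject
#'
#' segment -> (peripheral shell ROI) and/or (thinning -> spline ->
#' pleural extrapolation -> distal cylinder / perpendicular disks) ->
#' time-activity curve -> decay correction -> %Cleared. Re-running with
#' the same inputs overwrites its outputs deterministically.
#'
#' @param ct chest CT as a `scalar_volume` or a NIfTI path.
#' @param pet dynamic PET as a `dynamic_series` or a NIfTI path.
#' @param seed_airway voxel index (i, j, k) inside the airway lumen.
#' @param seed_lung voxel index inside the lung parenchyma.
#' @param config a `pipeline_config`.
#' @param subject_id,group labels carried into the curves.
#' @return A list of class `subject_report`: `curves` (one
#'   `clearance_curve` per scheme), `rois` (label volumes), `disks`
#'   (per-frame disk profiles when requested).
#' @export
run_subject <- function(ct, pet, seed_airway, seed_lung,
                        config = pipeline_config(),
                        subject_id = "subject", group = NA_character_) {
  if (is.character(ct))
    ct <- stage("read_ct", subject_id, read_volume(ct))
  if (is.character(pet))
    pet <- stage("read_pet", subject_id, read_series(pet))
  p <- config$params
  airway <- stage("segment_airway", subject_id,
                  threshold_region_grow(ct, seed_airway, p$hu_airway))
  lung0 <- stage("segment_lung", subject_id,
                 threshold_region_grow(ct, seed_lung, p$hu_parenchyma))
  lung <- stage("close_lung", subject_id,
                close_mask(lung0, p$closing_radius_mm))
  schemes <- if (config$scheme == "all") c("shell", "cylinder", "disks")
             else config$scheme
  rois <- list()
  curves <- list()
  disks <- NULL
  cl <- NULL
  if ("shell" %in% schemes)
    rois$shell <- stage("hollow_shell", subject_id,
                        hollow_shell(lung, p$shell_thickness_mm))
  if (any(c("cylinder", "disks") %in% schemes)) {
    cp <- stage("skeletonize", subject_id, skeletonize(airway, seed_airway))
    cl <- stage("fit_spline", subject_id, fit_centerline_spline(cp))
    cl <- stage("extrapolate", subject_id, extrapolate_to_pleura(cl, lung))
  }
  if ("cylinder" %in% schemes)
    rois$cylinder <- stage("cylinder_roi", subject_id,
                           cylinder_roi(cl, config$cylinder_diameter_mm,
                                        lung))
  for (nm in names(rois)) {
    tac <- stage(paste0("tac_", nm), subject_id, extract_tac(pet, rois[[nm]]))
    tac <- decay_correct(tac, config$acquisition$half_life_min)
    curves[[nm]] <- percent_cleared(tac, subject_id = subject_id,
                                    group = group)
  }
  if ("disks" %in% schemes) {
    disks <- stage("sample_disks", subject_id, do.call(rbind, lapply(
      seq_len(n_frames(pet)), function(fr) {
        d <- sample_disks(cl, get_frame(pet, fr), config$disk_spacing_mm,
                          config$disk_radius_mm)
        d$frame_index <- fr
        d
      })))
  }
  rep <- structure(list(subject_id = subject_id, group = group,
                        curves = curves, rois = rois, disks = disks,
                        centerline = cl),
                   class = "subject_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(curves)) {
      cu <- curves[[nm]]
      write.csv(data.frame(subject_id = subject_id, group = group,
                           scheme = nm, time_min = cu$times_min,
                           pct_cleared = cu$pct_cleared),
                file.path(config$out_dir,
                          sprintf("%s_%s_curve.csv", subject_id, nm)),
                row.names = FALSE)
    }
    if (!is.null(disks))
      write.csv(disks, file.path(config$out_dir,
                                 sprintf("%s_disks.csv", subject_id)),
                row.names = FALSE)
  }
  rep
}

fit_to_list <- function(fit) {
  fit[c("f", "k_fast", "k_slow", "rss", "n_obs", "df")]
}

#' Group statistics over a set of clearance curves
#'
#' Shared (one triple for all curves) and per-group two-phase fits, the
#' extra sum-of-squares F test, responder contingency at the threshold,
#' Fisher's exact p (per group pair when more than two), and group
#' means +/- SE at the endpoint.
#'
#' @param curves list of `clearance_curve`s with group labels.
#' @param config a `pipeline_config`.
#' @return A list with elements `global_fit`, `group_fits`, `f_test`,
#'   `responders`, `fisher`, `summary`.
#' @export
cohort_stats <- function(curves, config = pipeline_config()) {
  grp <- vapply(curves, `[[`, character(1), "group")
  groups <- unique(grp)
  global_fit <- fit_two_phase(curves)
  group_fits <- lapply(groups, function(g) fit_two_phase(curves[grp == g]))
  names(group_fits) <- groups
  out <- list(groups = groups,
              global_fit = fit_to_list(global_fit),
              group_fits = lapply(group_fits, fit_to_list),
              summary = group_summary(curves, config$endpoint_min))
  if (length(groups) >= 2) {
    ft <- compare_fits_f_test(global_fit, group_fits)
    out$f_test <- c(unclass(ft),
                    significant = unname(ft$p < config$alpha))
    resp <- classify_responders(curves, config$threshold_pct,
                                config$endpoint_min)
    out$responders <- list(
      threshold_pct = resp$threshold_pct,
      endpoint_min = resp$endpoint_min,
      counts = as.data.frame.matrix(unclass(resp$table)))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    out$fisher <- lapply(pairs, function(pr) {
      tab <- unclass(resp$table)[pr, , drop = FALSE]
      list(groups = pr, p = fisher_exact(tab),
           significant = fisher_exact(tab) < config$alpha)
    })
  } else {
    out$note <- "single group: comparative statistics skipped"
  }
  out
}

#' Run a cohort end to end
#'
#' Accepts a `phantom_cohort` (from [make_cohort()]), a cohort directory
#' written by it, or a list of subject descriptors
#' (`list(ct=, pet=, seed_airway=, seed_lung=, subject_id=, group=)`).
#' Each subject is processed with [run_subject()]; curves are pooled per
#' scheme and passed to [cohort_stats()]. With `config$out_dir` set, a
#' deterministic JSON report and per-subject CSV curves are written.
#'
#' @param cohort cohort input (see Details).
#' @param config a `pipeline_config`.
#' @return A list of class `cohort_report`: per-scheme statistics plus
#'   the per-subject curves.
#' @export
run_cohort <- function(cohort, config = pipeline_config()) {
  subjects <- cohort_subjects(cohort)
  reports <- lapply(subjects, function(s)
    run_subject(s$ct, s$pet, s$seed_airway, s$seed_lung, config,
                subject_id = s$subject_id, group = s$group))
  schemes <- unique(unlist(lapply(reports, function(r) names(r$curves))))
  stats <- list()
  for (sc in schemes) {
    cu <- Filter(Negate(is.null),
                 lapply(reports, function(r) r$curves[[sc]]))
    stats[[sc]] <- cohort_stats(cu, config)
  }
  rep <- structure(list(schemes = stats,
                        subjects = lapply(reports, function(r)
                          list(subject_id = r$subject_id,
                               group = r$group)),
                        config = list(
                          scheme = config$scheme,
                          endpoint_min = config$endpoint_min,
                          threshold_pct = config$threshold_pct,
                          alpha = config$alpha),
                        curves = lapply(reports, `[[`, "curves")),
                   class = "cohort_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(rep[c("schemes", "subjects", "config")],
                         file.path(config$out_dir, "cohort_report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  rep
}

## normalise the three accepted cohort inputs into subject descriptors
cohort_subjects <- function(cohort) {
  if (inherits(cohort, "phantom_cohort")) {
    ph <- cohort$phantom
    sa <- phantom_airway_seed(ph)
    slg <- phantom_lung_seed(ph)
    return(lapply(seq_len(nrow(cohort$manifest)), function(i) {
      sid <- cohort$manifest$subject_id[i]
      list(ct = ph$ct, pet = cohort$dynamics[[sid]]$series,
           seed_airway = sa, seed_lung = slg, subject_id = sid,
           group = cohort$manifest$group[i])
    }))
  }
  if (is.character(cohort) && length(cohort) == 1 && dir.exists(cohort)) {
    man <- jsonlite::fromJSON(file.path(cohort, "manifest.json"))
    ct <- read_volume(file.path(cohort, "ct.nii.gz"))
    sa <- ct_airway_seed(ct)
    slg <- ct_lung_seed(ct)
    return(lapply(seq_len(nrow(man$subjects)), function(i) {
      sid <- man$subjects$subject_id[i]
      list(ct = ct,
           pet = file.path(cohort, sid, "pet_4d.nii.gz"),
           seed_airway = sa, seed_lung = slg, subject_id = sid,
           group = man$subjects$group[i])
    }))
  }
  if (is.list(cohort)) return(cohort)
  stop("unrecognised cohort input")
}

phantom_airway_seed <- function(ph) {
  idx <- ph$branch_voxels[[1]][1]
  arrayInd(idx, dim(vol_values(ph$lumen)))[1, ]
}

phantom_lung_seed <- function(ph) {
  cand <- as_mask(ph$lung) & !as_mask(ph$lumen)
  d <- edt_mm(cand, ph$lung$spacing)
  arrayInd(which.max(d), dim(cand))[1, ]
}

## seeds recovered from HU classes when only the CT file is available
ct_airway_seed <- function(ct) {
  v <- vol_values(ct)
  air <- v < -700
  # exclude ambient air touching the grid border, then take the deepest
  # remaining air voxel: robustly inside the root lumen
  lab <- array(label_components_cpp(as.vector(air), dim(v), 6L), dim(v))
  border <- unique(c(lab[c(1, dim(v)[1]), , ], lab[, c(1, dim(v)[2]), ],
                     lab[, , c(1, dim(v)[3])]))
  internal <- air & !(lab %in% setdiff(border, 0L))
  internal <- array(internal, dim(v))
  if (!any(internal)) stop("no internal airway lumen found in the CT")
  d <- edt_mm(internal, ct$spacing)
  arrayInd(which.max(d), dim(v))[1, ]
}

ct_lung_seed <- function(ct) {
  v <- vol_values(ct)
  par <- v > -700 & v < -200
  d <- edt_mm(par, ct$spacing)
  arrayInd(which.max(d), dim(v))[1, ]
}
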