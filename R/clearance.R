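## %Cleared kinetics: time-activity curves, decay correction, two-phase
## exponential association fits, and the group statistics (extra
## sum-of-squares F test, responder contingency, Fisher's exact test).

#' Extract a time-activity curve from a dynamic series
#'
#' Sums the per-voxel activity over the ROI for each frame; times are the
#' frame midpoints in minutes.
#'
#' @param series a `dynamic_series` of activity (uCi per voxel).
#' @param roi a binary `label_volume` on the same geometry.
#' @return An object of class `time_activity_curve` with fields
#'   `times_min`, `activity_uCi`, `decay_corrected`, `t_ref_min`.
#' @export
extract_tac <- function(series, roi) {
  stopifnot(inherits(series, "dynamic_series"))
  if (!same_geometry(series, roi))
    stop("ROI geometry does not match the series")
  m <- as_mask(roi)
  if (!any(m)) stop("empty ROI")
  nf <- n_frames(series)
  nvox <- prod(dim(m))
  v <- matrix(series$values, nrow = nvox, ncol = nf)
  act <- colSums(v[as.vector(m), , drop = FALSE])
  structure(list(times_min = frame_midpoints_min(series),
                 activity_uCi = act, decay_corrected = FALSE,
                 t_ref_min = NA_real_),
            class = "time_activity_curve")
}

#' Decay-correct a time-activity curve
#'
#' Rescales activity by `2^((t - t_ref) / half_life)` to remove physical
#' isotope decay (Ga-68: 68 min) from the clearance signal.
#'
#' @param tac a `time_activity_curve` (not already corrected).
#' @param half_life_min isotope half-life in minutes.
#' @param t_ref_min reference time; defaults to the first frame midpoint.
#' @return The corrected `time_activity_curve`.
#' @export
decay_correct <- function(tac, half_life_min = 68,
                          t_ref_min = tac$times_min[1]) {
  stopifnot(inherits(tac, "time_activity_curve"))
  if (isTRUE(tac$decay_corrected))
    stop("curve is already decay-corrected")
  tac$activity_uCi <- tac$activity_uCi *
    2^((tac$times_min - t_ref_min) / half_life_min)
  tac$decay_corrected <- TRUE
  tac$t_ref_min <- t_ref_min
  tac
}

#' Percent cleared relative to the post-delivery baseline
#'
#' `pct(t) = 100 * (A0 - A(t)) / A0` with `A0` the decay-corrected
#' activity of the first post-delivery frame; the curve starts at 0 and is
#' not clamped (negative values indicate net inflow).
#'
#' @param tac a decay-corrected `time_activity_curve`.
#' @param subject_id,group optional labels carried on the curve.
#' @return An object of class `clearance_curve` with fields `times_min`,
#'   `pct_cleared`, `baseline_uCi`, `subject_id`, `group`.
#' @export
percent_cleared <- function(tac, subject_id = NA_character_,
                            group = NA_character_) {
  stopifnot(inherits(tac, "time_activity_curve"))
  if (!isTRUE(tac$decay_corrected))
    stop("decay-correct the curve first (decay_correct())")
  a0 <- tac$activity_uCi[1]
  if (a0 == 0) stop("baseline activity is zero")
  structure(list(times_min = tac$times_min,
                 pct_cleared = 100 * (a0 - tac$activity_uCi) / a0,
                 baseline_uCi = a0, subject_id = subject_id, group = group),
            class = "clearance_curve")
}

#' Construct a clearance curve directly
#' @param times_min frame midpoint times (min), strictly increasing.
#' @param pct_cleared percent cleared per frame (first value 0).
#' @param subject_id,group optional labels.
#' @param baseline_uCi optional baseline activity.
#' @export
clearance_curve <- function(times_min, pct_cleared,
                            subject_id = NA_character_,
                            group = NA_character_, baseline_uCi = NA_real_) {
  stopifnot(length(times_min) == length(pct_cleared),
            !is.unsorted(times_min, strictly = TRUE))
  structure(list(times_min = as.numeric(times_min),
                 pct_cleared = as.numeric(pct_cleared),
                 baseline_uCi = baseline_uCi,
                 subject_id = subject_id, group = group),
            class = "clearance_curve")
}

#' Two-phase exponential association model
#'
#' `pct(t) = 100 * (1 - f * exp(-k_fast * t) - (1 - f) * exp(-k_slow * t))`:
#' starts at 0% and plateaus at 100% (all tracer eventually clears), with a
#' fast fraction `f` in [0, 1] and rate constants in 1/min,
#' `k_fast >= k_slow >= 0`.
#'
#' @param t times in minutes.
#' @param f fast fraction.
#' @param k_fast,k_slow rate constants (1/min).
#' @return Percent cleared at `t`.
#' @export
two_phase_pct <- function(t, f, k_fast, k_slow) {
  100 * (1 - f * exp(-k_fast * t) - (1 - f) * exp(-k_slow * t))
}

## residuals and analytic Jacobian for nls.lm
tp_resid <- function(par, t, y) {
  two_phase_pct(t, par[1], par[2], par[3]) - y
}
tp_jac <- function(par, t, y) {
  ef <- exp(-par[2] * t)
  es <- exp(-par[3] * t)
  cbind(100 * (es - ef),
        100 * par[1] * t * ef,
        100 * (1 - par[1]) * t * es)
}

#' Fit the two-phase exponential association model
#'
#' Least-squares fit of the 3-parameter model to one clearance curve or,
#' with `shared = TRUE` (the default for a list), a single parameter
#' triple fitted jointly to all curves by pooling every frame observation
#' (equal weight per observation). Deterministic multi-start
#' Levenberg-Marquardt over the grid f in {0.25, 0.5, 0.75}, k_fast in
#' {0.1, 0.5, 2}, k_slow in {0.005, 0.02, 0.1} 1/min; the best residual
#' sum of squares wins. Label switching is removed by enforcing
#' `k_fast >= k_slow` (swapping and mapping f -> 1 - f when needed).
#'
#' @param curves a `clearance_curve` or a list of them.
#' @param starts optional matrix of starting values (columns f, k_fast,
#'   k_slow) replacing the default grid.
#' @return An object of class `two_phase_fit`: `f`, `k_fast`, `k_slow`,
#'   `rss`, `n_obs`, `n_params` (= 3), `df` (= n_obs - 3), `fitted_from`.
#' @export
fit_two_phase <- function(curves, starts = NULL) {
  if (inherits(curves, "clearance_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "clearance_curve")))
  t <- unlist(lapply(curves, `[[`, "times_min"))
  y <- unlist(lapply(curves, `[[`, "pct_cleared"))
  if (length(t) < 4) stop("need at least 4 observations to fit 3 parameters")
  if (min(t) > 2)
    warning("curve does not start near 0 min; the model assumes 0% at t=0")
  if (is.null(starts))
    starts <- as.matrix(expand.grid(f = c(0.25, 0.5, 0.75),
                                    k_fast = c(0.1, 0.5, 2),
                                    k_slow = c(0.005, 0.02, 0.1)))
  best <- NULL
  diag_msgs <- character(0)
  for (r in seq_len(nrow(starts))) {
    # individual starts may hit maxiter without converging; that is
    # expected for a multi-start strategy, so keep them quiet
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[r, ], lower = c(0, 0, 0),
                           upper = c(1, Inf, Inf),
                           fn = tp_resid, jac = tp_jac, t = t, y = y,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    if (fit$info %in% c(0, 9)) {
      diag_msgs <- c(diag_msgs, fit$message)
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("two-phase fit failed to converge from any start:\n",
         paste(unique(diag_msgs), collapse = "\n"))
  p <- unname(best$par)
  if (p[3] > p[2]) p <- c(1 - p[1], p[3], p[2])
  structure(list(f = p[1], k_fast = p[2], k_slow = p[3],
                 rss = best$deviance, n_obs = length(t), n_params = 3L,
                 df = length(t) - 3L,
                 fitted_from = length(curves)),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat(sprintf(paste0("<two_phase_fit> f = %.3f, k_fast = %.4f /min, ",
                     "k_slow = %.4f /min\n  rss = %.4g on %d obs (df %d)\n"),
              x$f, x$k_fast, x$k_slow, x$rss, x$n_obs, x$df))
  invisible(x)
}

#' @export
predict.two_phase_fit <- function(object, t, ...) {
  two_phase_pct(t, object$f, object$k_fast, object$k_slow)
}

#' Extra sum-of-squares F test for nested curve fits
#'
#' Compares the pooled one-curve model (all groups share one parameter
#' triple) against per-group fits:
#' `F = ((RSS1 - RSS2) / (df1 - df2)) / (RSS2 / df2)`, with the p-value
#' from the upper tail of the F distribution. If the separate fits are
#' (numerically) worse than the global fit, F is clamped at 0 with a
#' warning.
#'
#' @param fit_global a `two_phase_fit` over all curves.
#' @param fits_separate list of per-group `two_phase_fit`s over the same
#'   observations.
#' @return An object of class `f_test_result`: `F`, `df_num`, `df_den`,
#'   `p`.
#' @export
compare_fits_f_test <- function(fit_global, fits_separate) {
  stopifnot(inherits(fit_global, "two_phase_fit"))
  if (inherits(fits_separate, "two_phase_fit"))
    fits_separate <- list(fits_separate)
  rss2 <- sum(vapply(fits_separate, `[[`, numeric(1), "rss"))
  n2 <- sum(vapply(fits_separate, `[[`, numeric(1), "n_obs"))
  if (n2 != fit_global$n_obs)
    stop("global and separate fits must cover the same observations (",
         fit_global$n_obs, " vs ", n2, ")")
  df1 <- fit_global$df
  df2 <- sum(vapply(fits_separate, `[[`, numeric(1), "df"))
  if (df1 <= df2) stop("separate model must use more parameters")
  if (rss2 > fit_global$rss) {
    warning("separate fits have higher RSS than the global fit; F set to 0")
    Fv <- 0
  } else if (fit_global$rss - rss2 <= 1e-10 * fit_global$rss) {
    # both models fit essentially perfectly (e.g. noiseless data):
    # the RSS reduction is numerical noise, not evidence
    Fv <- 0
  } else {
    Fv <- ((fit_global$rss - rss2) / (df1 - df2)) / (rss2 / df2)
  }
  structure(list(F = Fv, df_num = df1 - df2, df_den = df2,
                 p = pf(Fv, df1 - df2, df2, lower.tail = FALSE)),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("<f_test> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p))
  invisible(x)
}

## %Cleared at the endpoint by linear interpolation of frame midpoints
endpoint_pct <- function(curve, endpoint_min = 12) {
  if (max(curve$times_min) < endpoint_min) return(NA_real_)
  approx(curve$times_min, curve$pct_cleared, xout = endpoint_min)$y
}

#' Classify responders at a clearance threshold
#'
#' A subject responds when its %Cleared at the endpoint strictly exceeds
#' the threshold (default: more than 20% cleared at 12 min). Curves that
#' do not reach the endpoint are excluded with a warning.
#'
#' @param curves list of `clearance_curve`s with group labels.
#' @param threshold_pct responder threshold (strict `>`).
#' @param endpoint_min endpoint time in minutes.
#' @return An object of class `responder_table`: a `table` of group x
#'   responder counts plus the per-subject endpoint values.
#' @export
classify_responders <- function(curves, threshold_pct = 20,
                                endpoint_min = 12) {
  stopifnot(all(vapply(curves, inherits, logical(1), "clearance_curve")))
  ep <- vapply(curves, endpoint_pct, numeric(1), endpoint_min = endpoint_min)
  grp <- vapply(curves, `[[`, character(1), "group")
  short <- is.na(ep)
  if (any(short))
    warning(sum(short), " curve(s) shorter than ", endpoint_min,
            " min excluded")
  groups <- unique(grp)
  if (any(table(grp[!short]) == 0) || length(groups) > length(unique(grp[!short])))
    warning("some group(s) have no usable curves")
  tab <- table(factor(grp[!short], levels = groups),
               factor(ep[!short] > threshold_pct,
                      levels = c(TRUE, FALSE),
                      labels = c("responder", "non-responder")))
  structure(list(table = tab, endpoints = ep, group = grp,
                 threshold_pct = threshold_pct,
                 endpoint_min = endpoint_min),
            class = "responder_table")
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided exact p-value by enumeration: the sum of hypergeometric
#' probabilities of every table with the observed margins whose
#' probability does not exceed that of the observed table.
#'
#' @param x a 2x2 matrix of non-negative integer counts, or a
#'   `responder_table` with exactly two groups.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(x) {
  if (inherits(x, "responder_table")) x <- unclass(x$table)
  x <- as.matrix(x)
  if (!all(dim(x) == 2) || any(x < 0) || any(x != round(x)))
    stop("need a 2x2 table of non-negative integer counts")
  a <- x[1, 1]
  r1 <- sum(x[1, ]); r2 <- sum(x[2, ]); c1 <- sum(x[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(x[, 2]) == 0) {
    warning("a margin is zero: p = 1 by convention")
    return(1)
  }
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(k, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

#' Group means and standard errors of endpoint clearance
#'
#' @param curves list of `clearance_curve`s with group labels.
#' @param endpoint_min endpoint time in minutes.
#' @return data.frame with columns group, n, mean_pct, se_pct (SE is NA
#'   for n = 1).
#' @export
group_summary <- function(curves, endpoint_min = 12) {
  ep <- vapply(curves, endpoint_pct, numeric(1), endpoint_min = endpoint_min)
  grp <- vapply(curves, `[[`, character(1), "group")
  keep <- !is.na(ep)
  groups <- unique(grp[keep])
  if (!length(groups)) stop("no curves reach the endpoint")
  out <- do.call(rbind, lapply(groups, function(g) {
    e <- ep[keep & grp == g]
    data.frame(group = g, n = length(e), mean_pct = mean(e),
               se_pct = if (length(e) > 1) sd(e) / sqrt(length(e))
                        else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
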