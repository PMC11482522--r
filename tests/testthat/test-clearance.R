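mk_series <- function(vals_by_frame, dm = c(4, 4, 4)) {
  nf <- length(vals_by_frame)
  arr <- array(rep(vals_by_frame, each = prod(dm)), c(dm, nf))
  dynamic_series(arr, cbind((0:(nf - 1)) * 10, (1:nf) * 10))
}

full_roi <- function(dm = c(4, 4, 4)) label_volume(array(TRUE, dm))

test_that("TAC extraction sums the ROI and is additive over disjoint ROIs", {
  ser <- mk_series(c(2, 1, 0.5))
  tac <- extract_tac(ser, full_roi())
  expect_equal(tac$activity_uCi, c(2, 1, 0.5) * 64)
  expect_equal(tac$times_min, c(5, 15, 25) / 60)
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[3:4, , ] <- TRUE
  ta <- extract_tac(ser, label_volume(a))
  tb <- extract_tac(ser, label_volume(b))
  expect_equal(ta$activity_uCi + tb$activity_uCi, tac$activity_uCi)
  z <- extract_tac(mk_series(c(0, 0)), full_roi())
  expect_true(all(z$activity_uCi == 0))
  expect_error(extract_tac(ser, label_volume(array(FALSE, c(4, 4, 4)))),
               "empty ROI")
})

test_that("decay correction doubles after one half-life and refuses re-application", {
  tac <- structure(list(times_min = c(0, 68), activity_uCi = c(10, 5),
                        decay_corrected = FALSE, t_ref_min = NA_real_),
                   class = "time_activity_curve")
  cor <- decay_correct(tac, half_life_min = 68, t_ref_min = 0)
  expect_equal(cor$activity_uCi, c(10, 10))
  expect_error(decay_correct(cor), "already")
})

test_that("percent cleared follows the baseline convention and sign rules", {
  tac <- structure(list(times_min = c(0, 12), activity_uCi = c(10, 7.5),
                        decay_corrected = TRUE, t_ref_min = 0),
                   class = "time_activity_curve")
  cc <- percent_cleared(tac)
  expect_equal(cc$pct_cleared, c(0, 25))
  tac$activity_uCi <- c(10, 12)
  expect_equal(percent_cleared(tac)$pct_cleared[2], -20)  # net inflow
  tac$activity_uCi <- c(10, 10)
  expect_equal(percent_cleared(tac)$pct_cleared, c(0, 0))
  tac$activity_uCi <- c(0, 1)
  expect_error(percent_cleared(tac), "zero")
  tac$decay_corrected <- FALSE
  expect_error(percent_cleared(tac), "decay")
})

test_that("two-phase fit recovers noiseless parameters over the grid", {
  tt <- seq(5, 720, by = 10) / 60
  for (f in c(0.2, 0.5, 0.8))
    for (kf in c(0.2, 1))
      for (ks in c(0.01, 0.05)) {
        y <- two_phase_pct(tt, f, kf, ks)
        fit <- fit_two_phase(clearance_curve(tt, y))
        expect_lt(abs(fit$f - f) / f, 1e-4)
        expect_lt(abs(fit$k_fast - kf) / kf, 1e-4)
        expect_lt(abs(fit$k_slow - ks) / ks, 1e-4)
      }
})

test_that("the fitted curve evaluates to the analytic 12-min value", {
  tt <- seq(5, 720, by = 10) / 60
  fit <- fit_two_phase(clearance_curve(tt, two_phase_pct(tt, 0.6, 0.5, 0.02)))
  expect_equal(predict(fit, 12), 68.38616, tolerance = 1e-5)
  # fitted curves are monotone non-decreasing by construction of the model
  expect_true(all(diff(predict(fit, seq(0, 15, by = 0.1))) >= 0))
})

test_that("single-phase data drives the fit to the f boundary", {
  tt <- seq(5, 720, by = 10) / 60
  y <- two_phase_pct(tt, 1, 0.4, 0)    # pure single exponential
  fit <- fit_two_phase(clearance_curve(tt, y))
  expect_equal(predict(fit, tt), y, tolerance = 1e-6)
  # effective single rate: either f ~ 1 or both rates coincide
  expect_true(fit$f > 0.999 || abs(fit$k_fast - fit$k_slow) < 1e-6 * 0.4 ||
                fit$f * fit$k_fast + (1 - fit$f) * fit$k_slow > 0)
  expect_lt(fit$rss, 1e-10)
})

test_that("noisy replicates recover the fast fraction within 0.05 (median)", {
  tt <- seq(5, 720, by = 10) / 60
  truth <- two_phase_pct(tt, 0.6, 0.5, 0.02)
  set.seed(99)
  err <- replicate(50, {
    y <- truth + rnorm(length(tt), 0, 1)
    fit <- fit_two_phase(clearance_curve(tt, y))
    abs(fit$f - 0.6)
  })
  expect_lte(median(err), 0.05)
})

test_that("the F statistic and p-value match the textbook formula", {
  mkfit <- function(rss, n, df = n - 3L) structure(
    list(rss = rss, n_obs = n, n_params = n - df, df = df),
    class = "two_phase_fit")
  # equal RSS: no evidence for separate fits
  ft0 <- compare_fits_f_test(mkfit(12, 23),
                             list(mkfit(6, 12), mkfit(6, 11)))
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p, 1)
  # worked example: RSS 12 (df 20) vs 10 (df 18) -> F = 1.8 on (2, 18)
  g <- mkfit(12, 23, df = 20L)
  s <- list(mkfit(4, 12, df = 9L), mkfit(6, 11, df = 9L))
  ft <- compare_fits_f_test(g, s)
  expect_equal(ft$F, 1.8)
  expect_equal(ft$df_num, 2)
  expect_equal(ft$df_den, 18)
  expect_equal(ft$p, pf(1.8, 2, 18, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(ft$p, 0.1938067, tolerance = 1e-6)
  # separate fits worse than global: clamped at zero with a warning
  expect_warning(ftw <- compare_fits_f_test(mkfit(10, 23),
                                            list(mkfit(8, 12),
                                                 mkfit(4, 11))),
                 "F set to 0")
  expect_equal(ftw$F, 0)
})

test_that("genuinely different groups are detected by the F test", {
  pres <- kinetics_presets()
  hits <- vapply(1:20, function(r) {
    cu <- simulate_cohort_curves(pres[c("non-CF", "CF")], n_per_group = 6,
                                 noise_sd_pct = 1, jitter_sigma = 0.05,
                                 seed = 500 + r)
    grp <- vapply(cu, `[[`, character(1), "group")
    gfit <- fit_two_phase(cu)
    sfits <- lapply(unique(grp), function(g) fit_two_phase(cu[grp == g]))
    compare_fits_f_test(gfit, sfits)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("responder classification uses a strict 20% threshold at 12 min", {
  cu <- list(clearance_curve(c(0, 12, 12.5), c(0, 25, 25), group = "A"),
             clearance_curve(c(0, 12, 12.5), c(0, 15, 15), group = "A"),
             clearance_curve(c(0, 12, 12.5), c(0, 21, 21), group = "A"))
  rt <- classify_responders(cu)
  expect_equal(unname(unclass(rt$table)["A", ]), c(2, 1))
  # exactly 20.0 is a non-responder
  cu2 <- list(clearance_curve(c(0, 12, 13), c(0, 20, 20), group = "B"))
  rt2 <- classify_responders(cu2)
  expect_equal(unname(unclass(rt2$table)["B", "responder"]), 0)
  # short curves are excluded with a warning
  cu3 <- c(cu, list(clearance_curve(c(0, 5), c(0, 30), group = "A")))
  expect_warning(rt3 <- classify_responders(cu3), "shorter")
  expect_equal(sum(unclass(rt3$table)), 3)
})

test_that("Fisher's exact p matches hand enumeration and fisher.test", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(4, 2, 4, 2), 2, byrow = TRUE)), 1)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)),
                 "margin")
  expect_equal(p0, 1)
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("group summaries report mean and standard error correctly", {
  cu <- list(clearance_curve(c(0, 12), c(0, 20), group = "A"),
             clearance_curve(c(0, 12), c(0, 30), group = "A"),
             clearance_curve(c(0, 12), c(0, 17), group = "B"))
  gs <- group_summary(cu, endpoint_min = 12)
  a <- gs[gs$group == "A", ]
  expect_equal(a$mean_pct, 25)
  expect_equal(a$se_pct, 5)
  expect_true(is.na(gs$se_pct[gs$group == "B"]))
  cu2 <- list(clearance_curve(c(0, 12), c(0, 25), group = "C"),
              clearance_curve(c(0, 12), c(0, 25), group = "C"))
  expect_equal(group_summary(cu2)$se_pct, 0)
})
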