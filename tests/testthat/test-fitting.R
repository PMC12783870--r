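test_that("noiseless Gaussian curves are recovered to numerical precision", {
  truth <- observer_params(a_peak = 0.9, b_pss = 50, c_tbw = 300)
  fit <- fit_gaussian(expected_sj_curve(truth))
  expect_equal(fit$estimates$a_peak, 0.9, tolerance = 1e-6)
  expect_equal(fit$estimates$b_pss, 50, tolerance = 1e-6)
  expect_equal(fit$estimates$c_tbw, 300, tolerance = 1e-6)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("a flat curve yields a degenerate, excluded Gaussian fit", {
  flat <- tibble::tibble(condition_label = "x",
                         soa_ms = as.numeric(default_soa_grid()),
                         prop_sync = 0.5)
  fit <- fit_gaussian(flat)
  expect_false(isTRUE(fit$adj_r2 >= 0.5))
  tab <- fit_cohort(flat)
  kept <- apply_exclusion(tab)$fits
  expect_false(kept$kept_gauss)
})

test_that("Gaussian fitting needs at least four defined points", {
  short <- tibble::tibble(soa_ms = c(-100, 0, 100), prop_sync = c(0.5, 1, 0.5))
  expect_error(fit_gaussian(short), class = "avtbw_insufficient_data")
})

test_that("noiseless logistic curves are recovered with absolute reporting", {
  soas <- as.numeric(default_soa_grid())
  al_curve <- tibble::tibble(
    soa_ms = soas,
    prop_sync = logistic_sj(soas, b = 0.02, t = -200)
  )
  fit <- fit_logistic(al_curve, "AL")
  expect_equal(fit$estimates$b_slope_raw, 0.02, tolerance = 1e-6)
  expect_equal(fit$estimates$t_raw, -200, tolerance = 1e-6)
  expect_equal(fit$estimates$t_threshold, 200, tolerance = 1e-6)
  expect_true(fit$converged)

  # the model value at x = t is 0.5 for any slope
  expect_equal(logistic_sj(-200, 0.02, -200), 0.5)
  expect_equal(logistic_sj(137, 0.4, 137), 0.5)

  vl_curve <- tibble::tibble(
    soa_ms = soas,
    prop_sync = logistic_sj(soas, b = -0.015, t = 250)
  )
  vfit <- fit_logistic(vl_curve, "VL")
  expect_equal(vfit$estimates$b_slope_raw, -0.015, tolerance = 1e-6)
  expect_equal(vfit$estimates$b_slope, 0.015, tolerance = 1e-6)
})

test_that("slope sign bounds hold across simulated subjects", {
  for (seed in 1:25) {
    curve <- simulate_subject_curve(
      observer_params(a_peak = 0.95, b_pss = 20, c_tbw = 280,
                      unsure_rate = 0.05),
      seed = seed)
    al <- fit_logistic(curve, "AL")
    vl <- fit_logistic(curve, "VL")
    expect_gte(al$estimates$b_slope_raw, 0)
    expect_lte(al$estimates$b_slope_raw, 1)
    expect_lte(vl$estimates$b_slope_raw, 0)
    expect_gte(vl$estimates$b_slope_raw, -1)
    expect_gte(al$estimates$b_slope, 0)
    expect_gte(vl$estimates$b_slope, 0)
    g <- fit_gaussian(curve)
    expect_lte(g$estimates$a_peak, 1)
  }
})

test_that("AL and VL thresholds agree for symmetric observers", {
  diffs <- purrr::map_dbl(1:20, function(seed) {
    curve <- simulate_subject_curve(
      observer_params(a_peak = 1, b_pss = 0, c_tbw = 300, unsure_rate = 0),
      n_reps = 40, seed = seed)
    al <- fit_logistic(curve, "AL")
    vl <- fit_logistic(curve, "VL")
    al$estimates$t_threshold - vl$estimates$t_threshold
  })
  expect_lt(abs(mean(diffs)), 25)
})

test_that("adjusted R-squared matches its closed forms", {
  obs <- c(0.1, 0.4, 0.8, 0.9, 0.6, 0.3)
  expect_equal(adjusted_r2(obs, obs, 3), 1)

  # fitted = mean: R^2 = 0, so adj = -p / (n - p - 1) = -3/7 at n = 11
  obs11 <- p_sync(observer_params(a_peak = 1, b_pss = 0, c_tbw = 300),
                  default_soa_grid())
  expect_equal(adjusted_r2(obs11, rep(mean(obs11), 11), 3), -3 / 7)

  # frozen 5-point example (independent numpy arithmetic)
  expect_equal(
    adjusted_r2(c(0.1, 0.35, 0.5, 0.8, 0.9),
                c(0.15, 0.3, 0.55, 0.75, 0.95), 2),
    0.941588785047, tolerance = 1e-10)

  expect_true(is.nan(adjusted_r2(rep(0.5, 11), rep(0.5, 11), 3)))
  expect_error(adjusted_r2(c(0.1, 0.2), c(0.1, 0.2), 3),
               class = "avtbw_insufficient_data")
})

test_that("fits match a dense brute-force grid search on simulated subjects", {
  for (seed in 1:5) {
    curve <- simulate_subject_curve(
      observer_params(a_peak = 0.95, b_pss = 40, c_tbw = 320,
                      unsure_rate = 0.05),
      seed = seed)
    g <- fit_gaussian(curve)
    grid_sse <- oracle_gaussian_sse(curve$soa_ms, curve$prop_sync)
    expect_lte(g$objective, grid_sse + 1e-6 * max(1, grid_sse))

    al <- fit_logistic(curve, "AL")
    sel <- curve$soa_ms <= 0
    grid_al <- oracle_logistic_sse(curve$soa_ms[sel], curve$prop_sync[sel], "AL")
    expect_lte(al$objective, grid_al + 1e-6 * max(1, grid_al))
  }
})

test_that("cohort fitting never aborts and records failures as non-converged", {
  # one subject with almost all 'not sure' answers leaves too few points
  props <- tibble::tibble(
    subject_id = "S001", condition_label = "3Hz",
    soa_ms = as.numeric(default_soa_grid()),
    prop_sync = c(NA, NA, NA, NA, 0.8, 1, 0.9, NA, NA, NA, NA),
    n_valid = c(rep(0L, 4), 5L, 5L, 5L, rep(0L, 4))
  )
  tab <- fit_cohort(props)
  expect_equal(nrow(tab), 1)
  expect_false(tab$converged_gauss)
  kept <- apply_exclusion(tab)$fits
  expect_false(kept$kept_gauss)
  expect_false(kept$kept_logistic)
})

test_that("exclusion applies the strict adjusted R-squared rules per roster", {
  base <- tibble::tibble(
    subject_id = c("S1", "S2", "S3", "S4"),
    condition_label = "3Hz",
    a = 1, pss_ms = 0, tbw_ms = 300,
    adj_r2_gauss = c(0.49, 0.50, 0.80, NaN),
    converged_gauss = c(TRUE, TRUE, TRUE, TRUE),
    slope_al = 0.02, slope_vl = 0.02, thr_al_ms = 200, thr_vl_ms = 200,
    adj_r2_al = c(0.80, 0.30, 0.80, 0.80),
    adj_r2_vl = c(0.80, 0.29, 0.20, 0.80),
    converged_al = TRUE, converged_vl = TRUE
  )
  out <- apply_exclusion(base)
  # boundary: .49 excluded, exactly .50 kept
  expect_equal(out$fits$kept_gauss, c(FALSE, TRUE, TRUE, FALSE))
  # either side below .3 excludes; exactly .30 with .29 on the other side fails
  expect_equal(out$fits$kept_logistic, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$roster$kept_gauss, c(FALSE, TRUE, TRUE, FALSE))
  expect_length(out$log, 2 + 2)
  warnings <- capture_warnings(apply_exclusion(base, verbose = TRUE))
  expect_length(warnings, 4)
})

test_that("raising an exclusion threshold never keeps more subjects", {
  cohort <- simulate_cohort(build_design(exp1_conditions(), seed = 1),
                            n_observers = 8,
                            priors = cohort_priors(unsure_range = c(0.2, 0.45)),
                            seed = 2)
  tab <- fit_cohort(sj_proportions(cohort$responses))
  thresholds <- c(0, 0.25, 0.5, 0.75, 0.95)
  kept <- purrr::map_int(thresholds, function(th)
    sum(apply_exclusion(tab, gaussian_threshold = th)$fits$kept_gauss))
  expect_true(all(diff(kept) <= 0))
})

test_that("condition summaries report mean and SE over kept rows only", {
  tab <- tibble::tibble(
    subject_id = c("S1", "S2", "S3", "S4"),
    condition_label = "3Hz",
    a = 1, pss_ms = c(10, 20, 30, 999), tbw_ms = c(250, 300, 350, 9999),
    adj_r2_gauss = c(0.9, 0.9, 0.9, 0.1), converged_gauss = TRUE,
    slope_al = 0.02, slope_vl = 0.02, thr_al_ms = 200, thr_vl_ms = 200,
    adj_r2_al = 0.9, adj_r2_vl = 0.9, converged_al = TRUE, converged_vl = TRUE
  )
  res <- summarize_by_condition(apply_exclusion(tab)$fits)
  tbw <- dplyr::filter(res, measure == "tbw_ms")
  expect_equal(tbw$n, 3)
  expect_equal(tbw$mean, 300)
  expect_equal(tbw$se, sd(c(250, 300, 350)) / sqrt(3)) # = 50/sqrt(3)

  solo <- tab[1, ]
  expect_warning(summarize_by_condition(apply_exclusion(solo)$fits),
                 "single-subject")
  expect_error(summarize_by_condition(tab), class = "avtbw_invalid_argument")
})

test_that("tidy and glance return the documented tibbles", {
  fit <- fit_gaussian(expected_sj_curve(observer_params()))
  td <- tidy(fit)
  expect_equal(td$term, c("a_peak", "b_pss", "c_tbw"))
  gl <- glance(fit)
  expect_equal(gl$model, "gaussian")
  expect_true(gl$converged)
  lfit <- fit_logistic(expected_sj_curve(observer_params()), "VL")
  expect_equal(tidy(lfit)$term,
               c("b_slope_raw", "b_slope", "t_raw", "t_threshold"))
})
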