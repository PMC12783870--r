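#' Psychometric model functions
#'
#' `gaussian_sj()` is the simultaneity-judgement model
#' \deqn{y = a \exp(-((x - b)/c)^2):} `a` is the peak simultaneity
#' proportion (bounded above at 1), `b` the point of subjective
#' simultaneity (PSS, ms), and `c` the curve width, reported as the
#' temporal binding window (TBW, ms). Note the exponent carries no factor
#' of 2, so `c` is the SOA offset at which the curve falls to `a/e`, not a
#' standard deviation in the conventional sense; it is reported as the TBW
#' exactly as estimated.
#'
#' `logistic_sj()` is the side-split model
#' \deqn{y = 1 / (1 + e^{b (t - x)}):} `b` is the slope (steepness per ms)
#' and `t` the inflection point (the SOA at which y = 0.5). On the
#' auditory-leading (AL) side `b` is bounded to \[0, 1\]; on the
#' visual-leading (VL) side to \[-1, 0\].
#'
#' @param x SOA(s) in ms.
#' @param a,b,c,t Model parameters.
#' @return Model proportions.
#' @export
gaussian_sj <- function(x, a, b, c) a * exp(-((x - b) / c)^2)

#' @rdname gaussian_sj
#' @export
logistic_sj <- function(x, b, t) 1 / (1 + exp(b * (t - x)))

#' Adjusted R-squared of a psychometric fit
#'
#' The Wherry form `1 - (1 - R^2) (n - 1) / (n - p - 1)`, with
#' `R^2 = 1 - SSres / SStot` and `n` the number of defined points. Used as
#' the subject-exclusion criterion (Gaussian fits below .5 and logistic
#' fits below .3 are excluded). When the observed proportions have zero
#' variance, R-squared is undefined and `NaN` is returned; downstream
#' exclusion treats any non-finite value as "not kept".
#'
#' @param observed,fitted Numeric vectors of observed and model
#'   proportions (same length; pairs with `NA` observations are dropped).
#' @param n_params Number of free model parameters (3 Gaussian,
#'   2 logistic).
#' @return Scalar adjusted R-squared (possibly `NaN`).
#' @export
adjusted_r2 <- function(observed, fitted, n_params) {
  ok <- !is.na(observed) & !is.na(fitted)
  observed <- observed[ok]
  fitted <- fitted[ok]
  n <- length(observed)
  if (n < n_params + 2) {
    abort("need at least n_params + 2 points for adjusted R-squared.",
          class = "avtbw_insufficient_data")
  }
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- 1 - ss_res / ss_tot      # NaN when ss_tot == 0
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

# coarse objective scans supplying extra multi-start points: the residual
# surface is multimodal on noisy curves, so the local optimizer is
# launched from the best few coarse basins, not just one
coarse_gaussian_start <- function(x, y, k = 6) {
  grid <- expand.grid(a = c(seq(0.1, 0.9, length.out = 9), 0.99),
                      b = seq(-600, 600, by = 50),
                      c = seq(25, 1000, by = 25))
  X <- matrix(x, nrow(grid), length(x), byrow = TRUE)
  Y <- matrix(y, nrow(grid), length(y), byrow = TRUE)
  sse <- rowSums((grid$a * exp(-((X - grid$b) / grid$c)^2) - Y)^2)
  # greedily pick low-SSE starts that sit in distinct regions of the box,
  # so one broad basin cannot absorb every start
  ord <- order(sse)
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= k) break
    distinct <- all(abs(grid$b[i] - grid$b[picked]) >= 100 |
                      abs(grid$c[i] - grid$c[picked]) >= 75 |
                      abs(grid$a[i] - grid$a[picked]) >= 0.2)
    if (length(picked) == 0 || distinct) picked <- c(picked, i)
  }
  lapply(picked, function(i) c(a = grid$a[i], b = grid$b[i], c = grid$c[i]))
}

coarse_logistic_start <- function(x, y, sgn, k = 8) {
  grid <- expand.grid(
    b = sgn * c(0.002, 0.005, 0.01, 0.02, 0.03, 0.05, 0.08, 0.12, 0.2, 0.35, 0.6, 1),
    t = seq(-800, 800, by = 25))
  X <- matrix(x, nrow(grid), length(x), byrow = TRUE)
  Y <- matrix(y, nrow(grid), length(y), byrow = TRUE)
  sse <- rowSums((1 / (1 + exp(grid$b * (grid$t - X))) - Y)^2)
  ord <- order(sse)
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= k) break
    distinct <- all(abs(grid$t[i] - grid$t[picked]) >= 100 |
                      abs(log10(abs(grid$b[i]) + 1e-4) -
                            log10(abs(grid$b[picked]) + 1e-4)) >= 0.5)
    if (length(picked) == 0 || distinct) picked <- c(picked, i)
  }
  lapply(picked, function(i) c(b = grid$b[i], t = grid$t[i]))
}

# shared bounded Levenberg-Marquardt driver with multi-start
lm_multistart <- function(residual_fn, starts, lower, upper) {
  fits <- list()
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper, fn = residual_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    fits[[length(fits) + 1]] <- list(par = fit$par, dev = fit$deviance,
                                     ok = fit$info %in% 1:3)
  }
  if (length(fits) == 0) return(NULL)
  devs <- vapply(fits, `[[`, 0, "dev")
  best <- fits[[which.min(devs)]]  # lowest objective wins; ties by order
  if (!best$ok) {
    # prefer a cleanly converged run when it is essentially as good
    near <- which(vapply(fits, `[[`, TRUE, "ok") &
                    devs <= best$dev * (1 + 1e-6) + 1e-12)
    if (length(near) > 0) best <- fits[[near[1]]]
  }
  best
}

#' Fit the Gaussian simultaneity model to one SJ curve
#'
#' Bounded least squares of `y = a exp(-((x - b)/c)^2)` on the per-SOA
#' simultaneity proportions of one (subject, condition). The `a` parameter
#' is bounded to \[0.01, 1\] (the upper bound at 1 because y is a
#' proportion; the small lower bound avoids degenerate flat fits), `b` is
#' free, and `c >= 1` ms. Three Levenberg-Marquardt starts are tried
#' (`a0` = max proportion, `b0` = SOA at the max, `c0` in 150/300/450 ms)
#' and the best objective wins. Cells with `NA` proportions are treated as
#' missing points.
#'
#' @param curve A proportions tibble for a single curve, with columns
#'   `soa_ms` and `prop_sync` (see [sj_proportions()]).
#' @param c_starts Initial width values (ms) for the multi-start.
#' @return An `sj_fit` object: estimates (`a_peak`, `b_pss`, `c_tbw`),
#'   `r2`, `adj_r2`, `converged`, `objective` (residual sum of squares),
#'   the model points, and the input data. Use [tidy()][generics::tidy]
#'   or [glance()][generics::glance] to extract tibbles.
#' @examples
#' curve <- expected_sj_curve(observer_params(a_peak = 0.9, b_pss = 50,
#'                                            c_tbw = 300))
#' fit <- fit_gaussian(curve)
#' glance(fit)
#' @export
fit_gaussian <- function(curve, c_starts = c(150, 300, 450)) {
  pts <- curve[!is.na(curve$prop_sync), c("soa_ms", "prop_sync")]
  if (nrow(pts) < 4) {
    abort("Gaussian fit needs at least 4 defined SOA points.",
          class = "avtbw_insufficient_data")
  }
  x <- pts$soa_ms
  y <- pts$prop_sync
  resid_fn <- function(p) y - gaussian_sj(x, p[1], p[2], p[3])
  # keep a0 strictly inside the box: a start pinned at a bound stays there
  a0 <- min(max(max(y), 0.01), 0.995)
  b0 <- x[which.max(y)]
  starts <- lapply(c_starts, function(c0) c(a = a0, b = b0, c = c0))
  starts <- c(starts, coarse_gaussian_start(x, y))
  best <- lm_multistart(resid_fn, starts,
                        lower = c(0.01, -Inf, 1), upper = c(1, Inf, Inf))
  finish_fit(best, x, y, model = "gaussian", n_params = 3, side = NA_character_)
}

#' Fit the side-split logistic model to one SJ curve
#'
#' Bounded least squares of `y = 1 / (1 + exp(b (t - x)))` on one side of
#' the SOA axis: `side = "AL"` uses SOAs from -500 to 0 ms and bounds the
#' slope to \[0, 1\]; `side = "VL"` uses 0 to +500 ms with slope in
#' \[-1, 0\]. SOA 0 belongs to both subsets. The inflection `t` is
#' unconstrained. Reported `b_slope` and `t_threshold` are absolute
#' values, since AL thresholds and VL slopes are negative by construction.
#'
#' @param curve A proportions tibble for a single curve (full SOA range;
#'   the side subset is taken internally).
#' @param side `"AL"` (auditory-leading) or `"VL"` (visual-leading).
#' @param b_starts Magnitudes of the slope starts (sign set by `side`).
#' @return An `sj_fit` object with estimates `b_slope_raw`, `b_slope`,
#'   `t_raw`, `t_threshold`, plus `r2`, `adj_r2`, `converged`,
#'   `objective`.
#' @export
fit_logistic <- function(curve, side = c("AL", "VL"),
                         b_starts = c(0.01, 0.05)) {
  side <- match.arg(side)
  sel <- if (side == "AL") curve$soa_ms <= 0 else curve$soa_ms >= 0
  pts <- curve[sel & !is.na(curve$prop_sync), c("soa_ms", "prop_sync")]
  if (nrow(pts) < 3) {
    abort(sprintf("logistic fit (%s) needs at least 3 defined SOA points.", side),
          class = "avtbw_insufficient_data")
  }
  x <- pts$soa_ms
  y <- pts$prop_sync
  resid_fn <- function(p) y - logistic_sj(x, p[1], p[2])
  sgn <- if (side == "AL") 1 else -1
  lower <- if (side == "AL") c(0, -Inf) else c(-1, -Inf)
  upper <- if (side == "AL") c(1, Inf) else c(0, Inf)
  half <- (max(y) + min(y)) / 2
  t0 <- x[which.min(abs(y - half))]
  starts <- lapply(b_starts, function(b0) c(b = sgn * b0, t = t0))
  starts <- c(starts, coarse_logistic_start(x, y, sgn))
  best <- lm_multistart(resid_fn, starts, lower = lower, upper = upper)
  finish_fit(best, x, y, model = "logistic", n_params = 2, side = side)
}

finish_fit <- function(best, x, y, model, n_params, side) {
  if (is.null(best)) {
    est <- rep(NA_real_, if (model == "gaussian") 3 else 2)
    fitted <- rep(NA_real_, length(x))
    converged <- FALSE
    objective <- NA_real_
  } else {
    est <- unname(best$par)
    fitted <- if (model == "gaussian") {
      gaussian_sj(x, est[1], est[2], est[3])
    } else {
      logistic_sj(x, est[1], est[2])
    }
    converged <- best$ok
    objective <- best$dev
  }
  r2 <- adj <- NA_real_
  if (!anyNA(fitted)) {
    ss_tot <- sum((y - mean(y))^2)
    r2 <- 1 - objective / ss_tot
    # a side subset can be too short for the penalty term (n <= p + 1)
    adj <- tryCatch(adjusted_r2(y, fitted, n_params), error = function(e) NA_real_)
  }
  estimates <- if (model == "gaussian") {
    list(a_peak = est[1], b_pss = est[2], c_tbw = est[3])
  } else {
    list(b_slope_raw = est[1], b_slope = abs(est[1]),
         t_raw = est[2], t_threshold = abs(est[2]))
  }
  structure(
    list(model = model, side = side, estimates = estimates,
         r2 = r2, adj_r2 = adj, converged = converged,
         objective = objective, n_points = length(x),
         data = tibble::tibble(soa_ms = x, prop_sync = y, fitted = fitted)),
    class = "sj_fit"
  )
}

#' @export
print.sj_fit <- function(x, ...) {
  lbl <- if (x$model == "gaussian") "Gaussian SJ fit" else
    sprintf("Logistic SJ fit (%s)", x$side)
  cat(lbl, "\n")
  est <- unlist(x$estimates)
  cat("  ", paste(sprintf("%s = %.4g", names(est), est), collapse = ", "), "\n")
  cat(sprintf("  adj R^2 = %.3f, converged = %s, n = %d\n",
              x$adj_r2, x$converged, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x An `sj_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: a one-row model summary (`model`, `side`, `r2`,
#'   `adj_r2`, `converged`, `objective`, `n_points`).
#' @export
tidy.sj_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(unlist(x$estimates)))
}

#' @rdname tidy.sj_fit
#' @export
glance.sj_fit <- function(x, ...) {
  tibble::tibble(model = x$model, side = x$side, r2 = x$r2,
                 adj_r2 = x$adj_r2, converged = x$converged,
                 objective = x$objective, n_points = x$n_points)
}

#' Fit all psychometric models for a cohort of SJ curves
#'
#' For every (subject, condition) curve, fits the Gaussian model on the
#' full SOA range and the logistic model separately on the AL and VL
#' sides, and assembles the flat parameter table consumed by exclusion and
#' summary steps. Fit failures (insufficient data, non-convergence from
#' every start) are recorded as non-converged rows, never raised, so a
#' cohort run cannot abort on one bad subject.
#'
#' @param proportions A proportions tibble from [sj_proportions()]
#'   (columns `condition_label`, `soa_ms`, `prop_sync`, optionally
#'   `subject_id`).
#' @return A tibble with one row per (subject, condition):
#'   `a`, `pss_ms`, `tbw_ms`, `adj_r2_gauss`, `converged_gauss`,
#'   `slope_al`, `slope_vl`, `thr_al_ms`, `thr_vl_ms`, `adj_r2_al`,
#'   `adj_r2_vl`, `converged_al`, `converged_vl`.
#' @examples
#' cohort <- simulate_cohort(build_design(exp1_conditions(), seed = 1),
#'                           n_observers = 2, seed = 5)
#' fit_cohort(sj_proportions(cohort$responses))
#' @export
fit_cohort <- function(proportions) {
  grp <- intersect(c("subject_id", "condition_label"), names(proportions))
  proportions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(curve, key) fit_curve_row(curve)) |>
    dplyr::ungroup()
}

fit_curve_row <- function(curve) {
  safe <- function(fn) tryCatch(fn, error = function(e) NULL)
  g <- safe(fit_gaussian(curve))
  al <- safe(fit_logistic(curve, "AL"))
  vl <- safe(fit_logistic(curve, "VL"))
  na_fit <- list(estimates = list(), adj_r2 = NA_real_, converged = FALSE)
  gv <- function(f, field) if (is.null(f)) NA_real_ else f$estimates[[field]]
  fv <- function(f, field) if (is.null(f)) na_fit[[field]] else f[[field]]
  tibble::tibble(
    a = gv(g, "a_peak"), pss_ms = gv(g, "b_pss"), tbw_ms = gv(g, "c_tbw"),
    adj_r2_gauss = fv(g, "adj_r2"), converged_gauss = isTRUE(fv(g, "converged")),
    slope_al = gv(al, "b_slope"), slope_vl = gv(vl, "b_slope"),
    thr_al_ms = gv(al, "t_threshold"), thr_vl_ms = gv(vl, "t_threshold"),
    adj_r2_al = fv(al, "adj_r2"), adj_r2_vl = fv(vl, "adj_r2"),
    converged_al = isTRUE(fv(al, "converged")),
    converged_vl = isTRUE(fv(vl, "converged"))
  )
}

#' Apply the adjusted-R-squared exclusion rules
#'
#' Flags each fitted (subject, condition) row for the two analysis
#' rosters. A row is kept for Gaussian-derived analyses (TBW, PSS) when
#' the Gaussian fit converged and its adjusted R-squared is not below
#' `gaussian_threshold`; the inequality is strict, so a fit at exactly the
#' threshold is kept. A row is kept for logistic-derived analyses (slopes,
#' thresholds) when both the AL and VL fits converged and neither adjusted
#' R-squared falls below `logistic_threshold` — a failure on either side
#' excludes the row. Non-finite adjusted R-squared values (degenerate
#' curves) are never kept. A subject-level roster (a subject is kept only
#' if all its condition rows are) and a plain-text exclusion log accompany
#' the table.
#'
#' @param fits A parameter table from [fit_cohort()].
#' @param gaussian_threshold Exclusion threshold for Gaussian fits
#'   (default 0.5).
#' @param logistic_threshold Exclusion threshold for logistic fits
#'   (default 0.3).
#' @param verbose Emit one warning per exclusion (used by the pipeline so
#'   drops are never silent); the log is returned either way.
#' @return A list: `fits` (the table with `kept_gauss`, `kept_logistic`
#'   columns), `roster` (per-subject keep flags, when `subject_id` is
#'   present), and `log` (character vector, one exclusion reason per
#'   line).
#' @export
apply_exclusion <- function(fits, gaussian_threshold = 0.5,
                            logistic_threshold = 0.3, verbose = FALSE) {
  keep_ok <- function(adj, thr, conv) conv & is.finite(adj) & !(adj < thr)
  out <- fits |>
    dplyr::mutate(
      kept_gauss = keep_ok(.data$adj_r2_gauss, gaussian_threshold,
                           .data$converged_gauss),
      kept_logistic = keep_ok(.data$adj_r2_al, logistic_threshold,
                              .data$converged_al) &
        keep_ok(.data$adj_r2_vl, logistic_threshold, .data$converged_vl)
    )
  has_subj <- "subject_id" %in% names(out)
  roster <- if (has_subj) {
    out |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(kept_gauss = all(.data$kept_gauss),
                       kept_logistic = all(.data$kept_logistic),
                       .groups = "drop")
  } else NULL
  log_lines <- character()
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    who <- paste(c(if (has_subj) row$subject_id, row$condition_label),
                 collapse = "/")
    if (!row$kept_gauss) {
      log_lines <- c(log_lines, sprintf(
        "%s: excluded from Gaussian analyses (adj R2 = %.3f, converged = %s)",
        who, row$adj_r2_gauss, row$converged_gauss))
    }
    if (!row$kept_logistic) {
      log_lines <- c(log_lines, sprintf(
        "%s: excluded from logistic analyses (adj R2 AL = %.3f, VL = %.3f)",
        who, row$adj_r2_al, row$adj_r2_vl))
    }
  }
  if (verbose) for (line in log_lines) warn(line, class = "avtbw_exclusion")
  list(fits = out, roster = roster, log = log_lines)
}

#' Per-condition summary of kept psychometric parameters
#'
#' Means and standard errors of the Gaussian-derived (TBW, PSS, peak) and
#' logistic-derived (AL/VL slope and threshold) measures across kept
#' subjects, per condition. Gaussian measures average over rows kept by
#' the Gaussian roster; logistic measures over rows kept by the logistic
#' roster. Conditions with no kept rows are omitted with a warning; a
#' single-subject condition yields an `NA` standard error with a warning.
#'
#' @param fits The flagged table from [apply_exclusion()]`$fits` (needs
#'   `kept_gauss` / `kept_logistic`; pass a [fit_cohort()] table through
#'   [apply_exclusion()] first).
#' @return A tidy tibble: `condition_label`, `measure`, `n`, `mean`, `se`.
#' @export
summarize_by_condition <- function(fits) {
  if (!all(c("kept_gauss", "kept_logistic") %in% names(fits))) {
    abort("`fits` must carry kept flags; run apply_exclusion() first.",
          class = "avtbw_invalid_argument")
  }
  gauss_measures <- c(tbw_ms = "tbw_ms", pss_ms = "pss_ms", a_peak = "a")
  logi_measures <- c(slope_al = "slope_al", slope_vl = "slope_vl",
                     thr_al_ms = "thr_al_ms", thr_vl_ms = "thr_vl_ms")
  one <- function(tab, col, nm) {
    tab |>
      dplyr::group_by(.data$condition_label) |>
      dplyr::summarise(measure = nm, n = dplyr::n(),
                       mean = mean(.data[[col]]),
                       se = sd(.data[[col]]) / sqrt(dplyr::n()),
                       .groups = "drop")
  }
  res <- purrr::list_rbind(c(
    purrr::map(names(gauss_measures), function(nm)
      one(dplyr::filter(fits, .data$kept_gauss), gauss_measures[[nm]], nm)),
    purrr::map(names(logi_measures), function(nm)
      one(dplyr::filter(fits, .data$kept_logistic), logi_measures[[nm]], nm))
  ))
  empty <- setdiff(unique(fits$condition_label), unique(res$condition_label))
  if (length(empty) > 0) {
    warn(paste("conditions with no kept fits omitted:",
               paste(empty, collapse = ", ")))
  }
  if (any(res$n == 1)) {
    warn("single-subject condition(s): standard error undefined.")
  }
  dplyr::arrange(res, .data$condition_label, .data$measure)
}
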