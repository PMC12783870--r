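#' Ground-truth parameters of a simulated observer
#'
#' A simulated observer judges simultaneity according to a Gaussian
#' simultaneity curve: at SOA x, the probability of a "synchronous"
#' judgement is
#' \deqn{p(x) = a \exp(-((x - b)/c)^2),}
#' where `a_peak` is the peak synchrony probability, `b_pss` the point of
#' subjective simultaneity (ms) and `c_tbw` the curve width, i.e. the
#' temporal binding window (ms). Ratings on the 5-point scale arise in two
#' stages: with probability `unsure_rate` the trial is a "not sure" (rating
#' 3) lapse; otherwise a Bernoulli draw on p(x) decides synchronous vs
#' asynchronous, and `confident_split` decides whether the extreme rating
#' (1 or 5) or the moderate one (2 or 4) is reported. The split does not
#' affect any analysis, since ratings 1/2 and 4/5 are collapsed on recoding.
#'
#' @param a_peak Peak synchrony probability, in (0, 1].
#' @param b_pss Point of subjective simultaneity in ms.
#' @param c_tbw Gaussian width (TBW) in ms, > 0.
#' @param unsure_rate Probability of a rating-3 lapse, in \[0, 0.5).
#' @param confident_split Probability of the extreme rating, in \[0, 1\].
#' @return An `observer_params` object (a validated named list).
#' @export
observer_params <- function(a_peak = 0.95, b_pss = 50, c_tbw = 300,
                            unsure_rate = 0.05, confident_split = 0.75) {
  if (!(a_peak > 0 && a_peak <= 1)) {
    abort("`a_peak` must be in (0, 1].", class = "avtbw_invalid_argument")
  }
  if (!(c_tbw > 0)) abort("`c_tbw` must be > 0.", class = "avtbw_invalid_argument")
  if (!(unsure_rate >= 0 && unsure_rate < 0.5)) {
    abort("`unsure_rate` must be in [0, 0.5).", class = "avtbw_invalid_argument")
  }
  if (!(confident_split >= 0 && confident_split <= 1)) {
    abort("`confident_split` must be in [0, 1].", class = "avtbw_invalid_argument")
  }
  structure(
    list(a_peak = a_peak, b_pss = b_pss, c_tbw = c_tbw,
         unsure_rate = unsure_rate, confident_split = confident_split),
    class = "observer_params"
  )
}

#' Probability of a synchronous judgement at a given SOA
#'
#' Evaluates the ground-truth Gaussian simultaneity curve
#' `a * exp(-((soa - b)/c)^2)`.
#'
#' @param params An [observer_params()] object.
#' @param soa_ms SOA(s) in ms; vectorized.
#' @return Probabilities in `[0, a_peak]`.
#' @export
p_sync <- function(params, soa_ms) {
  params$a_peak * exp(-((soa_ms - params$b_pss) / params$c_tbw)^2)
}

#' Simulate 5-point ratings for a trial list
#'
#' Draws one rating per trial from the two-stage mechanism described in
#' [observer_params()]: lapse to "not sure" (3), else a Bernoulli draw on
#' the Gaussian synchrony probability, then a confidence split between the
#' extreme and moderate rating.
#'
#' @param design A trial tibble from [build_design()] (needs `soa_ms`).
#' @param params An [observer_params()] object, or a data frame with a
#'   `condition_label` column and columns `a_peak`, `b_pss`, `c_tbw`,
#'   `unsure_rate`, `confident_split` giving per-condition parameters.
#' @param seed Integer seed.
#' @return `design` with a `rating` column (integers 1-5) appended.
#' @export
simulate_responses <- function(design, params, seed = 1) {
  if (nrow(design) == 0) abort("`design` is empty.", class = "avtbw_invalid_argument")
  if (inherits(params, "observer_params")) {
    par_tab <- tibble::as_tibble(unclass(params))
    p_row <- par_tab[rep(1L, nrow(design)), ]
  } else {
    stopifnot(is.data.frame(params), "condition_label" %in% names(params))
    idx <- match(design$condition_label, params$condition_label)
    if (anyNA(idx)) {
      abort("`params` lacks rows for some conditions in `design`.",
            class = "avtbw_invalid_argument")
    }
    p_row <- params[idx, c("a_peak", "b_pss", "c_tbw", "unsure_rate",
                           "confident_split")]
  }
  n <- nrow(design)
  p <- p_row$a_peak * exp(-((design$soa_ms - p_row$b_pss) / p_row$c_tbw)^2)
  rating <- local_rng(seed)(function() {
    u_lapse <- runif(n)
    u_sync <- runif(n)
    u_conf <- runif(n)
    sync <- u_sync < p
    r <- ifelse(sync,
                ifelse(u_conf < p_row$confident_split, 1L, 2L),
                ifelse(u_conf < p_row$confident_split, 5L, 4L))
    r[u_lapse < p_row$unsure_rate] <- 3L
    r
  })
  out <- design
  out$rating <- as.integer(rating)
  out
}

#' Priors for cohort simulation
#'
#' Ranges and distributions from which each simulated observer's
#' parameters are drawn: `a ~ U(a_range)`, `b ~ N(b_mean, b_sd)` (a small
#' visual-leading bias by default, matching the tendency for maximal
#' simultaneity near +100 ms), `c ~ U(c_range)` spanning typical group-mean
#' TBWs, `unsure ~ U(unsure_range)`. Optionally, `c_by_condition` gives a
#' named list of per-condition `c` ranges (named by `condition_label`),
#' letting ground-truth TBW differ across conditions within a subject.
#'
#' @param a_range,c_range,unsure_range Two-element ranges.
#' @param b_mean,b_sd Normal prior for the PSS, in ms.
#' @param confident_split Fixed confidence split for all observers.
#' @param c_by_condition Optional named list of two-element `c` ranges.
#' @return A `cohort_priors` list.
#' @export
cohort_priors <- function(a_range = c(0.85, 1), b_mean = 50, b_sd = 40,
                          c_range = c(200, 500), unsure_range = c(0, 0.15),
                          confident_split = 0.75, c_by_condition = NULL) {
  check_range <- function(r, what, positive = FALSE) {
    if (length(r) != 2 || r[1] > r[2] || (positive && r[1] <= 0)) {
      abort(sprintf("degenerate prior for %s.", what),
            class = "avtbw_invalid_argument")
    }
  }
  check_range(a_range, "a_peak")
  check_range(c_range, "c_tbw", positive = TRUE)
  check_range(unsure_range, "unsure_rate")
  if (!is.null(c_by_condition)) {
    purrr::iwalk(c_by_condition, function(r, nm)
      check_range(r, paste0("c_tbw[", nm, "]"), positive = TRUE))
  }
  structure(
    list(a_range = a_range, b_mean = b_mean, b_sd = b_sd, c_range = c_range,
         unsure_range = unsure_range, confident_split = confident_split,
         c_by_condition = c_by_condition),
    class = "cohort_priors"
  )
}

#' Simulate a cohort of observers
#'
#' Draws each observer's ground-truth parameters from the priors, then
#' simulates that observer's ratings over the trial design. Each observer
#' gets a private random stream derived from `(seed, subject index)`, so
#' subsets of the cohort reproduce identically under partial re-runs.
#' Ground truth is always returned next to the responses; no simulated
#' dataset exists without its generating parameters.
#'
#' @param design A trial tibble from [build_design()].
#' @param n_observers Number of observers to simulate.
#' @param priors A [cohort_priors()] object.
#' @param seed Master integer seed.
#' @return A list with `responses` (trial tibble with `subject_id` and
#'   `rating`) and `truth` (one row per subject x condition with the
#'   generating parameters).
#' @examples
#' cohort <- simulate_cohort(build_design(exp1_conditions(), seed = 1),
#'                           n_observers = 3, seed = 42)
#' dplyr::count(cohort$responses, subject_id)
#' @export
simulate_cohort <- function(design, n_observers, priors = cohort_priors(),
                            seed = 1) {
  if (n_observers < 1) abort("`n_observers` must be >= 1.",
                             class = "avtbw_invalid_argument")
  stopifnot(inherits(priors, "cohort_priors"))
  conds <- unique(design$condition_label)
  sub_seeds <- local_rng(seed)(function()
    sample.int(.Machine$integer.max - 1L, n_observers + 1L))
  par_seed <- sub_seeds[n_observers + 1L]
  truth <- local_rng(par_seed)(function() {
    purrr::map_dfr(seq_len(n_observers), function(i) {
      a <- runif(1, priors$a_range[1], priors$a_range[2])
      b <- rnorm(1, priors$b_mean, priors$b_sd)
      u <- runif(1, priors$unsure_range[1], priors$unsure_range[2])
      cs <- purrr::map_dbl(conds, function(cl) {
        rng <- priors$c_by_condition[[cl]] %||% priors$c_range
        runif(1, rng[1], rng[2])
      })
      tibble::tibble(
        subject_id = sprintf("S%03d", i), condition_label = conds,
        a_peak = a, b_pss = b, c_tbw = cs, unsure_rate = u,
        confident_split = priors$confident_split
      )
    })
  })
  responses <- purrr::map_dfr(seq_len(n_observers), function(i) {
    sid <- sprintf("S%03d", i)
    par_tab <- dplyr::filter(truth, .data$subject_id == sid)
    resp <- simulate_responses(design, par_tab, seed = sub_seeds[i])
    dplyr::mutate(resp, subject_id = sid, .before = 1)
  })
  list(responses = responses, truth = truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
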