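#' Recode 5-point ratings into sync / async / excluded
#'
#' Ratings 1 ("certainly synchronous") and 2 ("probably synchronous") code
#' as `sync`; 4 ("probably asynchronous") and 5 ("certainly asynchronous")
#' as `async`; 3 ("not sure") carries no information about perceived
#' synchrony and is `excluded` from the analysis.
#'
#' @param rating Integer vector of ratings in 1-5.
#' @return A factor with levels `sync`, `async`, `excluded`.
#' @examples
#' recode_rating(c(1, 2, 3, 4, 5))
#' @export
recode_rating <- function(rating) {
  bad <- which(!(rating %in% 1:5) | is.na(rating))
  if (length(bad) > 0) {
    abort(sprintf("invalid rating %s at position %d (must be 1-5).",
                  as.character(rating[bad[1]]), bad[1]),
          class = "avtbw_invalid_data")
  }
  factor(
    dplyr::case_when(rating %in% c(1, 2) ~ "sync",
                     rating %in% c(4, 5) ~ "async",
                     TRUE ~ "excluded"),
    levels = c("sync", "async", "excluded")
  )
}

#' Per-cell simultaneity proportions
#'
#' Recodes ratings and computes, for every (subject, condition, SOA) cell,
#' the proportion of synchronous judgements among valid (non-"not sure")
#' trials: `#sync / (#sync + #async)`. Cells whose every trial was "not
#' sure" have zero valid trials and an `NA` proportion; downstream fitting
#' treats them as missing points rather than imputing them.
#'
#' @param responses A response tibble with columns `condition_label`,
#'   `soa_ms`, `rating`, and optionally `subject_id` (grouping is by
#'   whichever of `subject_id`, `condition_label` are present).
#' @return A tibble with one row per cell: grouping columns, `soa_ms`
#'   (ascending within group), `prop_sync`, `n_valid`, `n_trials`.
#' @examples
#' design <- build_design(exp1_conditions(), seed = 1)
#' resp <- simulate_responses(design, observer_params(), seed = 2)
#' sj_proportions(resp)
#' @export
sj_proportions <- function(responses) {
  need <- c("condition_label", "soa_ms", "rating")
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0) {
    abort(paste0("`responses` lacks column(s): ", paste(miss, collapse = ", ")),
          class = "avtbw_invalid_data")
  }
  grp <- intersect(c("subject_id", "condition_label"), names(responses))
  responses |>
    dplyr::mutate(judgement = recode_rating(.data$rating)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "soa_ms")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_sync = sum(.data$judgement == "sync"),
      n_valid = sum(.data$judgement != "excluded"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prop_sync = ifelse(.data$n_valid > 0, .data$n_sync / .data$n_valid, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(grp), "soa_ms", "prop_sync", "n_valid",
                  "n_trials") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "soa_ms"))))
}

#' Analytic (noise-free) simultaneity curve for an observer
#'
#' Evaluates the ground-truth Gaussian synchrony probability on an SOA
#' grid, returning the same cell schema as [sj_proportions()]. Useful as a
#' noiseless reference cohort.
#'
#' @param params An [observer_params()] object.
#' @param soas SOA grid in ms.
#' @param condition_label Label attached to the curve.
#' @return A proportions tibble with `prop_sync = p_sync(soa)`.
#' @export
expected_sj_curve <- function(params, soas = default_soa_grid(),
                              condition_label = "cond") {
  tibble::tibble(
    condition_label = condition_label,
    soa_ms = as.numeric(sort(soas)),
    prop_sync = p_sync(params, sort(soas)),
    n_valid = NA_integer_,
    n_trials = NA_integer_
  )
}
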