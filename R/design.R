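#' The default SOA grid
#'
#' The eleven stimulus onset asynchronies used throughout:
#' -500 to +500 ms in 100 ms steps. Negative SOAs are auditory-leading
#' (AL), positive visual-leading (VL).
#'
#' @return An ascending integer vector of 11 SOAs in milliseconds.
#' @export
default_soa_grid <- function() {
  seq(-500L, 500L, by = 100L)
}

#' Condition tables for the three experiment presets
#'
#' A condition is one row of a tibble with columns `condition_label`,
#' `mode` (`"rhythmic"` or `"speech-like"`), `freq_hz`, `stream_mode`
#' (`"fixed_duration"` or `"fixed_pulses"`) and `stream_value` (seconds or
#' pulse count). `exp1_conditions()`: 3 s streams at 1/2/3 Hz.
#' `exp2_conditions()`: 3-pulse streams at 1/2/3 Hz (3/1.5/1 s).
#' `exp3_conditions()`: a 3 Hz rhythmic stream and a 3 Hz speech-like
#' stream.
#'
#' @return A condition tibble.
#' @export
exp1_conditions <- function() {
  tibble::tibble(
    condition_label = c("1Hz", "2Hz", "3Hz"),
    mode = "rhythmic",
    freq_hz = c(1, 2, 3),
    stream_mode = "fixed_duration",
    stream_value = 3
  )
}

#' @rdname exp1_conditions
#' @export
exp2_conditions <- function() {
  tibble::tibble(
    condition_label = c("1Hz", "2Hz", "3Hz"),
    mode = "rhythmic",
    freq_hz = c(1, 2, 3),
    stream_mode = "fixed_pulses",
    stream_value = 3
  )
}

#' @rdname exp1_conditions
#' @export
exp3_conditions <- function() {
  tibble::tibble(
    condition_label = c("rhythmic", "speech-like"),
    mode = c("rhythmic", "speech-like"),
    freq_hz = 3,
    stream_mode = "fixed_duration",
    stream_value = 3
  )
}

#' Build a randomized trial list
#'
#' Fully crosses SOAs, conditions and repetitions, then applies a single
#' seeded uniform shuffle. Every (condition, SOA) cell appears exactly
#' `n_reps` times. The canonical 11 SOAs x 3 conditions x 5 repetitions
#' design yields 165 trials.
#'
#' @param conditions A condition tibble (see [exp1_conditions()]); any
#'   tibble with a `condition_label` column works.
#' @param soas Vector of unique SOAs in ms (default [default_soa_grid()]).
#' @param n_reps Repetitions per (condition, SOA) cell.
#' @param seed Integer seed for the shuffle.
#' @return A trial tibble with `trial_index` (0-based, randomized order),
#'   the condition columns, `soa_ms` and `repetition` (1-based).
#' @examples
#' design <- build_design(exp1_conditions(), seed = 7)
#' nrow(design) # 165
#' @export
build_design <- function(conditions, soas = default_soa_grid(), n_reps = 5,
                         seed = 1) {
  if (length(soas) == 0 || anyDuplicated(soas)) {
    abort("`soas` must be non-empty and unique.", class = "avtbw_invalid_design")
  }
  if (!is.data.frame(conditions) || !"condition_label" %in% names(conditions) ||
      nrow(conditions) == 0) {
    abort("`conditions` must be a data frame with a `condition_label` column.",
          class = "avtbw_invalid_design")
  }
  if (n_reps < 1) abort("`n_reps` must be >= 1.", class = "avtbw_invalid_design")
  grid <- tidyr::crossing(
    conditions,
    soa_ms = as.numeric(soas),
    repetition = seq_len(n_reps)
  )
  ord <- local_rng(seed)(function() sample.int(nrow(grid)))
  out <- grid[ord, , drop = FALSE]
  out$trial_index <- seq_len(nrow(out)) - 1L
  dplyr::relocate(out, "trial_index")
}
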