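#' Plot an envelope
#'
#' @param object An envelope tibble.
#' @param ... Unused.
#' @return A ggplot of amplitude over time.
#' @export
autoplot.av_envelope <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude",
                  title = env_label(object)) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Observed per-SOA simultaneity proportions with the fitted Gaussian or
#' logistic curve drawn over a fine SOA grid.
#'
#' @param object An `sj_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sj_fit <- function(object, ...) {
  xg <- seq(min(object$data$soa_ms), max(object$data$soa_ms), length.out = 200)
  est <- object$estimates
  yg <- if (object$model == "gaussian") {
    gaussian_sj(xg, est$a_peak, est$b_pss, est$c_tbw)
  } else {
    logistic_sj(xg, est$b_slope_raw, est$t_raw)
  }
  lbl <- if (object$model == "gaussian") "Gaussian fit" else
    sprintf("Logistic fit (%s)", object$side)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$soa_ms, y = .data$prop_sync)) +
    ggplot2::geom_line(data = tibble::tibble(soa_ms = xg, prop_sync = yg),
                       colour = "#b2182b") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "SOA (ms)", y = "Proportion synchronous",
                  title = lbl,
                  subtitle = sprintf("adj R² = %.3f", object$adj_r2)) +
    ggplot2::theme_minimal()
}

#' Plot simultaneity-judgement curves by condition
#'
#' @param proportions A tibble from [sj_proportions()].
#' @return A ggplot, faceted by subject when `subject_id` is present.
#' @export
plot_sj_curves <- function(proportions) {
  p <- ggplot2::ggplot(proportions,
                       ggplot2::aes(x = .data$soa_ms, y = .data$prop_sync,
                                    colour = .data$condition_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "SOA (ms)", y = "Proportion synchronous",
                  colour = "Condition") +
    ggplot2::theme_minimal()
  if ("subject_id" %in% names(proportions)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$subject_id))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
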