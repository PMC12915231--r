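# ggplot2 displays for the main result types.

#' Plot a peri-event trial-average trace pair
#'
#' Mean dF/F0 with a shaded s.e.m. ribbon for each region, aligned to
#' behavior onset (vertical line at t = 0).
#'
#' @param trials tibble with columns `time_rel_s`, `dff`, `region`, `trial`
#'   (long format, one row per sample).
#' @return a ggplot object.
#' @export
plot_peri_event <- function(trials) {
  need <- c("time_rel_s", "dff", "region", "trial")
  miss <- setdiff(need, names(trials))
  if (length(miss)) abort(paste("missing column(s):", paste(miss, collapse = ", ")))
  avg <- trials %>%
    group_by(.data$region, .data$time_rel_s) %>%
    summarise(m = mean(.data$dff),
              sem = sd(.data$dff) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$time_rel_s, .data$m,
                                    color = .data$region, fill = .data$region)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$sem,
                                      ymax = .data$m + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from behavior onset (s)",
                  y = expression(Delta * F / F[0]),
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.xcorr_tbl <- function(object, ...) {
  peak <- object[which.max(abs(object$r)), ]
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_s, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = peak, color = "red") +
    ggplot2::labs(x = "lag (s): positive = region B precedes A",
                  y = "cross-correlation r") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-correlation series
#'
#' @param sliding tibble from [sliding_correlation()].
#' @return a ggplot object.
#' @export
plot_sliding_correlation <- function(sliding) {
  ggplot2::ggplot(sliding, ggplot2::aes(.data$window_center_s, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "window center (s)", y = "sliding-window r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motion_glm <- function(object, ...) {
  d <- tibble(regressor = object$regressor, dff = object$dff)
  ggplot2::ggplot(d, ggplot2::aes(.data$regressor, .data$dff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$beta,
                         color = "red") +
    ggplot2::labs(x = "convolved motion energy",
                  y = expression(Delta * F / F[0]),
                  subtitle = sprintf("beta = %.3f, R2 = %.3f",
                                     object$beta, object$r_squared)) +
    ggplot2::theme_minimal()
}
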