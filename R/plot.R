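#' Plot a detection result
#'
#' Two stacked panels: the segmented AP acceleration with the detected
#' heel-strike events, and the coefficient signal with the selected
#' sliding-window starts.
#'
#' @param object A `"step_detection"` from [detect_steps_lowback()] or
#'   [detect_strides_heel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.step_detection <- function(object, ...) {
  m <- object$match
  tl <- object$tl$tl
  dat <- dplyr::bind_rows(
    tibble::tibble(panel = "coefficient signal", sample = m$window_start,
                   value = m$coefficient),
    tibble::tibble(panel = "sd / correlation", sample = m$window_start,
                   value = m$sd_difference, series = "SD difference"),
    tibble::tibble(panel = "sd / correlation", sample = m$window_start,
                   value = m$correlation, series = "correlation")
  )
  dat$series[is.na(dat$series)] <- "coefficient"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$events$event, linetype = "dashed",
                        colour = "grey40", linewidth = 0.25) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "sample (raw-trace coordinates)", y = NULL,
                  colour = NULL,
                  title = sprintf("%s: %d events, TL = %d samples",
                                  object$placement, nrow(object$events), tl)) +
    ggplot2::theme_minimal()
}

#' Plot a between-method comparison
#'
#' Paired durations of the two methods per pair index, with stride-fallback
#' pairs marked, plus the per-pair absolute difference.
#'
#' @param object A `"method_comparison"` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.method_comparison <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, cols = c("a_ms", "b_ms"),
                              names_to = "method", values_to = "duration_ms")
  long$method <- ifelse(long$method == "a_ms", object$methods[1],
                        object$methods[2])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$duration_ms,
                                     colour = .data$method,
                                     shape = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "pair", y = "duration (ms)",
                  title = sprintf("%s vs %s: mean |diff| %.1f ms (%.1f%%)",
                                  object$methods[1], object$methods[2],
                                  object$mean_abs_diff_ms,
                                  object$pct_of_mean_step)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic gait trial
#'
#' The three AP acceleration traces with the ground-truth heel strikes and
#' the default segmentation window.
#'
#' @param object A `"gait_trial"` from [generate_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_trial <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(object$lowback, trace = "lower back"),
    dplyr::mutate(object$heel_left, trace = "left heel"),
    dplyr::mutate(object$heel_right, trace = "right heel")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$accel)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::geom_vline(xintercept = object$truth$event, colour = "red",
                        linewidth = 0.25, alpha = 0.6) +
    ggplot2::annotate("rect", xmin = object$window$start,
                      xmax = object$window$end, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "blue") +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "sample", y = "AP acceleration",
                  title = "synthetic gait trial (red: ground-truth heel strikes)") +
    ggplot2::theme_minimal()
}
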