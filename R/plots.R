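#' Plot a nocturnal tachogram
#'
#' Instantaneous HR (gray) with the smoothed trend (black); detected
#' arousals and episodes can be shaded to reproduce the classic
#' flat / sparse-CVHR / dense-CVHR phenotype panels.
#'
#' @param object A `cvhr_tachogram`.
#' @param arousals,episodes Optional tibbles from [detect_arousals()] /
#'   [assemble_episodes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cvhr_tachogram
#' @export
autoplot.cvhr_tachogram <- function(object, arousals = NULL,
                                    episodes = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 60)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_bpm),
                       color = "grey70", linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_smooth_bpm),
                       color = "black", linewidth = 0.4) +
    ggplot2::labs(x = "time (min)", y = "heart rate (bpm)",
                  title = attr(object, "patient_id")) +
    ggplot2::theme_minimal()
  if (!is.null(episodes) && nrow(episodes)) {
    p <- p + ggplot2::geom_rect(
      data = episodes, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s / 60, xmax = .data$end_s / 60,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.15)
  }
  if (!is.null(arousals) && nrow(arousals)) {
    p <- p + ggplot2::geom_rect(
      data = arousals, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s / 60, xmax = .data$end_s / 60,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.2)
  }
  p
}

#' Plot a Kaplan-Meier curve
#'
#' Step survival curve with the log-log Greenwood confidence band.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- tidy(object)
  t <- c(0, d$time)
  step <- function(y) utils::head(rep(c(1, y), each = 2), -1)
  d0 <- tibble::tibble(
    time = rep(t, each = 2)[-1],
    survival = step(d$survival),
    ci_low = step(d$ci_low),
    ci_high = step(d$ci_high)
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Plot the CVHR-threshold mortality scan
#'
#' 5-year Kaplan-Meier mortality of the subgroup with CVHR duration at or
#' below each threshold, with its confidence band.
#'
#' @param object A `cvhr_scan` from [threshold_mortality_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cvhr_scan
#' @export
autoplot.cvhr_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold_min,
                                       y = .data$mortality_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low_pct,
                                      ymax = .data$ci_high_pct),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "CVHR threshold (min)",
                  y = "5-year mortality of subgroup ≤ threshold (%)") +
    ggplot2::theme_minimal()
}

#' Violin panel of risk markers by flat-tachogram status
#'
#' @param patients Per-patient table from [run_cohort()]'s `patients`
#'   element (needs `is_flat` and the metric columns).
#' @param metrics Metric columns to show.
#' @return A ggplot.
#' @export
plot_risk_panel <- function(patients,
                            metrics = c("sdnn_ms", "sdann_ms", "rmssd_ms",
                                        "hrv_ti", "tp_ms2", "vlf_ms2",
                                        "lf_ms2", "hf_ms2", "dc_ms")) {
  metrics <- intersect(metrics, names(patients))
  d <- patients |>
    dplyr::filter(!is.na(.data$is_flat)) |>
    dplyr::select(dplyr::all_of(c("is_flat", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(
    x = ifelse(.data$is_flat, "flat", "non-flat"), y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
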