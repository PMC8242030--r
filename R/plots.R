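#' Plot per-community reporter traces
#'
#' Thin lines per community with the ensemble mean overlaid, the standard
#' view of synchronized reporter dynamics.
#'
#' @param data A tidy trace tibble; for multi-channel input the `channel`
#'   to display is selected first.
#' @param channel Channel to plot when a `channel` column is present.
#' @return A ggplot object.
#' @export
plot_traces <- function(data, channel = "dEGFP") {
  data <- as_tibble(data)
  if ("channel" %in% names(data)) {
    data <- data %>% filter(.data$channel == !!channel)
  }
  mean_tr <- data %>%
    group_by(.data$time_min) %>%
    summarise(value = mean(.data$value))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$time_min / 60, y = .data$value, group = .data$community
  )) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(
      data = mean_tr, ggplot2::aes(group = NULL),
      color = "black", linewidth = 0.8
    ) +
    ggplot2::labs(x = "time (h)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' Heatmap of rescaled traces across communities
#'
#' @param data A single-channel trace tibble, typically the 0-1 rescaled
#'   pipeline stage.
#' @return A ggplot tile heatmap (communities x time).
#' @export
plot_trace_heatmap <- function(data) {
  data <- check_series(data)
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$time_min / 60, y = .data$community, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "dEGFP (0-1)") +
    ggplot2::labs(x = "time (h)", y = "community") +
    ggplot2::theme_minimal()
}

#' Heatmap of a noise x period synchronization sweep
#'
#' @param sweep Output of [sweep_noise_rate()].
#' @return A ggplot tile heatmap of the synchronization index.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = factor(.data$period_h), y = factor(.data$noise_sigma),
    fill = .data$sync_index
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "sync index") +
    ggplot2::labs(x = "stimulation period (h)", y = "noise sigma") +
    ggplot2::theme_minimal()
}

#' Plot ensemble rhythmicity summaries of a pipeline report
#'
#' @param object A `sync_report` from [run_pipeline()].
#' @param which `"psd"` for the power spectrum (dominant period marked) or
#'   `"acf"` for the cumulative autocorrelation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sync_report <- function(object, which = c("psd", "acf"), ...) {
  which <- match.arg(which)
  if (which == "acf") {
    ggplot2::ggplot(object$acf, ggplot2::aes(.data$lag_h, .data$acf)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "lag (h)", y = "cumulative ACF") +
      ggplot2::theme_minimal()
  } else {
    psd <- object$psd %>% filter(.data$freq_per_h > 0)
    ggplot2::ggplot(psd, ggplot2::aes(.data$freq_per_h, .data$power)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(
        xintercept = 1 / object$dominant_period_h,
        linetype = 2, color = "firebrick"
      ) +
      ggplot2::labs(x = "frequency (1/h)", y = "power") +
      ggplot2::theme_minimal()
  }
}
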