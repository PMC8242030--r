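#' Growth-normalize the reporter signal
#'
#' Corrects the reporter for growth and acquisition variation using the
#' constitutive channel: `degfp / (degfp + mcherry)`. Where both channels
#' are zero (dead or empty region of interest) the result is defined as 0.
#'
#' @param degfp,mcherry Non-negative numeric vectors of equal length.
#' @return A numeric vector in \[0, 1\].
#' @examples
#' normalize_growth(c(0, 1, 2), c(1, 1, 0))
#' @export
normalize_growth <- function(degfp, mcherry) {
  if (length(degfp) != length(mcherry)) {
    abort("`degfp` and `mcherry` must have the same length.",
      class = "rhythmsync_error")
  }
  if (any(degfp < 0) || any(mcherry < 0)) {
    abort("Fluorescence values must be non-negative.",
      class = "rhythmsync_error")
  }
  tot <- degfp + mcherry
  out <- ifelse(tot == 0, 0, degfp / tot)
  out
}

#' Remove the least-squares linear trend
#'
#' Subtracts the ordinary least-squares straight line, leaving a zero-mean,
#' zero-slope residual. This is the detrending applied to raw traces before
#' smoothing and spectral analysis.
#'
#' @param x Numeric vector with at least 3 samples.
#' @return The detrended vector.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3) {
    abort("Need at least 3 samples to detrend.", class = "rhythmsync_error")
  }
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  x - mean(x) - slope * tc
}

# Savitzky-Golay least-squares projection matrix rows for a window of
# length `window` and polynomial order `polyorder`. Row r gives the
# weights producing the fitted value at in-window position r.
savgol_matrix <- function(window, polyorder) {
  z <- seq_len(window) - (window + 1) / 2
  A <- outer(z, 0:polyorder, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with the standard central
#' convolution kernel; any polynomial of degree at most `polyorder` passes
#' through unchanged. Near the record edges the leading/trailing window's
#' polynomial fit is evaluated at the edge positions (no wrap-around), so
#' bursts at the boundaries are not aliased.
#'
#' @param x Numeric vector, `length(x) >= window`.
#' @param window Odd filter length (the classic trace setting is 15
#'   samples, i.e. 150 min at 10-min sampling).
#' @param polyorder Polynomial order, `< window`.
#' @return The smoothed vector.
#' @export
smooth_savgol <- function(x, window = 15, polyorder = 3) {
  n <- length(x)
  if (window %% 2 != 1) {
    abort("`window` must be odd.", class = "rhythmsync_error")
  }
  if (polyorder >= window) {
    abort("`polyorder` must be smaller than `window`.",
      class = "rhythmsync_error")
  }
  if (n < window) {
    abort("Trace shorter than the filter window.", class = "rhythmsync_error")
  }
  S <- savgol_matrix(window, polyorder)
  half <- (window - 1) / 2
  mid_kernel <- S[half + 1, ]
  out <- numeric(n)
  for (i in (half + 1):(n - half)) {
    out[i] <- sum(mid_kernel * x[(i - half):(i + half)])
  }
  head_fit <- S %*% x[1:window]
  tail_fit <- S %*% x[(n - window + 1):n]
  out[1:half] <- head_fit[1:half]
  out[(n - half + 1):n] <- tail_fit[(window - half + 1):window]
  out
}

#' Rescale a trace to the unit interval
#'
#' Affine map `(x - min) / (max - min)` used to build 0-1 heatmaps across
#' communities. Constant traces have no meaningful range and are rejected.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return A vector in \[0, 1\] with minimum 0 and maximum 1.
#' @export
rescale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    abort("Cannot rescale a constant trace.", class = "rhythmsync_error")
  }
  (x - r[1]) / (r[2] - r[1])
}

# -- tidy wrappers over per-community traces ---------------------------------

# Validate a long single-channel trace table (time_min, community, value).
check_series <- function(data) {
  data <- as_tibble(data)
  need <- c("time_min", "community", "value")
  if (!all(need %in% names(data))) {
    abort("Expected columns time_min, community, value.",
      class = "rhythmsync_error")
  }
  data
}

#' Growth-normalize a tidy trace set
#'
#' Pairs the `dEGFP` and `mCherry` channels of every community and applies
#' [normalize_growth()], returning a single-channel table ready for
#' [detrend_traces()] and [smooth_traces()].
#'
#' @param data A tidy trace tibble with columns `time_min`, `community`,
#'   `channel`, `value` (as produced by [simulate_ensemble()] or
#'   [read_traces()]). Rows with other channels (e.g. `"toxin"`) are
#'   dropped.
#' @return A tibble with columns `time_min`, `community`, `value`.
#' @export
normalize_traces <- function(data) {
  data <- as_tibble(data)
  need <- c("time_min", "community", "channel", "value")
  if (!all(need %in% names(data))) {
    abort("Expected columns time_min, community, channel, value.",
      class = "rhythmsync_error")
  }
  wide <- data %>%
    filter(.data$channel %in% c("dEGFP", "mCherry")) %>%
    tidyr::pivot_wider(
      id_cols = c("time_min", "community"),
      names_from = "channel", values_from = "value"
    )
  if (!all(c("dEGFP", "mCherry") %in% names(wide)) ||
      anyNA(wide$dEGFP) || anyNA(wide$mCherry)) {
    abort("Every community needs both dEGFP and mCherry channels.",
      class = "rhythmsync_error")
  }
  wide %>%
    mutate(value = normalize_growth(.data$dEGFP, .data$mCherry)) %>%
    select("time_min", "community", "value") %>%
    arrange(.data$community, .data$time_min)
}

#' @rdname detrend_linear
#' @param data A single-channel trace tibble (`time_min`, `community`,
#'   `value`).
#' @export
detrend_traces <- function(data) {
  check_series(data) %>%
    group_by(.data$community) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    mutate(value = detrend_linear(.data$value)) %>%
    ungroup()
}

#' @rdname smooth_savgol
#' @param data A single-channel trace tibble (`time_min`, `community`,
#'   `value`).
#' @export
smooth_traces <- function(data, window = 15, polyorder = 3) {
  check_series(data) %>%
    group_by(.data$community) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    mutate(value = smooth_savgol(.data$value, window, polyorder)) %>%
    ungroup()
}

#' @rdname rescale01
#' @param data A single-channel trace tibble (`time_min`, `community`,
#'   `value`).
#' @export
rescale_traces <- function(data) {
  check_series(data) %>%
    group_by(.data$community) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    mutate(value = rescale01(.data$value)) %>%
    ungroup()
}
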