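#' Cumulative (ensemble) autocorrelation function
#'
#' Sample autocorrelation of every community's detrended trace (biased
#' normalization, so `acf(0) = 1` and the sequence is positive
#' semidefinite), averaged across communities. A synchronized ensemble
#' shows a pronounced maximum at the stimulation period; period doubling
#' moves the first dominant maximum to twice the period.
#'
#' @param data A single-channel trace tibble (`time_min`, `community`,
#'   `value`), detrended.
#' @param max_lag_h Maximal lag in hours; defaults to half the record and
#'   must be shorter than the record.
#' @return A tibble with columns `lag_h`, `acf`.
#' @export
cumulative_acf <- function(data, max_lag_h = NULL) {
  data <- check_series(data)
  dt_min <- series_dt(data)
  n_time <- length(unique(data$time_min))
  duration_h <- n_time * dt_min / 60
  if (is.null(max_lag_h)) max_lag_h <- duration_h / 2
  if (max_lag_h >= duration_h) {
    abort("`max_lag_h` must be shorter than the record.",
      class = "rhythmsync_error")
  }
  lag_max <- floor(max_lag_h * 60 / dt_min)
  acfs <- data %>%
    group_by(.data$community) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    reframe(
      lag_h = (0:lag_max) * dt_min / 60,
      acf = as.numeric(acf(.data$value, lag.max = lag_max,
        plot = FALSE, demean = TRUE)$acf)
    )
  acfs %>%
    group_by(.data$lag_h) %>%
    summarise(acf = mean(.data$acf)) %>%
    arrange(.data$lag_h)
}

#' Power spectrum of the ensemble-mean trace
#'
#' Periodogram of the across-community mean trace, computed with an
#' unwindowed FFT after zero-padding to four times the record length.
#' Power is one-sided and normalized so that its sum equals the variance
#' of the (demeaned) input. The dominant period is the inverse of the
#' frequency with maximal power, excluding the zero bin.
#'
#' @param data A single-channel trace tibble (`time_min`, `community`,
#'   `value`), detrended.
#' @return A tibble with columns `freq_per_h`, `power`; the attribute
#'   `dominant_period_h` carries the dominant period (also available via
#'   [dominant_period_h()]).
#' @export
power_spectrum <- function(data) {
  data <- check_series(data)
  dt_min <- series_dt(data)
  x <- data %>%
    group_by(.data$time_min) %>%
    summarise(value = mean(.data$value)) %>%
    arrange(.data$time_min) %>%
    pull(.data$value)
  x <- x - mean(x)
  if (all(x == 0)) {
    abort("Constant input has no spectrum.", class = "rhythmsync_error")
  }
  n <- length(x)
  npad <- 4 * n
  xf <- fft(c(x, numeric(npad - n)))
  full <- Mod(xf)^2 / (n * npad)
  k <- 0:(npad %/% 2)
  power <- full[k + 1]
  scale <- rep(2, length(k))
  scale[1] <- 1
  if (npad %% 2 == 0) scale[length(k)] <- 1
  power <- power * scale
  out <- tibble(freq_per_h = k / (npad * dt_min / 60), power = power)
  attr(out, "dominant_period_h") <- dominant_period_h(out)
  out
}

#' Dominant period of a power spectrum
#'
#' @param psd A tibble from [power_spectrum()] (columns `freq_per_h`,
#'   `power`).
#' @return The period (hours) of the maximal-power bin, excluding zero
#'   frequency.
#' @export
dominant_period_h <- function(psd) {
  psd <- as_tibble(psd)
  pos <- psd[psd$freq_per_h > 0, ]
  1 / pos$freq_per_h[which.max(pos$power)]
}

# Uniform sampling step (minutes) of a long trace table; errors on ragged
# grids.
series_dt <- function(data) {
  t <- sort(unique(data$time_min))
  if (length(t) < 2) {
    abort("Need at least two time points.", class = "rhythmsync_error")
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) {
    abort("Time grid is not uniform.", class = "rhythmsync_error")
  }
  dt[1]
}
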