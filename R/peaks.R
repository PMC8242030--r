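#' Detect reporter bursts as peaks
#'
#' A sample is a peak if it is preceded by at least `nups` non-decreasing
#' steps and followed by at least `ndowns` non-increasing steps (the
#' classic `nups`/`ndowns` rule used on fluorescence traces; the default 6
#' at 10-min sampling asks for an hour of monotone rise and fall), and its
#' topographic prominence reaches `min_prominence`. The burst width is the
#' full width at half prominence (FWHP), measured by linear interpolation
#' between samples at the level `height - prominence / 2`.
#'
#' @param x Numeric trace, uniformly sampled.
#' @param time Optional time stamps (same length as `x`); defaults to
#'   0-based sample indices.
#' @param nups,ndowns Required lengths of the rising and falling runs.
#' @param min_prominence Minimal topographic prominence.
#'
#' @return A tibble with one row per peak: `time`, `index`, `height`,
#'   `prominence`, `fwhp` (in the units of `time`).
#' @examples
#' x <- c(0:6, 5:0) # triangle with 6 rising and 6 falling steps
#' find_peaks(x)
#' @export
find_peaks <- function(x, time = NULL, nups = 6, ndowns = 6,
                       min_prominence = 0) {
  n <- length(x)
  if (n < nups + ndowns + 1) {
    abort("Trace shorter than nups + ndowns + 1 samples.",
      class = "rhythmsync_error")
  }
  if (is.null(time)) time <- seq_len(n) - 1
  if (length(time) != n) {
    abort("`time` must match the trace length.", class = "rhythmsync_error")
  }
  d <- diff(x)
  upr <- integer(n)
  dnr <- integer(n)
  for (i in 2:n) upr[i] <- if (d[i - 1] >= 0) upr[i - 1] + 1L else 0L
  for (i in (n - 1):1) dnr[i] <- if (d[i] <= 0) dnr[i + 1] + 1L else 0L
  cand <- which(upr >= nups & dnr >= ndowns)
  if (length(cand) > 1) {
    # collapse plateau runs of adjacent candidates to their first sample
    keep <- c(TRUE, diff(cand) > 1)
    cand <- cand[keep]
  }
  rows <- purrr::map_dfr(cand, function(i) {
    prom <- peak_prominence(x, i)
    if (prom < min_prominence || prom <= 0) {
      return(NULL)
    }
    width <- peak_fwhp(x, time, i, prom)
    tibble(
      time = time[i], index = i, height = x[i], prominence = prom,
      fwhp = width
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble(
      time = numeric(0), index = integer(0), height = numeric(0),
      prominence = numeric(0), fwhp = numeric(0)
    )
  }
  rows
}

# Topographic prominence: height above the higher of the two valley
# minima separating the peak from the nearest higher ground (or the
# record edge) on each side.
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i - 1
  while (j >= 1 && x[j] <= x[i]) {
    left_min <- min(left_min, x[j])
    j <- j - 1
  }
  if (j < 1) left_min <- min(x[1:i])
  right_min <- x[i]
  j <- i + 1
  while (j <= n && x[j] <= x[i]) {
    right_min <- min(right_min, x[j])
    j <- j + 1
  }
  if (j > n) right_min <- min(x[i:n])
  x[i] - max(left_min, right_min)
}

# Full width at half prominence by linear interpolation to the nearest
# crossings of level = height - prominence/2 on each side of the peak.
peak_fwhp <- function(x, time, i, prom) {
  level <- x[i] - prom / 2
  n <- length(x)
  j <- i
  while (j > 1 && x[j] > level) j <- j - 1
  t_left <- if (x[j] > level) {
    time[j] # record edge still above the level: truncate at the edge
  } else if (j == i) {
    time[i]
  } else {
    time[j] + (level - x[j]) / (x[j + 1] - x[j]) * (time[j + 1] - time[j])
  }
  j <- i
  while (j < n && x[j] > level) j <- j + 1
  t_right <- if (x[j] > level) {
    time[j]
  } else if (j == i) {
    time[i]
  } else {
    time[j - 1] +
      (x[j - 1] - level) / (x[j - 1] - x[j]) * (time[j] - time[j - 1])
  }
  t_right - t_left
}

#' Detect peaks in every community of a trace set
#'
#' @param data A single-channel trace tibble (`time_min`, `community`,
#'   `value`), typically the smoothed, growth-normalized signal.
#' @inheritParams find_peaks
#' @return A tibble with columns `community`, `peak_time_min`, `height`,
#'   `prominence`, `fwhp_min`.
#' @export
trace_peaks <- function(data, nups = 6, ndowns = 6, min_prominence = 0) {
  check_series(data) %>%
    group_by(.data$community) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    reframe({
      pk <- find_peaks(.data$value, .data$time_min,
        nups = nups, ndowns = ndowns, min_prominence = min_prominence
      )
      tibble(
        peak_time_min = pk$time, height = pk$height,
        prominence = pk$prominence, fwhp_min = pk$fwhp
      )
    })
}

#' Periods from successive peak times
#'
#' Periods are the first differences of successive burst peak times within
#' each community, reported in hours. Communities with fewer than two
#' peaks contribute no rows.
#'
#' @param peaks A peak table from [trace_peaks()] (columns `community`,
#'   `peak_time_min`).
#' @return A tibble with columns `community`, `period_h`.
#' @export
compute_periods <- function(peaks) {
  peaks <- as_tibble(peaks)
  if (!all(c("community", "peak_time_min") %in% names(peaks))) {
    abort("`peaks` needs columns community and peak_time_min.",
      class = "rhythmsync_error")
  }
  peaks %>%
    group_by(.data$community) %>%
    arrange(.data$peak_time_min, .by_group = TRUE) %>%
    reframe(period_h = diff(.data$peak_time_min) / 60)
}
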