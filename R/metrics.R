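#' Response precision of a reporter burst
#'
#' Relative agreement between the duration of the reporter burst and the
#' duration of the chemical pulse,
#' `precision = 1 - |width_output - width_input| / (width_output + width_input)`.
#' It equals 1 when the burst exactly matches the pulse and decreases as
#' the time-lagged decay widens (or truncates) the burst. The absolute
#' difference keeps the value in (0, 1\] whichever width is larger.
#'
#' @param width_output_min Burst full width at half prominence, minutes.
#' @param width_input_min Chemical pulse ON duration, minutes.
#' @return Precision in (0, 1\]; vectorized over the widths.
#' @examples
#' response_precision(450, 300)
#' @export
response_precision <- function(width_output_min, width_input_min) {
  if (any(width_output_min <= 0) || any(width_input_min <= 0)) {
    abort("Widths must be positive.", class = "rhythmsync_error")
  }
  1 - abs(width_output_min - width_input_min) /
    (width_output_min + width_input_min)
}

# Assign to every (community, cycle) the peak nearest to the cycle's drive
# onset, provided it lies within half a period; also count how many peaks
# fall inside that window. Cycle onsets are k * period (k = 0, 1, ...)
# plus an optional common reference offset.
assign_peaks_to_cycles <- function(peaks, program, ref_offset_min = 0) {
  peaks <- as_tibble(peaks)
  if (!all(c("community", "peak_time_min") %in% names(peaks))) {
    abort("`peaks` needs columns community and peak_time_min.",
      class = "rhythmsync_error")
  }
  T_min <- program$period_h * 60
  n_cycles <- floor(program$duration_h / program$period_h + 1e-9)
  onsets <- (seq_len(n_cycles) - 1) * T_min + ref_offset_min
  communities <- unique(peaks$community)
  purrr::map_dfr(communities, function(cm) {
    pt <- sort(peaks$peak_time_min[peaks$community == cm])
    purrr::map_dfr(seq_along(onsets), function(k) {
      lags <- pt - onsets[k]
      inside <- abs(lags) <= T_min / 2
      tibble(
        community = cm, cycle = k, onset_min = onsets[k],
        n_in_window = sum(inside),
        peak_time_min = if (any(inside)) {
          pt[inside][which.min(abs(lags[inside]))]
        } else {
          NA_real_
        }
      )
    })
  }) %>%
    mutate(lag_min = .data$peak_time_min - .data$onset_min)
}

#' Phase drift across communities
#'
#' Inter-community dispersion of burst timing, as a percentage of the
#' stimulation period. For every cycle, each community is assigned its
#' peak nearest to the cycle's drive onset (within half a period); the
#' per-cycle drift is the standard deviation of the assigned peak times
#' across communities divided by the period, in percent. The reported
#' value is the mean over cycles with at least two assigned communities.
#'
#' @param peaks A peak table from [trace_peaks()] covering two or more
#'   communities.
#' @param program The [input_program()] that drove the recording.
#' @param ref_offset_min Optional common offset of the cycle reference
#'   from the drive onset, minutes.
#' @return Phase drift in percent (a single non-negative number).
#' @export
phase_drift <- function(peaks, program, ref_offset_min = 0) {
  asg <- assign_peaks_to_cycles(peaks, program, ref_offset_min)
  per_cycle <- asg %>%
    filter(!is.na(.data$peak_time_min)) %>%
    group_by(.data$cycle) %>%
    summarise(n = dplyr::n(), sd_min = sd(.data$peak_time_min)) %>%
    filter(.data$n >= 2)
  if (nrow(per_cycle) == 0) {
    abort("No cycle has two or more assigned peaks.",
      class = "rhythmsync_error")
  }
  mean(per_cycle$sd_min) / (program$period_h * 60) * 100
}

#' Fraction of synchronized communities
#'
#' A community counts as phase-locked when it shows exactly one peak
#' within half a period of the cycle reference in at least
#' `cycle_coverage` of the cycles, and the mean absolute lag of those
#' peaks from the reference stays below `lag_tol_min` (default a quarter
#' period).
#'
#' @inheritParams phase_drift
#' @param lag_tol_min Lag tolerance in minutes (default `period / 4`).
#' @param cycle_coverage Required fraction of cycles with exactly one
#'   in-window peak.
#' @return The locked fraction, in \[0, 1\].
#' @export
sync_fraction <- function(peaks, program, lag_tol_min = NULL,
                          cycle_coverage = 0.9, ref_offset_min = 0) {
  if (is.null(lag_tol_min)) lag_tol_min <- program$period_h * 60 / 4
  asg <- assign_peaks_to_cycles(peaks, program, ref_offset_min)
  per_comm <- asg %>%
    group_by(.data$community) %>%
    summarise(
      coverage = mean(.data$n_in_window == 1),
      mean_lag = mean(abs(.data$lag_min[.data$n_in_window == 1]))
    )
  locked <- per_comm$coverage >= cycle_coverage &
    !is.na(per_comm$mean_lag) & per_comm$mean_lag < lag_tol_min
  mean(locked)
}

#' Period-doubling ratios
#'
#' Ratio between the reporter period (median of successive peak
#' distances) and the stimulation period, per community. Ratios are
#' snapped to the nearest of 1, 2, 4, 8 when within 25% relative distance
#' (`ratio_snapped`, `NA` otherwise); the raw ratio is retained.
#' Communities with fewer than two peaks are omitted.
#'
#' @inheritParams phase_drift
#' @return A tibble with columns `community`, `ratio`, `ratio_snapped`.
#' @export
doubling_ratios <- function(peaks, program) {
  periods <- compute_periods(peaks)
  if (nrow(periods) == 0) {
    return(tibble(
      community = character(0), ratio = numeric(0),
      ratio_snapped = numeric(0)
    ))
  }
  targets <- c(1, 2, 4, 8)
  periods %>%
    group_by(.data$community) %>%
    summarise(ratio = median(.data$period_h) / program$period_h) %>%
    mutate(
      ratio_snapped = purrr::map_dbl(.data$ratio, function(r) {
        m <- targets[which.min(abs(r - targets) / targets)]
        if (abs(r - m) / m <= 0.25) m else NA_real_
      })
    )
}

#' Construct jittered peak trains for metric validation
#'
#' Builds an ensemble of per-community peak trains in which every
#' community peaks once per cycle at the cycle reference plus independent
#' Gaussian jitter of standard deviation `jitter_sd_frac * period`. Used
#' to verify that [phase_drift()] recovers an engineered dispersion.
#'
#' @param n_communities Number of communities.
#' @param program An [input_program()]; one peak per cycle is placed at
#'   each cycle onset.
#' @param jitter_sd_frac Jitter standard deviation as a fraction of the
#'   period.
#' @param seed Integer seed.
#' @param lag_min Common lag added to every peak time, minutes.
#' @return A peak table with columns `community`, `peak_time_min`.
#' @export
jitter_peak_ensemble <- function(n_communities, program, jitter_sd_frac,
                                 seed, lag_min = 0) {
  set.seed(seed)
  T_min <- program$period_h * 60
  n_cycles <- floor(program$duration_h / program$period_h + 1e-9)
  onsets <- (seq_len(n_cycles) - 1) * T_min
  purrr::map_dfr(seq_len(n_communities), function(i) {
    tibble(
      community = community_label(i),
      peak_time_min = onsets + lag_min +
        rnorm(n_cycles, 0, jitter_sd_frac * T_min)
    )
  })
}
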