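#' Rate-dependent hysteresis width
#'
#' Effective hysteresis width seen by a drive of period `T_input_h`:
#' `h(T) = h0 * (1 + kappa * T_ref_h / T)`. The width grows linearly with
#' the input rate `1/T`, so faster rhythms switch through a wider
#' hysteresis region; `kappa = 0` recovers the classical fixed width.
#'
#' @param T_input_h Input period in hours (> 0; `Inf` gives the base width).
#' @param switch A [switch_params()] object.
#' @return The dimensionless width `h`.
#' @examples
#' hysteresis_width(10, switch_params(h0 = 0.2, kappa = 1.25))
#' @export
hysteresis_width <- function(T_input_h, switch) {
  stopifnot(inherits(switch, "switch_params"))
  if (any(T_input_h <= 0)) {
    abort("`T_input_h` must be positive.", class = "rhythmsync_error")
  }
  switch$h0 * (1 + switch$kappa * switch$T_ref_h / T_input_h)
}

#' Switching thresholds for a given drive period
#'
#' @inheritParams hysteresis_width
#' @return Named numeric vector with `theta_on = mid + h/2` and
#'   `theta_off = mid - h/2`.
#' @export
switch_thresholds <- function(T_input_h, switch) {
  h <- hysteresis_width(T_input_h, switch)
  c(theta_on = switch$mid + h / 2, theta_off = switch$mid - h / 2)
}

#' Simulate the noisy hysteretic switch
#'
#' Two-state Schmitt trigger driven by `u(t)` plus Ornstein-Uhlenbeck
#' noise. The noise obeys
#' `d(eta) = -eta / noise_tau_h dt + noise_sigma * sqrt(2 dt / noise_tau_h) * N(0,1)`
#' (Euler-Maruyama on the drive grid). The state flips 0 to 1 when
#' `u + eta > theta_on` and 1 to 0 when `u + eta < theta_off`; landing
#' exactly on a threshold causes no transition. The initial state is
#' `u(0) > mid`.
#'
#' @param drive A data frame with columns `time_h` and `u` on a uniform
#'   grid, e.g. a renamed output of [chemical_to_drive()].
#' @param switch A [switch_params()] object. The grid spacing must satisfy
#'   the `dt <= noise_tau_h / 5` stability bound when `noise_sigma > 0`.
#' @param period_h Period of the drive, used to set the rate-dependent
#'   thresholds via [hysteresis_width()]. Use `Inf` for non-periodic
#'   drives (base width).
#' @param seed Integer seed; the trajectory is bit-reproducible.
#'
#' @return A tibble with columns `time_h`, `drive`, `state` (0/1), and
#'   attributes `theta_on`, `theta_off`.
#' @export
simulate_switch <- function(drive, switch, period_h, seed) {
  stopifnot(inherits(switch, "switch_params"))
  drive <- as_tibble(drive)
  if (!all(c("time_h", "u") %in% names(drive)) || nrow(drive) == 0) {
    abort("`drive` needs non-empty columns time_h and u.",
      class = "rhythmsync_error")
  }
  n <- nrow(drive)
  dt_h <- if (n > 1) drive$time_h[2] - drive$time_h[1] else switch$dt_h
  if (n > 2 && max(abs(diff(drive$time_h) - dt_h)) > 1e-8 * dt_h) {
    abort("`drive` must be uniformly sampled.", class = "rhythmsync_error")
  }
  if (switch$noise_sigma > 0 && dt_h > switch$noise_tau_h / 5) {
    abort("Drive grid too coarse for the noise correlation time.",
      class = "rhythmsync_error")
  }
  th <- switch_thresholds(period_h, switch)
  set.seed(seed)
  state <- schmitt_trigger(drive$u, th[["theta_on"]], th[["theta_off"]],
    mid = switch$mid, sigma = switch$noise_sigma,
    tau = switch$noise_tau_h, dt = dt_h
  )
  out <- tibble(time_h = drive$time_h, drive = drive$u, state = state)
  attr(out, "theta_on") <- th[["theta_on"]]
  attr(out, "theta_off") <- th[["theta_off"]]
  out
}

# Core Schmitt-trigger loop with OU noise; uses the current RNG stream.
# `gate` (optional logical vector) forces the state to 0 where TRUE without
# consuming extra random numbers, so gated and ungated runs share streams.
schmitt_trigger <- function(u, theta_on, theta_off, mid, sigma, tau, dt,
                            gate = NULL) {
  n <- length(u)
  state <- integer(n)
  s <- as.integer(u[1] > mid)
  eta <- 0
  kick <- sigma * sqrt(2 * dt / tau)
  decay <- 1 - dt / tau
  z <- if (n > 1) rnorm(n - 1) else numeric(0)
  if (!is.null(gate) && isTRUE(gate[1])) s <- 0L
  state[1] <- s
  if (n > 1) {
    for (k in 2:n) {
      eta <- eta * decay + kick * z[k - 1]
      v <- u[k] + eta
      if (s == 0L) {
        if (v > theta_on) s <- 1L
      } else if (v < theta_off) {
        s <- 0L
      }
      if (!is.null(gate) && gate[k]) s <- 0L
      state[k] <- s
    }
  }
  state
}

#' Square-wave drive for switch experiments
#'
#' Builds the symmetric drive used in the stochastic-resonance sweeps:
#' `u = +amplitude` during the first half of each cycle and `-amplitude`
#' during the second half.
#'
#' @param amplitude Drive amplitude (dimensionless).
#' @param period_h Cycle period, hours.
#' @param duration_h Total duration, hours.
#' @param dt_h Grid step, hours.
#' @return A tibble with columns `time_h`, `u`.
#' @export
square_drive <- function(amplitude, period_h, duration_h, dt_h = 1 / 120) {
  time_h <- seq(0, duration_h - dt_h, by = dt_h)
  phase <- time_h %% period_h
  tibble(time_h = time_h, u = ifelse(phase < period_h / 2, amplitude, -amplitude))
}

#' Write a synchronization sweep as a CSV matrix with a JSON sidecar
#'
#' Stores a [sweep_noise_rate()] result as a noise x period matrix
#' (rows = noise levels, columns = periods, both as headers) plus a
#' `<path>.json` sidecar holding the switch parameters and sweep settings
#' so the grid is reconstructible.
#'
#' @param sweep Output of [sweep_noise_rate()].
#' @param path CSV output path.
#' @param switch The [switch_params()] used (stored in the sidecar).
#' @param settings Optional named list of extra sweep settings to record.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, switch = NULL, settings = list()) {
  wide <- sweep %>%
    tidyr::pivot_wider(names_from = "period_h", values_from = "sync_index",
      names_prefix = "period_h_")
  readr::write_csv(wide, path)
  sidecar <- settings
  if (!is.null(switch)) sidecar$switch <- unclass(switch)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Synchronization index of switch trajectories
#'
#' Fraction of (trajectory, cycle) pairs in which the state makes exactly
#' one OFF-to-ON transition inside the cycle and that transition falls
#' within a quarter period of the drive's upward crossing at the cycle
#' onset. 1 means perfect locking to the rhythm. The first cycle is not
#' scored: the switch initializes to the sign of the drive, so a record
#' that starts inside a high phase has no transition there by
#' construction (an entrainment transient, not a locking failure).
#'
#' @param trajectories A data frame with columns `trajectory` (id),
#'   `time_h` and `state`, stacking two or more [simulate_switch()]
#'   outputs on a common grid.
#' @param period_h Drive period in hours (cycle onsets at `k * period_h`).
#'
#' @return A number in \[0, 1\].
#' @export
sync_index <- function(trajectories, period_h) {
  trajectories <- as_tibble(trajectories)
  need <- c("trajectory", "time_h", "state")
  if (!all(need %in% names(trajectories))) {
    abort("`trajectories` needs columns trajectory, time_h, state.",
      class = "rhythmsync_error")
  }
  ids <- unique(trajectories$trajectory)
  if (length(ids) < 2) {
    abort("Need at least two trajectories.", class = "rhythmsync_error")
  }
  grids <- trajectories %>%
    group_by(.data$trajectory) %>%
    summarise(n = dplyr::n(), t0 = min(.data$time_h), t1 = max(.data$time_h))
  if (length(unique(grids$n)) > 1 || length(unique(grids$t0)) > 1 ||
      length(unique(grids$t1)) > 1) {
    abort("Trajectories are on mismatched grids.", class = "rhythmsync_error")
  }
  tgrid <- sort(unique(trajectories$time_h))
  duration_h <- max(tgrid) + (tgrid[2] - tgrid[1])
  n_cycles <- floor(duration_h / period_h + 1e-9)
  if (n_cycles < 2) {
    abort("Need at least two full cycles to score locking.",
      class = "rhythmsync_error")
  }
  onsets <- seq_len(n_cycles - 1) * period_h
  hits <- 0L
  total <- 0L
  for (id in ids) {
    tr <- trajectories[trajectories$trajectory == id, ]
    tr <- tr[order(tr$time_h), ]
    on_idx <- which(diff(tr$state) == 1) + 1
    on_times <- tr$time_h[on_idx]
    for (t0 in onsets) {
      in_cycle <- on_times[on_times >= t0 & on_times < t0 + period_h]
      total <- total + 1L
      if (length(in_cycle) == 1 && abs(in_cycle - t0) <= period_h / 4) {
        hits <- hits + 1L
      }
    }
  }
  hits / total
}

#' Sweep synchronization over noise level and stimulation period
#'
#' For every (noise, period) grid cell, simulates an ensemble of
#' independent switch trajectories under a square-wave drive and averages
#' the [sync_index()] over `n_rep` replicate seeds. Reproduces the
#' stochastic-resonance behaviour of the rate-dependent switch: with
#' `kappa > 0` the enlarged hysteresis at fast rhythms tolerates a wider
#' band of noise, while weak driving degrades synchronization.
#'
#' @param noise_grid Numeric vector of noise standard deviations.
#' @param period_grid Numeric vector of drive periods, hours.
#' @param amplitude Square-wave drive amplitude. The default 1.2 clears
#'   the enlarged ON threshold at the fastest default period.
#' @param switch A [switch_params()] object (`noise_sigma` is overridden
#'   cell by cell).
#' @param n_rep Replicate seeds per cell.
#' @param seed Root seed.
#' @param n_traj Trajectories per replicate.
#' @param n_cycles Drive cycles per trajectory.
#'
#' @return A tibble with columns `noise_sigma`, `period_h`, `sync_index`.
#' @export
sweep_noise_rate <- function(noise_grid, period_grid, amplitude = 1.2,
                             switch = switch_params(), n_rep = 3, seed = 1,
                             n_traj = 8, n_cycles = 6) {
  if (length(noise_grid) == 0 || length(period_grid) == 0) {
    abort("Grids must be non-empty.", class = "rhythmsync_error")
  }
  if (n_rep < 1) {
    abort("`n_rep` must be >= 1.", class = "rhythmsync_error")
  }
  grid <- tidyr::expand_grid(noise_sigma = noise_grid, period_h = period_grid)
  grid$sync_index <- purrr::pmap_dbl(
    grid,
    function(noise_sigma, period_h) {
      sw <- switch
      sw$noise_sigma <- noise_sigma
      drv <- square_drive(amplitude, period_h,
        duration_h = n_cycles * period_h, dt_h = sw$dt_h
      )
      vals <- vapply(seq_len(n_rep), function(rep) {
        trajs <- purrr::map(seq_len(n_traj), function(j) {
          tr <- simulate_switch(drv, sw, period_h,
            seed = stream_seed(seed, (rep - 1) * n_traj + j)
          )
          tr$trajectory <- j
          tr
        })
        sync_index(bind_rows(trajs), period_h)
      }, numeric(1))
      mean(vals)
    }
  )
  grid
}
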