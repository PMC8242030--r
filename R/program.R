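#' Sample the chemical waveforms of a stimulation program
#'
#' Evaluates the rectangular SA and IAA concentration waveforms of an
#' [input_program()] on a uniform grid. IAA is ON during
#' `[k*T, k*T + pulse_width)` of every cycle `k`; in antiphase mode SA is ON
#' exactly when IAA is OFF. The grid spans `[0, duration)` so each cycle
#' contributes exactly `60 * period_h / dt_min` samples.
#'
#' @param program An [input_program()].
#' @param dt_min Sampling step in minutes; defaults to the program's own
#'   step. A finer step is used internally by the simulator.
#'
#' @return A tibble with columns `time_min`, `c_SA`, `c_IAA` (micromolar).
#' @examples
#' wf <- program_waveforms(input_program(10, 5, duration_h = 20))
#' range(wf$c_IAA)
#' @export
program_waveforms <- function(program, dt_min = program$dt_min) {
  stopifnot(inherits(program, "input_program"))
  steps_per_cycle <- 60 * program$period_h / dt_min
  if (abs(steps_per_cycle - round(steps_per_cycle)) > 1e-8) {
    abort("`dt_min` must divide the program period exactly.",
      class = "rhythmsync_error")
  }
  time_min <- seq(0, program$duration_h * 60 - dt_min, by = dt_min)
  phase_min <- time_min %% (program$period_h * 60)
  iaa_on <- phase_min < program$pulse_width_h * 60
  sa_on <- if (program$antiphase) !iaa_on else iaa_on
  tibble(
    time_min = time_min,
    c_SA = ifelse(sa_on, program$amplitude_SA, 0),
    c_IAA = ifelse(iaa_on, program$amplitude_IAA, 0)
  )
}

#' Map chemical concentrations to the effective promoter drive
#'
#' The raw drive is the activating Hill response to IAA minus the
#' repressing Hill response to SA,
#' `u_raw = c_IAA^n / (c_IAA^n + ec50_IAA^n) - c_SA^m / (c_SA^m + ec50_SA^m)`,
#' bounded in \[-1, 1\]. Receptor turnover and sensing delays are lumped
#' into a first-order relaxation `du/dt = (u_raw - u) / tau_u_h` with
#' `u(0) = u_raw(0)`, integrated exactly on each sampling interval.
#'
#' @param waveforms A data frame with columns `time_min`, `c_SA`, `c_IAA`
#'   on a uniform grid (e.g. from [program_waveforms()]).
#' @param circuit A [circuit_params()] object.
#'
#' @return The input tibble with added columns `u_raw` and `u`.
#' @examples
#' wf <- program_waveforms(input_program(10, 5, duration_h = 20))
#' drv <- chemical_to_drive(wf, circuit_params())
#' range(drv$u)
#' @export
chemical_to_drive <- function(waveforms, circuit) {
  stopifnot(inherits(circuit, "circuit_params"))
  waveforms <- as_tibble(waveforms)
  need <- c("time_min", "c_SA", "c_IAA")
  if (!all(need %in% names(waveforms))) {
    abort("`waveforms` needs columns time_min, c_SA, c_IAA.",
      class = "rhythmsync_error")
  }
  if (nrow(waveforms) == 0) {
    abort("Empty concentration grid.", class = "rhythmsync_error")
  }
  if (any(waveforms$c_SA < 0) || any(waveforms$c_IAA < 0)) {
    abort("Concentrations must be non-negative.", class = "rhythmsync_error")
  }
  u_raw <- hill_fraction(waveforms$c_IAA, circuit$ec50_IAA, circuit$hill_IAA) -
    hill_fraction(waveforms$c_SA, circuit$ec50_SA, circuit$hill_SA)
  dt_h <- if (nrow(waveforms) > 1) diff(waveforms$time_min[1:2]) / 60 else 0
  waveforms$u_raw <- u_raw
  waveforms$u <- relax_first_order(u_raw, circuit$tau_u_h, dt_h)
  waveforms
}

# Fractional Hill occupancy c^n / (c^n + ec50^n); returns 0 at c = 0.
hill_fraction <- function(c, ec50, n) {
  r <- (c / ec50)^n
  r / (1 + r)
}

# Exact exponential relaxation of x toward target on each step;
# tau = 0 returns the target itself.
relax_first_order <- function(target, tau_h, dt_h) {
  if (tau_h <= 0 || dt_h <= 0 || length(target) < 2) {
    return(target)
  }
  a <- exp(-dt_h / tau_h)
  out <- numeric(length(target))
  out[1] <- target[1]
  for (k in 2:length(target)) {
    out[k] <- target[k] + (out[k - 1] - target[k]) * a
  }
  out
}
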