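#' Chemical stimulation program
#'
#' Describes the rectangular antiphase rhythm of salicylic acid (SA) and
#' auxin (IAA) delivered to the communities: IAA is ON during the first
#' `pulse_width_h` hours of every cycle and, in antiphase mode, SA is ON
#' exactly when IAA is OFF.
#'
#' @param period_h Cycle period in hours.
#' @param pulse_width_h ON duration of the IAA pulse per cycle, hours.
#'   Defaults to half the period (symmetric antiphase rhythm).
#' @param amplitude_SA SA pulse amplitude in micromolar.
#' @param amplitude_IAA IAA pulse amplitude in micromolar.
#' @param antiphase If `TRUE`, SA is ON exactly when IAA is OFF; if `FALSE`
#'   both chemicals share the same ON window.
#' @param duration_h Total program duration in hours.
#' @param dt_min Sampling step in minutes. Must divide the period (in
#'   minutes) exactly; incommensurate steps are rejected rather than
#'   silently rounded.
#'
#' @return An object of class `input_program` (a named list of the
#'   validated fields).
#' @examples
#' prog <- input_program(period_h = 10, pulse_width_h = 5, duration_h = 20)
#' program_waveforms(prog)
#' @export
input_program <- function(period_h,
                          pulse_width_h = period_h / 2,
                          amplitude_SA = 500,
                          amplitude_IAA = 1,
                          antiphase = TRUE,
                          duration_h = 48,
                          dt_min = 10) {
  if (!is.numeric(period_h) || period_h <= 0) {
    abort("`period_h` must be a positive number.", class = "rhythmsync_error")
  }
  if (pulse_width_h <= 0 || pulse_width_h > period_h) {
    abort("`pulse_width_h` must satisfy 0 < pulse_width_h <= period_h.",
      class = "rhythmsync_error")
  }
  if (duration_h < period_h) {
    abort("`duration_h` must cover at least one full cycle.",
      class = "rhythmsync_error")
  }
  if (dt_min <= 0) {
    abort("`dt_min` must be positive.", class = "rhythmsync_error")
  }
  if (amplitude_SA < 0 || amplitude_IAA < 0) {
    abort("Amplitudes must be non-negative.", class = "rhythmsync_error")
  }
  steps_per_cycle <- 60 * period_h / dt_min
  if (abs(steps_per_cycle - round(steps_per_cycle)) > 1e-8) {
    abort(
      "`dt_min` must divide the period exactly (no silent rounding).",
      class = "rhythmsync_error"
    )
  }
  structure(
    list(
      period_h = period_h, pulse_width_h = pulse_width_h,
      amplitude_SA = amplitude_SA, amplitude_IAA = amplitude_IAA,
      antiphase = isTRUE(antiphase), duration_h = duration_h,
      dt_min = dt_min
    ),
    class = "input_program"
  )
}

#' @export
print.input_program <- function(x, ...) {
  cat(sprintf(
    "<input_program> %g h cycle (%g h IAA pulse%s), %g uM SA / %g uM IAA, %g h at %g min\n",
    x$period_h, x$pulse_width_h,
    if (x$antiphase) ", antiphase SA" else ", in-phase SA",
    x$amplitude_SA, x$amplitude_IAA, x$duration_h, x$dt_min
  ))
  invisible(x)
}

#' Receptor-circuit parameters
#'
#' Phenomenological parameters of the dual-receptor reporter circuit: Hill
#' dose responses of the IAA-sensing activator and SA-sensing repressor, the
#' sensing relaxation time of the effective drive, reporter production and
#' turnover, and community-level heterogeneity.
#'
#' Defaults use the measured receptor EC50s (0.13 uM IAA, 407.3 uM SA) with
#' Hill coefficient 2, a short-lived reporter (2.5 h half-life) diluted by
#' growth at 0.1 per hour, and mild extrinsic (10% CV) and measurement
#' (5% CV) variability.
#'
#' @param ec50_IAA,ec50_SA Half-maximal concentrations, micromolar.
#' @param hill_IAA,hill_SA Hill coefficients (>= 1).
#' @param tau_u_h Sensing relaxation time of the effective drive, hours.
#' @param alpha Maximal reporter production rate, fluorescence per hour.
#' @param basal_frac Basal (promoter OFF) production as a fraction of
#'   `alpha`, in \[0, 1).
#' @param reporter_halflife_h Reporter protein half-life, hours.
#' @param mcherry_level Constitutive mCherry level, fluorescence units.
#' @param growth_dilution_h Dilution rate from growth, per hour.
#' @param extrinsic_cv Coefficient of variation of per-community lognormal
#'   parameter perturbations, in \[0, 0.5\].
#' @param meas_cv Multiplicative lognormal measurement-noise CV applied to
#'   the sampled fluorescence channels.
#' @param feedback_mode One of `"OL"` (open loop), `"NFL"` (negative
#'   feedback), `"PFL"` (positive feedback).
#' @param feedback_gain Dimensionless feedback gain (>= 0).
#'
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(ec50_IAA = 0.13, hill_IAA = 2,
                           ec50_SA = 407.3, hill_SA = 2,
                           tau_u_h = 1.5,
                           alpha = 1, basal_frac = 0.02,
                           reporter_halflife_h = 2.5,
                           mcherry_level = 1,
                           growth_dilution_h = 0.1,
                           extrinsic_cv = 0.1,
                           meas_cv = 0.05,
                           feedback_mode = c("OL", "NFL", "PFL"),
                           feedback_gain = 0) {
  feedback_mode <- match.arg(feedback_mode)
  if (ec50_IAA <= 0 || ec50_SA <= 0) {
    abort("EC50 values must be positive.", class = "rhythmsync_error")
  }
  if (hill_IAA < 1 || hill_SA < 1) {
    abort("Hill coefficients must be >= 1.", class = "rhythmsync_error")
  }
  if (reporter_halflife_h <= 0) {
    abort("`reporter_halflife_h` must be positive.", class = "rhythmsync_error")
  }
  if (basal_frac < 0 || basal_frac >= 1) {
    abort("`basal_frac` must lie in [0, 1).", class = "rhythmsync_error")
  }
  if (extrinsic_cv < 0 || extrinsic_cv > 0.5) {
    abort("`extrinsic_cv` must lie in [0, 0.5].", class = "rhythmsync_error")
  }
  if (tau_u_h < 0 || meas_cv < 0 || growth_dilution_h < 0 ||
      feedback_gain < 0 || alpha < 0 || mcherry_level < 0) {
    abort("Rates, gains and levels must be non-negative.",
      class = "rhythmsync_error")
  }
  structure(
    list(
      ec50_IAA = ec50_IAA, hill_IAA = hill_IAA,
      ec50_SA = ec50_SA, hill_SA = hill_SA,
      tau_u_h = tau_u_h, alpha = alpha, basal_frac = basal_frac,
      reporter_halflife_h = reporter_halflife_h,
      mcherry_level = mcherry_level,
      growth_dilution_h = growth_dilution_h,
      extrinsic_cv = extrinsic_cv, meas_cv = meas_cv,
      feedback_mode = feedback_mode, feedback_gain = feedback_gain
    ),
    class = "circuit_params"
  )
}

#' Hysteretic switch parameters
#'
#' Two-state (Schmitt-trigger) promoter switch with rate-dependent
#' hysteresis and Ornstein-Uhlenbeck input noise. The effective hysteresis
#' width for a drive of period `T` is `h(T) = h0 * (1 + kappa * T_ref_h / T)`:
#' faster rhythms see a wider hysteresis region, which gates out noise.
#'
#' @param mid Threshold midpoint on the drive axis.
#' @param h0 Base hysteresis width (>= 0).
#' @param kappa Rate-dependence coefficient (>= 0); `kappa = 0` recovers a
#'   classical fixed hysteresis.
#' @param T_ref_h Reference period, hours.
#' @param noise_sigma Stationary standard deviation of the OU noise added
#'   to the drive.
#' @param noise_tau_h OU noise correlation time, hours.
#' @param dt_h Integration step, hours. Must satisfy
#'   `dt_h <= noise_tau_h / 5` whenever `noise_sigma > 0`.
#'
#' @return An object of class `switch_params`.
#' @export
switch_params <- function(mid = 0.325, h0 = 0.2, kappa = 1.25,
                          T_ref_h = 10, noise_sigma = 0.3,
                          noise_tau_h = 0.5, dt_h = 1 / 120) {
  if (h0 < 0 || kappa < 0) {
    abort("`h0` and `kappa` must be non-negative.", class = "rhythmsync_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be non-negative.", class = "rhythmsync_error")
  }
  if (noise_tau_h <= 0 || dt_h <= 0) {
    abort("`noise_tau_h` and `dt_h` must be positive.",
      class = "rhythmsync_error")
  }
  if (noise_sigma > 0 && dt_h > noise_tau_h / 5) {
    abort("`dt_h` must be <= noise_tau_h / 5 when noise_sigma > 0.",
      class = "rhythmsync_error")
  }
  structure(
    list(
      mid = mid, h0 = h0, kappa = kappa, T_ref_h = T_ref_h,
      noise_sigma = noise_sigma, noise_tau_h = noise_tau_h, dt_h = dt_h
    ),
    class = "switch_params"
  )
}

#' Killer-toxin parameters for the two-strain consortium
#'
#' The killer strain produces K1 toxin while its promoter is ON; the shared
#' toxin field decays first-order. Sensitive communities integrate the
#' toxin into a stress variable (1 h relaxation) and, when stressed at a
#' cycle onset, skip `refractory_cycles` input cycles before responding
#' again -- the mechanism that produces period doubling.
#'
#' @param toxin_rate Toxin production rate while the killer promoter is ON,
#'   a.u. per hour.
#' @param toxin_decay_h Toxin decay rate, per hour.
#' @param stress_threshold Stress level above which a community skips
#'   cycles (> 0).
#' @param refractory_cycles Number of cycles skipped per stress event
#'   (integer >= 1).
#'
#' @return An object of class `toxin_params`.
#' @export
toxin_params <- function(toxin_rate = 1, toxin_decay_h = 0.3,
                         stress_threshold = 0.5, refractory_cycles = 1) {
  if (toxin_rate < 0 || toxin_decay_h < 0) {
    abort("Toxin rates must be non-negative.", class = "rhythmsync_error")
  }
  if (stress_threshold <= 0) {
    abort("`stress_threshold` must be positive.", class = "rhythmsync_error")
  }
  if (refractory_cycles < 1 || refractory_cycles != round(refractory_cycles)) {
    abort("`refractory_cycles` must be an integer >= 1.",
      class = "rhythmsync_error")
  }
  structure(
    list(
      toxin_rate = toxin_rate, toxin_decay_h = toxin_decay_h,
      stress_threshold = stress_threshold,
      refractory_cycles = as.integer(refractory_cycles)
    ),
    class = "toxin_params"
  )
}
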