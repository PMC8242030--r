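# Deterministic per-community seed streams: the root seed and a stream
# index are mixed into a 32-bit seed, so adding communities never perturbs
# the streams of existing ones. All intermediates stay below 2^53.
stream_seed <- function(root, index) {
  ((root %% 2147483647) * 69069 + index * 1013904223) %% 2147483647
}

# Lognormal per-community perturbation (mean 1, coefficient of variation
# `cv`) of the scale parameters alpha, reporter half-life, sensing time and
# mCherry level. Four variates are always consumed so RNG streams align
# across heterogeneity settings.
perturb_circuit <- function(circuit, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  f <- stats::rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  circuit$alpha <- circuit$alpha * f[1]
  circuit$reporter_halflife_h <- circuit$reporter_halflife_h * f[2]
  circuit$tau_u_h <- circuit$tau_u_h * f[3]
  circuit$mcherry_level <- circuit$mcherry_level * f[4]
  circuit
}

# Single-community simulation core. Assumes the RNG has been seeded by the
# caller. Integrates promoter switching and the reporter ODE on the fine
# switch grid (dt_h, default 0.5 min) and samples at the program's dt_min.
# `gate` forces the promoter OFF on fine-grid steps where TRUE.
sim_community_core <- function(program, circuit, switch, gate = NULL,
                               with_reporter = TRUE) {
  dt_int_min <- switch$dt_h * 60
  ratio <- program$dt_min / dt_int_min
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1) {
    abort("Switch step `dt_h` must divide the sampling step `dt_min`.",
      class = "rhythmsync_error")
  }
  drv <- chemical_to_drive(program_waveforms(program, dt_min = dt_int_min),
    circuit)
  th <- switch_thresholds(program$period_h, switch)
  state <- schmitt_trigger(drv$u, th[["theta_on"]], th[["theta_off"]],
    mid = switch$mid, sigma = switch$noise_sigma,
    tau = switch$noise_tau_h, dt = switch$dt_h, gate = gate
  )
  idx <- seq(1, nrow(drv), by = round(ratio))
  if (!with_reporter) {
    return(list(time_min = drv$time_min, state = state, idx = idx))
  }
  G <- integrate_reporter(state, circuit, switch$dt_h)
  degfp <- G[idx]
  mcherry <- rep(circuit$mcherry_level, length(idx))
  if (circuit$meas_cv > 0) {
    sdlog <- sqrt(log(1 + circuit$meas_cv^2))
    degfp <- degfp *
      stats::rlnorm(length(idx), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mcherry <- mcherry *
      stats::rlnorm(length(idx), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tibble(
    time_min = drv$time_min[idx],
    degfp = degfp,
    mcherry = mcherry,
    promoter = state[idx]
  )
}

# Euler integration of the reporter ODE
#   dG/dt = alpha_eff(G) * (basal + (1 - basal) * P) - delta * G
# with delta = ln2 / halflife + growth dilution and phenomenological
# production-rate feedback around G_ref = alpha * halflife / ln2.
integrate_reporter <- function(state, circuit, dt_h) {
  n <- length(state)
  delta <- log(2) / circuit$reporter_halflife_h + circuit$growth_dilution_h
  basal <- circuit$basal_frac
  alpha <- circuit$alpha
  g_ref <- alpha * circuit$reporter_halflife_h / log(2)
  gain <- circuit$feedback_gain
  mode <- circuit$feedback_mode
  G <- numeric(n)
  G[1] <- alpha * basal / delta
  for (k in 2:n) {
    g <- G[k - 1]
    aeff <- switch(mode,
      OL = alpha,
      NFL = alpha / (1 + gain * g / g_ref),
      PFL = alpha * (1 + gain * g / g_ref) / (1 + g / g_ref)
    )
    prod <- aeff * (basal + (1 - basal) * state[k - 1])
    G[k] <- g + dt_h * (prod - delta * g)
  }
  if (any(!is.finite(G))) {
    bad <- which(!is.finite(G))[1]
    abort(sprintf("Reporter state became non-finite at step %d.", bad),
      class = "rhythmsync_error")
  }
  G
}

#' Simulate one community's reporter dynamics
#'
#' Drives the hysteretic promoter switch with the effective chemical drive
#' of the program and integrates the short-lived reporter
#' `dG/dt = alpha_eff * (basal + (1 - basal) * P(t)) - (ln2 / halflife + dilution) * G`
#' at the fine switch step (default 0.5 min), sampling the output at the
#' program's `dt_min` to mimic the imaging cadence. The constitutive
#' mCherry channel is a constant level with multiplicative lognormal
#' measurement noise.
#'
#' @param program An [input_program()].
#' @param circuit A [circuit_params()] object.
#' @param switch A [switch_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A tibble with columns `time_min`, `degfp`, `mcherry`,
#'   `promoter` (0/1 switch state).
#' @examples
#' prog <- input_program(10, 5, duration_h = 20)
#' tr <- simulate_community(prog, circuit_params(), switch_params(), seed = 1)
#' @export
simulate_community <- function(program, circuit, switch, seed) {
  stopifnot(inherits(program, "input_program"),
    inherits(circuit, "circuit_params"), inherits(switch, "switch_params"))
  set.seed(seed)
  sim_community_core(program, circuit, switch)
}

community_label <- function(i) sprintf("C%02d", i)

#' Simulate an ensemble of uncoupled communities
#'
#' Each community receives the same chemical program but its own
#' independent noise stream and lognormally perturbed parameters
#' (coefficient of variation `extrinsic_cv`), emulating trap-to-trap
#' variability in microfluidics recordings. Communities are mutually
#' uncoupled; seed streams are keyed by community index so adding
#' communities never perturbs existing ones.
#'
#' @param n_communities Number of communities (>= 1).
#' @inheritParams simulate_community
#'
#' @return A tidy tibble with columns `time_min`, `community`, `channel`
#'   (`"dEGFP"` or `"mCherry"`), `value`.
#' @export
simulate_ensemble <- function(n_communities, program, circuit, switch, seed) {
  if (n_communities < 1) {
    abort("`n_communities` must be >= 1.", class = "rhythmsync_error")
  }
  purrr::map_dfr(seq_len(n_communities), function(i) {
    set.seed(stream_seed(seed, i))
    circ_i <- perturb_circuit(circuit, circuit$extrinsic_cv)
    tr <- sim_community_core(program, circ_i, switch)
    tibble(
      time_min = rep(tr$time_min, 2),
      community = community_label(i),
      channel = rep(c("dEGFP", "mCherry"), each = nrow(tr)),
      value = c(tr$degfp, tr$mcherry)
    )
  })
}

#' Simulate a killer/sensitive two-strain consortium
#'
#' The killer strain carries the same switch but produces K1 toxin instead
#' of the reporter: the shared toxin field obeys
#' `dX/dt = toxin_rate * P_killer - toxin_decay_h * X`. Sensitive
#' communities integrate the toxin into a stress variable
#' (`ds/dt = X - s`, 1 h relaxation); a community that is stressed at a
#' cycle onset skips `refractory_cycles` cycles (its switch is held OFF)
#' and responds again on the following cycle, after which stress is
#' re-evaluated. Under sustained toxin this skip/respond alternation
#' yields period doubling of the reporter rhythm. With `toxin_rate = 0`
#' the output reduces element-wise to [simulate_ensemble()] at the same
#' seed.
#'
#' @param n_sensitive Number of sensitive communities.
#' @param circuit_killer Circuit parameters of the killer strain (defaults
#'   to the sensitive circuit).
#' @param toxin A [toxin_params()] object.
#' @inheritParams simulate_community
#'
#' @return A tidy tibble as in [simulate_ensemble()], plus rows with
#'   `community = "killer"`, `channel = "toxin"` carrying the shared toxin
#'   field sampled at `dt_min`.
#' @export
simulate_consortium <- function(program, circuit, switch, toxin,
                                n_sensitive, seed,
                                circuit_killer = circuit) {
  stopifnot(inherits(toxin, "toxin_params"))
  if (n_sensitive < 1) {
    abort("`n_sensitive` must be >= 1.", class = "rhythmsync_error")
  }
  # Killer community (stream 0): switch only, no reporter.
  set.seed(stream_seed(seed, 0))
  circ_k <- perturb_circuit(circuit_killer, circuit_killer$extrinsic_cv)
  killer <- sim_community_core(program, circ_k, switch, with_reporter = FALSE)
  dt_h <- switch$dt_h
  n <- length(killer$state)
  X <- numeric(n)
  s <- numeric(n)
  for (k in 2:n) {
    X[k] <- X[k - 1] +
      dt_h * (toxin$toxin_rate * killer$state[k - 1] -
        toxin$toxin_decay_h * X[k - 1])
    s[k] <- s[k - 1] + dt_h * (X[k - 1] - s[k - 1])
  }
  gate <- stress_gate(s, program, dt_h, toxin)
  traces <- purrr::map_dfr(seq_len(n_sensitive), function(i) {
    set.seed(stream_seed(seed, i))
    circ_i <- perturb_circuit(circuit, circuit$extrinsic_cv)
    tr <- sim_community_core(program, circ_i, switch, gate = gate)
    tibble(
      time_min = rep(tr$time_min, 2),
      community = community_label(i),
      channel = rep(c("dEGFP", "mCherry"), each = nrow(tr)),
      value = c(tr$degfp, tr$mcherry)
    )
  })
  idx <- killer$idx
  bind_rows(
    traces,
    tibble(
      time_min = killer$time_min[idx], community = "killer",
      channel = "toxin", value = X[idx]
    )
  )
}

# Cycle-skipping refractory gate. At each cycle onset: a cycle already
# inside a refractory block stays gated; otherwise, if the community just
# responded and stress exceeds the threshold, the next `refractory_cycles`
# cycles (starting now) are gated; after a refractory block the community
# always responds once before stress is re-evaluated.
stress_gate <- function(s, program, dt_h, toxin) {
  n <- length(s)
  steps_per_cycle <- round(program$period_h / dt_h)
  n_cycles <- floor(program$duration_h / program$period_h + 1e-9)
  gate <- rep(FALSE, n)
  skip <- 0L
  eligible <- FALSE # stress can only trigger right after a responding cycle
  for (cyc in seq_len(n_cycles)) {
    i0 <- (cyc - 1) * steps_per_cycle + 1
    i1 <- min(cyc * steps_per_cycle, n)
    if (skip > 0L) {
      gate[i0:i1] <- TRUE
      skip <- skip - 1L
    } else if (eligible && s[i0] > toxin$stress_threshold) {
      gate[i0:i1] <- TRUE
      skip <- toxin$refractory_cycles - 1L
      eligible <- FALSE
    } else {
      eligible <- TRUE
    }
  }
  if (n_cycles * steps_per_cycle < n) {
    gate[(n_cycles * steps_per_cycle + 1):n] <- FALSE
  }
  gate
}
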