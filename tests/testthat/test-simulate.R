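test_that("a noiseless 10-h rhythm drives one lagged burst per cycle", {
  prog <- input_program(10, 5, duration_h = 50)
  tr <- simulate_community(prog, quiet_circuit(), quiet_switch(), seed = 1)
  pk <- find_peaks(conditioned_trace(tr), tr$time_min, min_prominence = 0.05)
  expect_equal(nrow(pk), 5) # one burst per cycle
  # exhaustive-scan oracle agrees on the burst count
  expect_equal(nrow(pk),
    length(oracle_peak_indices(conditioned_trace(tr))))
  # promoter switches ON after the IAA onset and OFF after the offset
  on_steps <- which(diff(tr$promoter) == 1) + 1
  on_lag_min <- tr$time_min[on_steps] %% 600
  expect_true(all(on_lag_min > 0 & on_lag_min < 300))
  expect_true(all(pk$fwhp > 300)) # bursts outlast the 5-h pulse
})

test_that("zero production yields an identically zero reporter", {
  prog <- input_program(10, 5, duration_h = 20)
  circ <- quiet_circuit(alpha = 0)
  tr <- simulate_community(prog, circ, quiet_switch(), seed = 1)
  expect_true(all(tr$degfp == 0))
})

test_that("burst width matches the closed-form crossing-time analysis", {
  # Single 5-h pulse from rest, zero noise: every stage of the reporter
  # trajectory is piecewise first-order, so the FWHP can be computed from
  # threshold and half-prominence crossing times alone.
  prog <- input_program(20, 5, amplitude_SA = 0, duration_h = 20)
  circ <- quiet_circuit()
  sw <- quiet_switch()
  tr <- simulate_community(prog, circ, sw, seed = 1)
  pk <- find_peaks(tr$degfp, tr$time_min, min_prominence = 0.1)
  expect_equal(nrow(pk), 1)

  # independent closed form (pure arithmetic on the model constants)
  umax <- (1 / circ$ec50_IAA)^2 / (1 + (1 / circ$ec50_IAA)^2)
  th_off <- sw$mid - hysteresis_width(20, sw) / 2
  t_off <- 5 + circ$tau_u_h * log(umax / th_off) # promoter OFF, hours
  delta <- log(2) / circ$reporter_halflife_h + circ$growth_dilution_h
  Ga <- circ$alpha / delta
  Gb <- circ$alpha * circ$basal_frac / delta
  Gp <- Ga - (Ga - Gb) * exp(-delta * t_off)
  G_end <- Gb + (Gp - Gb) * exp(-delta * (20 - t_off))
  prom <- Gp - G_end # right-hand valley is the record end
  level <- Gp - prom / 2
  t_rise <- log((Ga - Gb) / (Ga - level)) / delta
  t_fall <- t_off + log((Gp - Gb) / (level - Gb)) / delta
  fwhp_closed_min <- (t_fall - t_rise) * 60
  expect_equal(pk$fwhp, fwhp_closed_min, tolerance = 5 / fwhp_closed_min)
})

test_that("identical seeds give bit-identical traces and ensembles", {
  prog <- input_program(4, 2, duration_h = 24)
  a <- simulate_community(prog, circuit_params(), switch_params(), seed = 9)
  b <- simulate_community(prog, circuit_params(), switch_params(), seed = 9)
  expect_identical(a, b)
  e1 <- simulate_ensemble(4, prog, circuit_params(), switch_params(), seed = 2)
  e2 <- simulate_ensemble(4, prog, circuit_params(), switch_params(), seed = 2)
  expect_identical(e1, e2)
})

test_that("seed streams are keyed by community index", {
  prog <- input_program(10, 5, duration_h = 20)
  small <- simulate_ensemble(3, prog, circuit_params(), switch_params(),
    seed = 5)
  large <- simulate_ensemble(5, prog, circuit_params(), switch_params(),
    seed = 5)
  expect_identical(small, dplyr::filter(large, community %in%
    c("C01", "C02", "C03")))
})

test_that("without any noise source all communities are identical", {
  prog <- input_program(10, 5, duration_h = 20)
  ens <- simulate_ensemble(5, prog, quiet_circuit(), quiet_switch(), seed = 3)
  wide <- tidyr::pivot_wider(dplyr::filter(ens, channel == "dEGFP"),
    names_from = "community", values_from = "value")
  cols <- as.matrix(wide[, -(1:2)])
  expect_true(all(cols == cols[, 1]))
})

test_that("generated trace sets satisfy the container invariants", {
  set.seed(99)
  for (rep in 1:5) {
    prog <- input_program(
      period_h = sample(c(4, 6, 10), 1),
      duration_h = sample(c(12, 24, 30), 1),
      pulse_width_h = sample(c(1, 2), 1)
    )
    circ <- circuit_params(extrinsic_cv = runif(1, 0, 0.3))
    ens <- simulate_ensemble(sample(2:5, 1), prog, circ, switch_params(),
      seed = rep)
    expect_true(all(ens$value >= 0)) # reporter positivity
    counts <- dplyr::count(ens, community, channel)
    expect_true(all(counts$n == prog$duration_h * 60 / prog$dt_min))
    times <- sort(unique(ens$time_min))
    expect_true(all(diff(times) == prog$dt_min))
  }
})

test_that("an IAA-only rhythm at fast cycles never switches off", {
  # fast-rhythm widening puts theta_off below zero, and without SA the
  # drive never goes negative: the reporter cannot oscillate
  sw <- switch_params(noise_sigma = 0.1)
  expect_lt(switch_thresholds(4, sw)[["theta_off"]], 0)
  prog <- input_program(4, 2, amplitude_SA = 0, duration_h = 48)
  tr <- simulate_community(prog, quiet_circuit(), sw, seed = 4)
  on_idx <- which(tr$promoter == 1)[1]
  expect_true(all(tr$promoter[on_idx:nrow(tr)] == 1))
  expect_equal(sum(abs(diff(tr$promoter[on_idx:nrow(tr)]))), 0)
  # no recurring bursts: at most the one hump of the saturating rise
  pk <- find_peaks(conditioned_trace(tr), tr$time_min, min_prominence = 0.05)
  expect_lte(nrow(pk), 1)
  expect_equal(nrow(compute_periods(
    dplyr::mutate(tibble::tibble(peak_time_min = pk$time), community = "C01")
  )), 0)
})

test_that("faster default rhythms synchronize more tightly than slow ones", {
  drift_at <- function(period_h, seed) {
    prog <- input_program(period_h, period_h / 2, duration_h = 40)
    ens <- simulate_ensemble(14, prog, circuit_params(), switch_params(),
      seed = seed)
    pk <- trace_peaks(smooth_traces(detrend_traces(normalize_traces(ens))),
      min_prominence = 0.05)
    phase_drift(pk, prog)
  }
  fast <- mean(vapply(1:2, function(s) drift_at(4, 40 + s), numeric(1)))
  slow <- mean(vapply(1:2, function(s) drift_at(10, 40 + s), numeric(1)))
  expect_lt(fast, slow)
})
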