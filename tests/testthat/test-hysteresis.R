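test_that("hysteresis width follows the rate-dependent law", {
  sw <- switch_params(h0 = 0.2, kappa = 1.25, T_ref_h = 10)
  expect_equal(hysteresis_width(10, sw), 0.45)
  expect_equal(hysteresis_width(Inf, sw), 0.2)
  # strictly decreasing in the period when kappa > 0
  expect_true(hysteresis_width(2, sw) > hysteresis_width(4, sw))
  expect_true(hysteresis_width(4, sw) > hysteresis_width(10, sw))
  # kappa = 0 recovers a classical fixed hysteresis
  sw0 <- switch_params(h0 = 0.2, kappa = 0)
  expect_equal(hysteresis_width(c(2, 4, 10), sw0), rep(0.2, 3))
  expect_error(hysteresis_width(0, sw), class = "rhythmsync_error")
  th <- switch_thresholds(10, sw)
  expect_equal(unname(th["theta_on"] - th["theta_off"]), 0.45)
  expect_gt(th[["theta_on"]], th[["theta_off"]])
})

test_that("noiseless trajectories equal an exhaustive crossing-scan oracle", {
  sw <- quiet_switch()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(50:300, 1)
    # smoothed random drives that wander through both thresholds
    u <- stats::filter(runif(n, -1.2, 1.2), rep(1 / 5, 5), sides = 1)
    u <- as.numeric(u)
    u[is.na(u)] <- 0
    drv <- tibble::tibble(time_h = (0:(n - 1)) * sw$dt_h, u = as.numeric(u))
    period <- sample(c(2, 4, 10, Inf), 1)
    tr <- simulate_switch(drv, sw, period, seed = rep)
    th <- switch_thresholds(period, sw)
    expect_identical(
      tr$state,
      oracle_schmitt(drv$u, th[["theta_on"]], th[["theta_off"]], sw$mid)
    )
  }
})

test_that("sub-threshold drive never switches and exact hits do not flip", {
  sw <- quiet_switch(mid = 0.3, h0 = 0.4, kappa = 0)
  n <- 500
  drv <- tibble::tibble(
    time_h = (0:(n - 1)) * sw$dt_h,
    u = 0.3 + 0.15 * sin((0:(n - 1)) / 20) # amplitude < h/2 = 0.2
  )
  tr <- simulate_switch(drv, sw, 10, seed = 1)
  expect_equal(sum(abs(diff(tr$state))), 0)
  # landing exactly on a threshold is not a crossing (strict inequality)
  drv2 <- tibble::tibble(time_h = (0:9) * sw$dt_h, u = c(0, rep(0.5, 9)))
  tr2 <- simulate_switch(drv2, sw, 10, seed = 1) # theta_on = 0.5 exactly
  expect_true(all(tr2$state == 0))
})

test_that("mirroring the drive about the midpoint swaps states exactly", {
  sw <- quiet_switch()
  set.seed(7)
  for (rep in 1:10) {
    n <- 300
    u <- as.numeric(stats::filter(runif(n, -1.2, 1.2), rep(0.2, 5), sides = 1))
    u[is.na(u)] <- sw$mid + 0.5
    u[u == sw$mid] <- sw$mid + 1e-6 # avoid exact midpoint ties
    drv <- tibble::tibble(time_h = (0:(n - 1)) * sw$dt_h, u = u)
    mirrored <- drv
    mirrored$u <- 2 * sw$mid - u
    a <- simulate_switch(drv, sw, 4, seed = rep)$state
    b <- simulate_switch(mirrored, sw, 4, seed = rep)$state
    expect_identical(which(diff(a) != 0), which(diff(b) != 0))
    expect_identical(a, 1L - b)
  }
})

test_that("noise-driven switching rate is consistent under step refinement", {
  # Constant drive at the midpoint: switching is purely noise-induced.
  # Euler-Maruyama threshold crossing carries an O(sqrt(dt)) bias, so the
  # rate at dt is compared with a 10x finer reference at a matched band.
  rate_at <- function(dt_h, seed, hours = 300) {
    nsteps <- round(hours / dt_h)
    drv <- tibble::tibble(time_h = (0:(nsteps - 1)) * dt_h, u = 0.325)
    sw <- switch_params(noise_sigma = 0.3, noise_tau_h = 0.5, dt_h = dt_h)
    tr <- simulate_switch(drv, sw, Inf, seed)
    sum(abs(diff(tr$state))) / hours
  }
  coarse <- mean(vapply(1:3, function(s) rate_at(1 / 960, s), numeric(1)))
  fine <- mean(vapply(1:3, function(s) rate_at(1 / 9600, 100 + s), numeric(1)))
  expect_gt(coarse, 0.5)
  expect_lt(abs(coarse - fine) / fine, 0.12)
  # refinement from the default step moves toward the fine reference
  default_dt <- mean(vapply(1:3, function(s) rate_at(1 / 120, 200 + s),
    numeric(1)))
  expect_lt(abs(coarse - fine), abs(default_dt - fine))
})

test_that("too-coarse grids and empty drives are rejected", {
  sw <- switch_params(noise_sigma = 0.3, noise_tau_h = 0.5)
  drv <- tibble::tibble(time_h = (0:10) * 0.5, u = rep(0, 11)) # dt = tau
  expect_error(simulate_switch(drv, sw, 10, seed = 1),
    class = "rhythmsync_error")
  expect_error(
    simulate_switch(tibble::tibble(time_h = numeric(0), u = numeric(0)),
      sw, 10, seed = 1),
    class = "rhythmsync_error"
  )
})
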