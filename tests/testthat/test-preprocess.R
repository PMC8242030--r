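test_that("growth normalization handles the boundary cases", {
  expect_equal(normalize_growth(0, 2), 0)
  expect_equal(normalize_growth(3, 3), 0.5)
  expect_equal(normalize_growth(2, 0), 1)
  expect_equal(normalize_growth(0, 0), 0) # dead ROI reads as no signal
  g <- runif(50, 0, 5)
  m <- runif(50, 0, 5)
  out <- normalize_growth(g, m)
  expect_true(all(out >= 0 & out <= 1))
  # monotone in the reporter at fixed mCherry
  expect_true(all(diff(normalize_growth(seq(0, 5, 0.5), rep(2, 11))) > 0))
  expect_error(normalize_growth(c(1, 2), 1), class = "rhythmsync_error")
  expect_error(normalize_growth(-1, 1), class = "rhythmsync_error")
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- 1:100
  expect_equal(detrend_linear(3 + 0.7 * t), rep(0, 100))
  expect_equal(detrend_linear(rep(5, 100)), rep(0, 100))
  # centered cosine over full periods is orthogonal to the line
  n <- 960
  s <- cos(2 * pi * 8 * (seq_len(n) - (n + 1) / 2) / n)
  out <- detrend_linear(5 + 0.01 * seq_len(n) + s)
  expect_lt(max(abs(out - s)), 1e-8)
  # idempotence
  expect_equal(detrend_linear(out), out, tolerance = 1e-12)
  expect_error(detrend_linear(c(1, 2)), class = "rhythmsync_error")
})

test_that("Savitzky-Golay smoothing is exact on low-degree polynomials", {
  t <- seq(-3, 3, length.out = 101)
  cubic <- 1 + t - 2 * t^2 + 0.5 * t^3
  expect_lt(max(abs(smooth_savgol(cubic, 15, 3) - cubic)), 1e-9)
  expect_equal(smooth_savgol(rep(4, 40), 15, 3), rep(4, 40))
})

test_that("the impulse response equals the least-squares kernel", {
  x <- rep(0, 41)
  x[21] <- 1
  sm <- smooth_savgol(x, 15, 3)
  # response at position 21 + k is the kernel weight the least-squares
  # fit assigns to the impulse sample
  for (k in -5:5) {
    xw <- x[(21 + k - 7):(21 + k + 7)]
    expect_equal(sm[21 + k], oracle_sg_value(xw, 3, 8), tolerance = 1e-9)
  }
})

test_that("smoothing matches the reference implementation away from edges", {
  set.seed(3)
  x <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, 0, 0.1)
  ref <- pracma::savgol(x, 15, forder = 2) # shares the cubic kernel
  expect_equal(smooth_savgol(x, 15, 3)[8:193], ref[8:193], tolerance = 1e-10)
})

test_that("smoothing rejects invalid windows", {
  expect_error(smooth_savgol(1:30, 14), class = "rhythmsync_error")
  expect_error(smooth_savgol(1:10, 15), class = "rhythmsync_error")
  expect_error(smooth_savgol(1:30, 5, 5), class = "rhythmsync_error")
})

test_that("unit rescaling is an exact affine map and idempotent on [0,1]", {
  expect_equal(rescale01(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(rescale01(x), x)
  y <- rescale01(detrend_linear(c(1, 5, 2, 8, 3)))
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(rescale01(rescale01(y)), rescale01(y))
  expect_error(rescale01(rep(1, 5)), class = "rhythmsync_error")
})

test_that("the tidy wrappers condition every community independently", {
  prog <- input_program(10, 5, duration_h = 20)
  ens <- simulate_ensemble(3, prog, circuit_params(), switch_params(),
    seed = 21)
  norm <- normalize_traces(ens)
  expect_true(all(norm$value >= 0 & norm$value <= 1))
  det <- detrend_traces(norm)
  by_comm <- split(det$value, det$community)
  for (v in by_comm) expect_lt(abs(mean(v)), 1e-10)
  # detrend twice equals detrend once
  expect_equal(detrend_traces(det)$value, det$value, tolerance = 1e-12)
  resc <- rescale_traces(smooth_traces(det))
  rng <- tapply(resc$value, resc$community, range)
  for (r in rng) expect_equal(r, c(0, 1))
  # missing channel is a distinct diagnostic
  expect_error(normalize_traces(dplyr::filter(ens, channel == "dEGFP")),
    class = "rhythmsync_error")
})
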