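series_of <- function(x, dt_min = 10, community = "C01") {
  tibble::tibble(
    time_min = (seq_along(x) - 1) * dt_min,
    community = community, value = x
  )
}

test_that("the ACF of a pure cosine has a near-unit maximum at the period", {
  t_h <- seq(0, 47.9, by = 1 / 6)
  x <- cos(2 * pi * t_h / 4)
  a <- cumulative_acf(series_of(x))
  at_T <- a$acf[abs(a$lag_h - 4) < 1e-9]
  expect_gt(at_T, 0.9)
  # local maximum at the period
  near <- a$acf[a$lag_h > 3 & a$lag_h < 5]
  expect_equal(max(near), at_T)
})

test_that("white-noise autocorrelation stays inside the Bartlett band", {
  set.seed(8)
  x <- rnorm(1000)
  a <- cumulative_acf(series_of(x))
  inside <- mean(abs(a$acf[a$lag_h > 0]) < 3 / sqrt(1000))
  expect_gte(inside, 0.99)
})

test_that("a period-doubled burst train moves the ACF maximum to 2T", {
  t_h <- seq(0, 95.9, by = 1 / 6)
  bursts <- rowSums(sapply(seq(2, 94, by = 8), function(c0) {
    exp(-(t_h - c0)^2 / 0.5)
  })) # bursts every 8 h under a 4-h rhythm
  a <- cumulative_acf(series_of(bursts - mean(bursts)))
  peak_lag <- function(center) {
    w <- a[a$lag_h > center - 1 & a$lag_h < center + 1, ]
    max(w$acf)
  }
  expect_gt(peak_lag(8), 0.5)
  expect_gt(peak_lag(8), peak_lag(4) + 0.3)
})

test_that("the periodogram finds the tone and obeys Parseval's identity", {
  t_h <- seq(0, 47.9, by = 1 / 6)
  x <- sin(2 * pi * t_h / 4)
  psd <- power_spectrum(series_of(x))
  expect_equal(dominant_period_h(psd), 4, tolerance = 0.05)
  expect_equal(sum(psd$power), mean((x - mean(x))^2), tolerance = 1e-6)
  set.seed(2)
  y <- rnorm(length(t_h))
  psd_y <- power_spectrum(series_of(y))
  expect_equal(sum(psd_y$power), mean((y - mean(y))^2), tolerance = 1e-6)
  expect_error(power_spectrum(series_of(rep(1, 100))),
    class = "rhythmsync_error")
})

test_that("a stronger subharmonic shifts the dominant period to 2T", {
  t_h <- seq(0, 95.9, by = 1 / 6)
  x <- 0.6 * sin(2 * pi * t_h / 4) + 1.0 * sin(2 * pi * t_h / 8)
  expect_equal(dominant_period_h(power_spectrum(series_of(x))), 8,
    tolerance = 0.05)
})

test_that("ACF and PSD agree on the dominant period of a periodic input", {
  t_h <- seq(0, 71.9, by = 1 / 6)
  set.seed(5)
  x <- sin(2 * pi * t_h / 6)^3 + rnorm(length(t_h), 0, 0.1)
  d <- series_of(x)
  psd_period <- dominant_period_h(power_spectrum(d))
  a <- cumulative_acf(d, max_lag_h = 20)
  pos <- a[a$lag_h > 2, ]
  acf_period <- pos$lag_h[which.max(pos$acf)]
  expect_equal(psd_period, acf_period, tolerance = 0.2 / acf_period)
})

test_that("lags at or beyond the record length are rejected", {
  expect_error(cumulative_acf(series_of(rnorm(100)), max_lag_h = 100),
    class = "rhythmsync_error")
})
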