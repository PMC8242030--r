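prog4 <- input_program(4, 2, duration_h = 40)

test_that("response precision follows the printed formula", {
  expect_equal(response_precision(300, 300), 1.0)
  expect_equal(response_precision(450, 300), 0.8)
  expect_equal(response_precision(900, 300), 0.5)
  # symmetric under exchange and scale-invariant
  expect_equal(response_precision(450, 300), response_precision(300, 450))
  expect_equal(response_precision(450 * 7, 300 * 7),
    response_precision(450, 300))
  expect_error(response_precision(0, 300), class = "rhythmsync_error")
})

test_that("identical peak trains have zero phase drift", {
  pk <- purrr::map_dfr(1:5, function(i) tibble::tibble(
    community = sprintf("C%02d", i),
    peak_time_min = (0:9) * 240 + 30
  ))
  expect_equal(phase_drift(pk, prog4), 0)
})

test_that("phase drift recovers an engineered dispersion and ignores offsets", {
  drifts <- vapply(1:6, function(s) {
    phase_drift(jitter_peak_ensemble(46, prog4, 0.02, seed = s), prog4)
  }, numeric(1))
  expect_equal(mean(drifts), 2, tolerance = 0.25)
  # common offsets shift every community alike and cannot create drift
  base <- jitter_peak_ensemble(46, prog4, 0.02, seed = 1)
  shifted <- dplyr::mutate(base, peak_time_min = peak_time_min + 30)
  expect_equal(phase_drift(shifted, prog4), phase_drift(base, prog4),
    tolerance = 1e-8)
  expect_error(
    phase_drift(tibble::tibble(community = "C01", peak_time_min = 10), prog4),
    class = "rhythmsync_error"
  )
})

test_that("sync fraction counts locked and peakless communities", {
  locked <- purrr::map_dfr(1:8, function(i) tibble::tibble(
    community = sprintf("C%02d", i),
    peak_time_min = (0:9) * 240 + 20
  ))
  expect_equal(sync_fraction(locked, prog4), 1.0)
  # half the communities peakless: they are present in the trace set but
  # contribute no assignable peaks
  half <- dplyr::bind_rows(
    locked,
    purrr::map_dfr(9:16, function(i) tibble::tibble(
      community = sprintf("C%02d", i),
      peak_time_min = -1e6 # far outside every cycle window
    ))
  )
  expect_equal(sync_fraction(half, prog4), 0.5)
})

test_that("doubling ratios snap only within a quarter of the target", {
  pk <- dplyr::bind_rows(
    tibble::tibble(community = "A", peak_time_min = (0:5) * 240),
    tibble::tibble(community = "B", peak_time_min = (0:5) * 240 * 1.9),
    tibble::tibble(community = "C", peak_time_min = (0:5) * 240 * 1.4)
  )
  r <- doubling_ratios(pk, prog4)
  expect_equal(r$ratio_snapped[r$community == "A"], 1)
  expect_equal(r$ratio_snapped[r$community == "B"], 2)
  expect_true(is.na(r$ratio_snapped[r$community == "C"]))
  expect_equal(r$ratio[r$community == "B"], 1.9)
})
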