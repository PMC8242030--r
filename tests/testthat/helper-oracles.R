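# Independent brute-force oracles used across the suite. These deliberately
# re-derive the definitions naively (double loops, exhaustive scans) and
# never call the implementation they check.

# Peak detector by exhaustive scan: O(N * (nups + ndowns)).
oracle_peak_indices <- function(x, nups = 6, ndowns = 6) {
  n <- length(x)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (i - nups < 1 || i + ndowns > n) next
    ok <- TRUE
    for (k in 1:nups) {
      if (x[i - k + 1] < x[i - k]) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      for (k in 1:ndowns) {
        if (x[i + k] > x[i + k - 1]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) hits <- c(hits, i)
  }
  # collapse plateau runs to their first index, as the contract states
  if (length(hits) > 1) hits <- hits[c(TRUE, diff(hits) > 1)]
  hits
}

# Noiseless Schmitt trigger by a literal crossing scan.
oracle_schmitt <- function(u, theta_on, theta_off, mid) {
  state <- integer(length(u))
  s <- as.integer(u[1] > mid)
  state[1] <- s
  for (k in seq_along(u)[-1]) {
    if (s == 0L && u[k] > theta_on) s <- 1L
    if (s == 1L && u[k] < theta_off) s <- 0L
    state[k] <- s
  }
  state
}

# Savitzky-Golay reference: explicit least-squares polynomial fit in one
# window, evaluated at a position.
oracle_sg_value <- function(xw, polyorder, pos) {
  z <- seq_along(xw) - (length(xw) + 1) / 2
  fit <- lm(xw ~ poly(z, polyorder, raw = TRUE))
  unname(predict(fit)[pos])
}

quiet_circuit <- function(...) {
  circuit_params(extrinsic_cv = 0, meas_cv = 0, ...)
}

quiet_switch <- function(...) switch_params(noise_sigma = 0, ...)

# Smoothed growth-normalized signal of a wide single-community trace.
conditioned_trace <- function(tr) {
  smooth_savgol(detrend_linear(normalize_growth(tr$degfp, tr$mcherry)))
}
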