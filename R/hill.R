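#' Four-parameter Hill dose-response curve
#'
#' `response(c) = bottom + (top - bottom) * c^n / (c^n + ec50^n)`,
#' monotone non-decreasing in the concentration, equal to `bottom` at
#' `c = 0` and to the midpoint at `c = ec50`.
#'
#' @param conc Concentrations, micromolar (>= 0).
#' @param bottom,top Lower and upper response asymptotes.
#' @param ec50 Half-maximal concentration, micromolar (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @return Response values.
#' @examples
#' hill_response(0.13, bottom = 0, top = 1, ec50 = 0.13, hill_n = 2)
#' @export
hill_response <- function(conc, bottom = 0, top = 1, ec50, hill_n = 1) {
  if (any(conc < 0)) {
    abort("Concentrations must be non-negative.", class = "rhythmsync_error")
  }
  if (ec50 <= 0 || hill_n <= 0) {
    abort("`ec50` and `hill_n` must be positive.", class = "rhythmsync_error")
  }
  bottom + (top - bottom) * hill_fraction(conc, ec50, hill_n)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the four-parameter Hill model to pooled
#' concentration-response points, with the EC50 and Hill coefficient
#' parameterized on the log scale so the optimizer cannot leave the
#' positive domain. Starting values come from the data: the extreme mean
#' responses for the asymptotes, the geometric midpoint of the positive
#' concentration range for the EC50, and a Hill coefficient of 1.
#' Zero-concentration points enter through the untransformed model (no
#' logarithm of the dose is taken).
#'
#' Flat or non-monotone data, where the fitted dynamic range does not
#' exceed three residual standard deviations, raise a classed fit-failure
#' error rather than returning a silent result.
#'
#' @param data A data frame with a concentration column (micromolar) and a
#'   response column; replicate rows are pooled.
#' @param concentration,response Column names (tidy-select style strings)
#'   holding doses and responses.
#' @return An object of class `hill_fit` with elements `bottom`, `top`,
#'   `ec50`, `hill_n`, `rss`, `se_ec50` and the underlying `nls` fit.
#'   Supports [tidy()], [glance()], [predict()] and [autoplot()].
#' @examples
#' d <- simulate_dose_response(ec50 = 0.13, hill_n = 2, seed = 1)
#' fit <- fit_hill(d)
#' glance(fit)
#' @export
fit_hill <- function(data, concentration = "concentration_uM",
                     response = "response") {
  data <- as_tibble(data)
  if (!all(c(concentration, response) %in% names(data))) {
    abort("Concentration/response columns not found.",
      class = "rhythmsync_error")
  }
  conc <- data[[concentration]]
  resp <- data[[response]]
  if (any(conc < 0) || any(resp < 0)) {
    abort("Concentrations and responses must be non-negative.",
      class = "rhythmsync_error")
  }
  if (length(unique(conc)) < 4) {
    abort("Need at least 4 distinct concentrations.",
      class = "rhythmsync_error")
  }
  if (sd(resp) == 0) {
    abort("All responses are equal; no transition to fit.",
      class = "rhythmsync_hill_failure")
  }
  mean_by_conc <- tapply(resp, conc, mean)
  pos <- conc[conc > 0]
  start <- list(
    bottom = min(mean_by_conc),
    top = max(mean_by_conc),
    lec50 = mean(log(range(pos))),
    lhill = 0
  )
  df <- tibble(conc = conc, resp = resp)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) * conc^exp(lhill) /
        (conc^exp(lhill) + exp(lec50 * exp(lhill))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste("Hill fit did not converge:", conditionMessage(e)),
        class = "rhythmsync_hill_failure")
    }
  )
  cf <- coef(fit)
  sigma <- sqrt(sum(stats::resid(fit)^2) / stats::df.residual(fit))
  if ((cf[["top"]] - cf[["bottom"]]) < 3 * sigma) {
    abort("Fitted dynamic range below 3 residual SDs; data too flat.",
      class = "rhythmsync_hill_failure")
  }
  ec50 <- exp(cf[["lec50"]])
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, 4)
  })
  names(se) <- names(cf)
  structure(
    list(
      bottom = cf[["bottom"]], top = cf[["top"]],
      ec50 = ec50, hill_n = exp(cf[["lhill"]]),
      rss = sum(stats::resid(fit)^2),
      se_ec50 = se[["lec50"]] * ec50, # delta method from the log scale
      nobs = nrow(df), fit = fit, data = df
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> EC50 = %.4g uM (SE %.3g), n = %.3g, range [%.3g, %.3g], RSS = %.3g\n",
    x$ec50, x$se_ec50, x$hill_n, x$bottom, x$top, x$rss
  ))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata
  if (is.data.frame(conc)) conc <- conc[[1]]
  hill_response(conc, object$bottom, object$top, object$ec50, object$hill_n)
}

#' Tidy a Hill fit into a parameter table
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.hill_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(vcov(x$fit))), error = function(e) {
    setNames(rep(NA_real_, 4), c("bottom", "top", "lec50", "lhill"))
  })
  tibble(
    term = c("bottom", "top", "ec50", "hill_n"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill_n),
    std.error = c(
      se[["bottom"]], se[["top"]],
      se[["lec50"]] * x$ec50, se[["lhill"]] * x$hill_n
    )
  )
}

#' One-row summary of a Hill fit
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `ec50`, `se_ec50`, `hill_n`, `bottom`,
#'   `top`, `rss`, `nobs`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(
    ec50 = x$ec50, se_ec50 = x$se_ec50, hill_n = x$hill_n,
    bottom = x$bottom, top = x$top, rss = x$rss, nobs = x$nobs
  )
}

#' Plot a Hill dose-response fit
#'
#' @param object A `hill_fit` object.
#' @param ... Unused.
#' @return A ggplot: data points and the fitted curve on a log dose axis
#'   (zero doses are shown at the left edge).
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  pos <- d$conc[d$conc > 0]
  grid <- exp(seq(log(min(pos) / 3), log(max(pos) * 3), length.out = 200))
  curve <- tibble(conc = grid, resp = predict(object, grid))
  floor_conc <- min(pos) / 3
  d2 <- d %>% mutate(conc_plot = pmax(.data$conc, floor_conc))
  ggplot2::ggplot(d2, ggplot2::aes(x = .data$conc_plot, y = .data$resp)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$conc, y = .data$resp),
      color = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (uM, log scale)", y = "response (a.u.)",
      title = sprintf("EC50 = %.3g uM, Hill n = %.2f", object$ec50,
        object$hill_n)
    ) +
    ggplot2::theme_minimal()
}

#' Simulate a dose-response table
#'
#' Generates replicate measurements from a known Hill curve with
#' multiplicative lognormal noise of the given coefficient of variation.
#' Used for fit-recovery validation.
#'
#' @param concentrations Dose grid, micromolar. The default is 10
#'   log-spaced points spanning two orders of magnitude around `ec50`,
#'   plus a zero dose.
#' @inheritParams hill_response
#' @param cv Measurement coefficient of variation.
#' @param n_replicates Replicates per dose.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration_uM`, `replicate`,
#'   `response`.
#' @export
simulate_dose_response <- function(concentrations = NULL, bottom = 0.05,
                                   top = 1, ec50, hill_n = 2, cv = 0.05,
                                   n_replicates = 3, seed = 1) {
  if (is.null(concentrations)) {
    concentrations <- c(0, ec50 * 10^seq(-1.5, 1.5, length.out = 9))
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    mu <- hill_response(concentrations, bottom, top, ec50, hill_n)
    tibble(
      concentration_uM = concentrations,
      replicate = r,
      response = mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    )
  })
}
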