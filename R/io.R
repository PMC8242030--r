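#' Write a trace set to tidy CSV
#'
#' Columns `time_min`, `community`, `channel`, `value`; UTF-8, header row,
#' `.` decimal separator.
#'
#' @param data A tidy trace tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(data, path) {
  data <- as_tibble(data)
  need <- c("time_min", "community", "channel", "value")
  if (!all(need %in% names(data))) {
    abort("Expected columns time_min, community, channel, value.",
      class = "rhythmsync_error")
  }
  readr::write_csv(data[need], path)
  invisible(path)
}

#' Read and validate a tidy trace CSV
#'
#' Expects columns `time_min`, `community`, `channel`, `value`. Validates
#' that values are non-negative, that every community carries both the
#' `dEGFP` and `mCherry` channels, and that each community/channel series
#' sits on a uniform time grid; each violation raises a distinct
#' diagnostic.
#'
#' @param path CSV path.
#' @return A validated tidy trace tibble.
#' @export
read_traces <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_min", "community", "channel", "value")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("Missing column(s):", paste(missing_cols, collapse = ", ")),
      class = "rhythmsync_io_error")
  }
  if (any(data$value < 0, na.rm = TRUE)) {
    abort("Negative fluorescence values in the trace file.",
      class = "rhythmsync_io_error")
  }
  chans <- data %>%
    filter(.data$channel %in% c("dEGFP", "mCherry")) %>%
    distinct(.data$community, .data$channel) %>%
    group_by(.data$community) %>%
    summarise(n_chan = dplyr::n())
  bad <- chans$community[chans$n_chan < 2]
  if (length(bad) > 0) {
    abort(
      paste0("Community ", paste(bad, collapse = ", "),
        " is missing a dEGFP or mCherry channel."),
      class = "rhythmsync_io_error"
    )
  }
  check_grid <- data %>%
    group_by(.data$community, .data$channel) %>%
    arrange(.data$time_min, .by_group = TRUE)
  grids <- dplyr::group_split(check_grid)
  for (g in grids) {
    dt <- diff(g$time_min)
    if (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1)) {
      row <- which(abs(dt - dt[1]) > 1e-8 * max(dt[1], 1))[1] + 1
      abort(
        sprintf("Non-uniform time grid in community %s (%s) at row %d.",
          g$community[1], g$channel[1], row),
        class = "rhythmsync_io_error"
      )
    }
  }
  as_tibble(data)
}

#' Assemble a resolved pipeline configuration
#'
#' Bundles the stimulation program, circuit, switch and (optionally)
#' toxin parameters together with the metric thresholds, the mandatory
#' seed and the number of communities. All defaults are merged here so a
#' logged configuration fully reconstructs a run.
#'
#' @param program An [input_program()].
#' @param circuit A [circuit_params()] object.
#' @param switch A [switch_params()] object.
#' @param toxin Optional [toxin_params()]; when supplied the run uses the
#'   killer/sensitive consortium mode.
#' @param n_communities Ensemble size.
#' @param seed Mandatory integer seed.
#' @param nups,ndowns,min_prominence Peak-detection settings (see
#'   [find_peaks()]).
#' @param sg_window,sg_polyorder Savitzky-Golay settings (see
#'   [smooth_savgol()]).
#' @param lag_tol_frac [sync_fraction()] lag tolerance as a fraction of
#'   the period.
#' @param cycle_coverage [sync_fraction()] coverage threshold.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(program, circuit = circuit_params(),
                            switch = switch_params(), toxin = NULL,
                            n_communities = 46, seed,
                            nups = 6, ndowns = 6, min_prominence = 0.05,
                            sg_window = 15, sg_polyorder = 3,
                            lag_tol_frac = 0.25, cycle_coverage = 0.9) {
  stopifnot(inherits(program, "input_program"),
    inherits(circuit, "circuit_params"), inherits(switch, "switch_params"))
  if (missing(seed)) {
    abort("A seed is mandatory for any stochastic run.",
      class = "rhythmsync_error")
  }
  if (!is.null(toxin)) stopifnot(inherits(toxin, "toxin_params"))
  structure(
    list(
      program = program, circuit = circuit, switch = switch, toxin = toxin,
      n_communities = n_communities, seed = as.integer(seed),
      nups = nups, ndowns = ndowns, min_prominence = min_prominence,
      sg_window = sg_window, sg_polyorder = sg_polyorder,
      lag_tol_frac = lag_tol_frac, cycle_coverage = cycle_coverage
    ),
    class = "pipeline_config"
  )
}

#' Read a flat key = value configuration file
#'
#' Parses a plain-text configuration with one `key = value` pair per line
#' (`#` starts a comment). Keys are named exactly as the parameter fields
#' of [input_program()], [circuit_params()], [switch_params()] and
#' [toxin_params()], plus the [pipeline_config()] settings (`seed`,
#' `n_communities`, ...). A toxin block is activated by the presence of
#' any toxin field.
#'
#' @param path Path to the configuration file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(sprintf("Malformed config line: '%s'", lines[bad][1]),
      class = "rhythmsync_io_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  parse_val <- function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) {
      return(as.logical(toupper(v)))
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  cfg <- setNames(lapply(vals, parse_val), keys)
  take <- function(fn, required = character(0)) {
    fields <- setdiff(names(formals(fn)), "...")
    args <- cfg[intersect(names(cfg), fields)]
    do.call(fn, args)
  }
  program <- take(input_program)
  circuit <- take(circuit_params)
  sw <- take(switch_params)
  toxin_fields <- names(formals(toxin_params))
  toxin <- if (any(toxin_fields %in% names(cfg))) take(toxin_params) else NULL
  extra <- cfg[intersect(
    names(cfg),
    setdiff(names(formals(pipeline_config)),
      c("program", "circuit", "switch", "toxin"))
  )]
  do.call(pipeline_config, c(
    list(program = program, circuit = circuit, switch = sw, toxin = toxin),
    extra
  ))
}
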