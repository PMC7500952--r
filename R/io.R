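#' Read and write tidy reporter trace tables
#'
#' Traces travel as tidy long CSV with header
#' `cell_id,time_h,channel,value` (the long format accommodates unequal
#' channel cadences).  Reading sorts times within each cell/channel (with a
#' warning if the input was unsorted) and rejects duplicate
#' (cell, channel, time) rows, reporting the offending line numbers.
#' Write-then-read round-trips the table.
#'
#' @param traces data frame with `cell_id`, `time_h`, `channel`, `value`.
#' @param path CSV file path.
#' @return `read_traces()`: the trace data frame; `write_traces()`: the path,
#'   invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("cell_id", "time_h", "channel", "value") %in%
                  names(traces)))
  write.csv(traces[, c("cell_id", "time_h", "channel", "value")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_h", "channel", "value")
  if (!all(need %in% names(tr)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tr$time_h) | !is.numeric(tr$value) |
                 is.na(tr$value))
  if (length(bad))
    stop("malformed trace rows at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  key <- interaction(tr$cell_id, tr$channel, drop = TRUE)
  dup <- duplicated(data.frame(key, tr$time_h))
  if (any(dup))
    stop("duplicate (cell, channel, time) rows at line(s) ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "))
  o <- order(tr$cell_id, tr$channel, tr$time_h)
  if (!identical(o, seq_len(nrow(tr)))) {
    warning("trace rows were not sorted; sorting by cell, channel, time")
    tr <- tr[o, ]
    rownames(tr) <- NULL
  }
  tr
}

#' Read and write delay-sample tables
#'
#' Delay samples travel as CSV with column `delay_h` and an optional
#' `onset_phase_h` column.
#'
#' @param delays numeric vector of delays (h) or data frame with `delay_h`
#'   (and optionally `onset_phase_h`).
#' @param path CSV file path.
#' @return `read_delays()`: data frame with `delay_h` (and `onset_phase_h`
#'   when present); `write_delays()`: the path, invisibly.
#' @export
write_delays <- function(delays, path) {
  if (is.numeric(delays)) delays <- data.frame(delay_h = delays)
  stopifnot("delay_h" %in% names(delays))
  write.csv(delays[, intersect(c("delay_h", "onset_phase_h"),
                               names(delays)), drop = FALSE],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delays
#' @export
read_delays <- function(path) {
  if (!file.exists(path)) stop("delay file not found: ", path)
  d <- read.csv(path)
  if (!"delay_h" %in% names(d))
    stop("delay CSV must have a 'delay_h' column")
  d
}

#' Export a trajectory as tidy CSV
#'
#' Columns `time_h`, `irf9`, `usp18`, `input`.
#'
#' @param trajectory an `ifn_trajectory`.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ifn_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    model = list(k1 = 2000, k2 = 2000, k3 = 10000, k4 = 20, k5 = 50,
                 tau = 8),
    variant = list(positive_feedback = TRUE, negative_feedback = TRUE,
                   usp18_knockdown = FALSE),
    # NB: bare "n"/"on"/"off" are YAML-1.1 booleans, hence the suffixed keys
    program = list(type = "pretreatment", pre = 24, break_h = 8,
                   second = 10, n_pulses = 5, pulse_h = 8, gap_h = 8,
                   on_times = numeric(), off_times = numeric()),
    gating = list(mode = "fixed_delay", tau = 8, T_cycle = 21.82, w = 7.3,
                  t0 = 0),
    noise = list(sigma_irf9 = 250, sigma_usp18 = 1000,
                 convention = "plain_euler"),
    integrator = list(dt = 0.001, t_end = 42, thin = 100),
    cohort = list(n_cells = 400, pre_durations = c(2, 10, 24), break_h = 8,
                  horizon = 34),
    fit = list(taus = 1:20, n_starts = 10, endpoint_weight = 10,
               maxiter = 40),
    generator = list(n_cells = 500, noise_sd = 0),
    analysis = list(window = 5, persist = 3, k_sd = 3, threshold = 10),
    seed = 1,
    out_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with sections `model`, `variant`,
#' `program`, `gating`, `noise`, `integrator`, `cohort`, `fit`, `generator`,
#' `analysis` plus global `seed` and `out_dir`; missing keys are filled from
#' the package defaults (`dt = 0.001`, `n_cells = 400`, ...), unknown keys
#' are rejected with their key path, and basic value constraints are checked
#' with the offending key named.
#'
#' @param path YAML or JSON file path.
#' @return A validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- run_config_defaults()
  unknown_sec <- setdiff(names(cfg), names(defaults))
  if (length(unknown_sec))
    stop("unknown config key(s): ", paste(unknown_sec, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
      if (length(bad))
        stop("unknown config key(s): ",
             paste(paste0(sec, ".", bad), collapse = ", "))
    }
  }
  merged <- modifyList(defaults, cfg)
  # yaml renders empty numeric vectors as [] and reads them back as lists
  for (nm in c("on_times", "off_times"))
    merged$program[[nm]] <- as.numeric(unlist(merged$program[[nm]]))
  merged$fit$taus <- as.numeric(unlist(merged$fit$taus))
  merged$cohort$pre_durations <- as.numeric(unlist(
    merged$cohort$pre_durations))
  chk <- function(cond, key, msg)
    if (!cond) stop(sprintf("config error at '%s': %s", key, msg))
  m <- merged$model
  for (nm in c("k1", "k2", "k3", "k4", "k5", "tau"))
    chk(is.numeric(m[[nm]]) && m[[nm]] >= 0, paste0("model.", nm),
        "must be a non-negative number")
  chk(m$k2 > 0, "model.k2", "must be > 0")
  chk(m$k3 > 0, "model.k3", "must be > 0")
  chk(merged$integrator$dt > 0, "integrator.dt", "must be > 0")
  chk(merged$integrator$t_end > merged$integrator$dt, "integrator.t_end",
      "must exceed dt")
  chk(merged$cohort$n_cells >= 1, "cohort.n_cells", "must be >= 1")
  chk(merged$gating$mode %in% c("fixed_delay", "cell_cycle", "always_on",
                                "never_on"),
      "gating.mode", "unknown gate mode")
  chk(merged$program$type %in% c("intervals", "pretreatment", "pulse"),
      "program.type", "must be intervals, pretreatment or pulse")
  structure(merged, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param config a configuration list (e.g. from [load_run_config()]).
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the input program described by a configuration
#'
#' @param config a `run_config` (or its `program` section).
#' @return An [input_program()].
#' @export
config_program <- function(config) {
  p <- if (!is.null(config$program)) config$program else config
  switch(p$type,
         intervals = input_program(p$on_times, p$off_times),
         pretreatment = pretreatment_program(p$pre, p$break_h, p$second),
         pulse = pulse_program(p$n_pulses, p$pulse_h, p$gap_h),
         stop("unknown program type: ", p$type))
}
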