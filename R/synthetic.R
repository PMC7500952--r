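#' Generate a synthetic dual-reporter single-cell cohort
#'
#' Emulates the statistical structure of a time-lapse dual-reporter imaging
#' experiment on unsynchronized cells treated with interferon at time 0:
#'
#' * per-cell cycle lengths are truncated-normal (mean 21.82 h, SD 2 h by
#'   default, truncated above 4 h), with the treatment onset landing at a
#'   uniform phase of the current cycle;
#' * the IRF9-reporter activation time is lognormal with target mean 7.9 h
#'   and CV 0.556;
#' * the USP18-reporter activation follows after the cell-cycle-gated delay
#'   ([gated_delay()] with the cell's own cycle length) plus a small Gaussian
#'   jitter, floored so it never precedes the IRF9 activation;
#' * each reporter trace is a baseline plus a linear ramp from the activation
#'   time saturating at a plateau, sampled at the channel cadence (20 min for
#'   the IRF9 reporter, 30 min for the USP18 reporter) with additive Gaussian
#'   noise, including a short pre-treatment baseline segment.
#'
#' Ground truth (onset phase, cycle length, activation times, delay) is
#' returned alongside so every downstream quantification can be validated.
#'
#' @param n_cells number of cells.
#' @param seed optional integer seed (fixed seed gives identical cohorts).
#' @param T_mean,T_sd,T_min cycle-length distribution (h): normal mean/SD,
#'   truncated at `T_min`.
#' @param w open-window length (h).
#' @param act_mean,act_cv IRF9 activation-time lognormal target mean (h) and
#'   coefficient of variation.
#' @param jitter_sd SD of the USP18 activation jitter (h).
#' @param irf9_interval,usp18_interval sampling cadences (h) of the two
#'   reporter channels.
#' @param baseline_h pre-treatment baseline duration sampled before time 0
#'   (h).
#' @param t_end trace end time (h).
#' @param noise_sd additive trace noise SD (fluorescence a.u.).
#' @param irf9_baseline,usp18_baseline baseline fluorescence levels.
#' @param irf9_rate,usp18_rate post-activation accumulation rates (a.u./h).
#' @param irf9_sat,usp18_sat accumulation plateaus (a.u. above baseline).
#' @param traces if `FALSE`, skip trace synthesis and return ground truth and
#'   divisions only (fast path for distribution-level checks).
#' @return An object of class `synthetic_cohort`: list with data frames
#'   `truth` (`cell_id`, `onset_phase_h`, `cycle_h`, `act_irf9_h`,
#'   `act_usp18_h`, `delay_h`), `divisions` (`cell_id`,
#'   `division_time_h`) and, unless `traces = FALSE`, `traces` (`cell_id`,
#'   `time_h`, `channel`, `value` with channels `reporter_irf9`,
#'   `reporter_usp18`), plus the configuration.
#' @examples
#' coh <- generate_cohort(5, seed = 1)
#' head(coh$truth)
#' @export
generate_cohort <- function(n_cells, seed = NULL, T_mean = 21.82, T_sd = 2,
                            T_min = 4, w = 7.3, act_mean = 7.9,
                            act_cv = 0.556, jitter_sd = 0.5,
                            irf9_interval = 1 / 3, usp18_interval = 0.5,
                            baseline_h = 2, t_end = 72, noise_sd = 0,
                            irf9_baseline = 100, usp18_baseline = 100,
                            irf9_rate = 1500, usp18_rate = 600,
                            irf9_sat = 30000, usp18_sat = 20000,
                            traces = TRUE) {
  stopifnot(n_cells >= 1, T_mean > 0, T_sd >= 0, w >= 0, act_mean > 0,
            act_cv > 0, jitter_sd >= 0, irf9_interval > 0, usp18_interval > 0,
            irf9_interval < T_mean, usp18_interval < T_mean,
            baseline_h >= 0, t_end > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)

  # truncated-normal cycle lengths by rejection
  cyc <- numeric(n_cells)
  need <- seq_len(n_cells)
  while (length(need)) {
    cyc[need] <- rnorm(length(need), T_mean, T_sd)
    need <- which(cyc <= T_min)
  }
  t0 <- runif(n_cells, 0, cyc)
  delay <- ifelse(t0 < pmin(w, cyc), 0, cyc - t0)

  sdlog <- sqrt(log(1 + act_cv^2))
  meanlog <- log(act_mean) - sdlog^2 / 2
  act_i <- rlnorm(n_cells, meanlog, sdlog)
  act_u <- act_i + pmax(0, delay + rnorm(n_cells, 0, jitter_sd))

  truth <- data.frame(cell_id = seq_len(n_cells), onset_phase_h = t0,
                      cycle_h = cyc, act_irf9_h = act_i, act_usp18_h = act_u,
                      delay_h = delay)
  divisions <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    dv <- seq(-t0[i], t_end, by = cyc[i])
    data.frame(cell_id = i, division_time_h = dv)
  }))

  out <- list(truth = truth, divisions = divisions,
              config = list(n_cells = n_cells, seed = seed, T_mean = T_mean,
                            T_sd = T_sd, T_min = T_min, w = w,
                            act_mean = act_mean, act_cv = act_cv,
                            jitter_sd = jitter_sd,
                            irf9_interval = irf9_interval,
                            usp18_interval = usp18_interval,
                            baseline_h = baseline_h, t_end = t_end,
                            noise_sd = noise_sd))
  if (traces) {
    ramp <- function(t, act, base, rate, sat)
      base + pmin(pmax(t - act, 0) * rate, sat)
    t_i <- seq(-baseline_h, t_end, by = irf9_interval)
    t_u <- seq(-baseline_h, t_end, by = usp18_interval)
    tr <- vector("list", 2L * n_cells)
    for (i in seq_len(n_cells)) {
      vi <- ramp(t_i, act_i[i], irf9_baseline, irf9_rate, irf9_sat)
      vu <- ramp(t_u, act_u[i], usp18_baseline, usp18_rate, usp18_sat)
      if (noise_sd > 0) {
        vi <- vi + rnorm(length(vi), 0, noise_sd)
        vu <- vu + rnorm(length(vu), 0, noise_sd)
      }
      tr[[2L * i - 1L]] <- data.frame(cell_id = i, time_h = t_i,
                                      channel = "reporter_irf9", value = vi)
      tr[[2L * i]] <- data.frame(cell_id = i, time_h = t_u,
                                 channel = "reporter_usp18", value = vu)
    }
    out$traces <- do.call(rbind, tr)
  }
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic dual-reporter cohort: %d cells%s\n", nrow(x$truth),
    if (is.null(x$traces)) " (ground truth only)" else
      sprintf(", %d trace samples", nrow(x$traces))))
  invisible(x)
}

#' Generate a synthetic fitting dataset
#'
#' Simulates the deterministic model with known parameters and delay, samples
#' the sustained-input IRF9 trace at the imaging cadence and computes the
#' pretreatment endpoint inductions (normalized to the 0-h control), with
#' optional multiplicative Gaussian noise (`noise_frac` of each observation's
#' value).  The result is an [ifn_dataset()] ready for [fit_kinetics()],
#' [scan_tau()] and [compare_models_aic()]; the generating parameters are
#' attached as attribute `truth`.
#'
#' @param params generating [ifn_params()].
#' @param tau generating delay (h).
#' @param noise_frac relative noise SD (0 = noiseless).
#' @param seed optional integer seed.
#' @param trace_t_end sustained-trace duration (h).
#' @param trace_interval trace sampling cadence (h); default 20 min.
#' @param pre_durations endpoint pretreatment durations (h), must include 0.
#' @param break_h,second protocol constants (h).
#' @param endpoint_weight endpoint weight, see [ifn_dataset()].
#' @param dt Euler step of the generating simulation (h).
#' @param variant generating [model_variant()].
#' @return An [ifn_dataset()].
#' @export
generate_fitting_dataset <- function(params, tau = 8, noise_frac = 0,
                                     seed = NULL, trace_t_end = 48,
                                     trace_interval = 1 / 3,
                                     pre_durations = c(0, 2, 10, 24),
                                     break_h = 8, second = 10,
                                     endpoint_weight = 10, dt = 0.001,
                                     variant = NULL) {
  params <- as_ifn_params(params)
  stopifnot(noise_frac >= 0, trace_t_end > 0, trace_interval > 0,
            0 %in% pre_durations)
  if (!is.null(seed)) set.seed(seed)
  pol <- gating_policy("fixed_delay", tau = tau)
  times <- seq(0, trace_t_end, by = trace_interval)
  tr <- simulate_pathway(params, input_program(0, trace_t_end + dt),
                         policy = pol, variant = variant,
                         t_end = trace_t_end + dt, dt = dt)
  vals <- trajectory_at(tr, times)$irf9
  pres <- sort(unique(pre_durations))
  ind <- vapply(pres, function(p) {
    prog <- pretreatment_program(p, break_h, second)
    on2 <- p + break_h
    sim <- simulate_pathway(params, prog, policy = pol, variant = variant,
                            t_end = on2 + second, dt = dt)
    st <- trajectory_at(sim, c(on2, on2 + second))
    st$irf9[2] - st$irf9[1]
  }, numeric(1))
  if (noise_frac > 0) {
    vals <- vals * (1 + rnorm(length(vals), 0, noise_frac))
    ind <- ind * (1 + rnorm(length(ind), 0, noise_frac))
  }
  ds <- ifn_dataset(
    trace = data.frame(time_h = times, value = vals),
    endpoints = data.frame(pre_duration_h = pres,
                           induction_norm = ind / ind[pres == 0]),
    endpoint_weight = endpoint_weight, break_h = break_h, second = second)
  attr(ds, "truth") <- list(params = params, tau = tau,
                            noise_frac = noise_frac)
  ds
}
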