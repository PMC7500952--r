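#' Simulate one stochastic single cell
#'
#' One realization of the stochastic model: Euler stepping of the
#' deterministic derivatives plus an additive Gaussian term per step (see
#' [noise_config()] for the two discretization conventions), state clamped
#' at zero.  In the zero-noise limit the trajectory reproduces the
#' deterministic [simulate_pathway()] exactly on the same grid.
#'
#' This is a thin wrapper around [simulate_pathway()] that makes the
#' single-cell intent explicit: the policy is usually a cell-cycle gate with
#' a per-cell onset phase.
#'
#' @inheritParams simulate_pathway
#' @param noise a [noise_config()].
#' @return An `ifn_trajectory`.
#' @examples
#' set.seed(1)
#' pol <- gating_policy("cell_cycle", T_cycle = 21.82, w = 7.3, t0 = 12)
#' tr <- simulate_cell(ifn_params(), pretreatment_program(24, 8, 34),
#'                     policy = pol, noise = noise_config(),
#'                     t_end = 66, dt = 0.01, thin = 10)
#' @export
simulate_cell <- function(params, program, policy, noise = noise_config(),
                          t_end, dt = 0.001, thin = 1L, variant = NULL) {
  simulate_pathway(params, program, policy = policy, variant = variant,
                   t_end = t_end, dt = dt, noise = noise, thin = thin)
}

#' Stochastic pretreatment cohorts
#'
#' Simulates `n_cells` independent single cells per pretreatment condition
#' under the cell-cycle-gated stochastic model and records, per cell, the
#' onset phase, the gate delay of the pretreatment episode, USP18 at the end
#' of the break, and the IRF9 increment from second-input onset to the
#' measurement horizon.  Each cell draws one uniform onset phase at time 0;
#' the phase advances continuously modulo the cycle length, so the second
#' input episode sees the gate state implied by the same draw.
#'
#' Defaults follow the reference protocol: pretreatments of 2, 10 and 24 h,
#' an 8-h break, a sustained second input measured 34 h after its onset, 400
#' cells per condition, noise scales 250 (IRF9) and 1000 (USP18).
#'
#' @param params an [ifn_params()].
#' @param pre_durations pretreatment durations (h), non-empty.
#' @param n_cells cells per condition.
#' @param gating list or [gating_policy()] giving `T_cycle` and `w` of the
#'   cell-cycle gate (the per-cell onset phase is drawn internally).
#' @param noise a [noise_config()], or `NULL` for a noise-free cohort.
#' @param break_h break duration (h).
#' @param second second-input duration (h); by default equal to `horizon`.
#' @param horizon measurement horizon after second-input onset (h).
#' @param dt Euler step (h).
#' @param seed optional integer seed.
#' @param variant a [model_variant()].
#' @return An object of class `ifn_cohort`: list with `cells` (data frame:
#'   `condition`, `cell_id`, `onset_phase_h`, `delay_h`, `usp18_end_break`,
#'   `irf9_induction`) and the configuration used.
#' @examples
#' coh <- simulate_cohort(ifn_params(), n_cells = 20, dt = 0.01, seed = 1)
#' summary(coh)
#' @export
simulate_cohort <- function(params, pre_durations = c(2, 10, 24),
                            n_cells = 400,
                            gating = list(T_cycle = 21.82, w = 7.3),
                            noise = noise_config(), break_h = 8,
                            second = NULL, horizon = 34, dt = 0.001,
                            seed = NULL, variant = NULL) {
  params <- as_ifn_params(params)
  stopifnot(length(pre_durations) >= 1, n_cells >= 1)
  if (inherits(gating, "gating_policy"))
    gating <- list(T_cycle = gating$T_cycle, w = gating$w)
  T_cycle <- gating$T_cycle; w <- gating$w
  if (is.null(second)) second <- horizon
  stopifnot(horizon >= 0, second >= 0, second <= horizon + 1e-9)
  if (!is.null(seed)) set.seed(seed)

  thin <- max(1L, as.integer(round(0.1 / dt)))
  rows <- vector("list", length(pre_durations) * n_cells)
  k <- 0L
  for (pre in pre_durations) {
    prog <- pretreatment_program(pre, break_h, second)
    on2 <- pre + break_h
    t_end <- on2 + horizon
    phases <- runif(n_cells, 0, T_cycle)
    for (i in seq_len(n_cells)) {
      pol <- gating_policy("cell_cycle", T_cycle = T_cycle, w = w,
                           t0 = phases[i])
      tr <- simulate_pathway(params, prog, policy = pol, variant = variant,
                             t_end = t_end, dt = dt, noise = noise,
                             thin = thin)
      st <- trajectory_at(tr, c(on2, on2 + horizon))
      u_break <- trajectory_at(tr, on2)$usp18
      k <- k + 1L
      rows[[k]] <- data.frame(
        condition = sprintf("pre_%gh", pre), cell_id = i,
        onset_phase_h = phases[i],
        delay_h = gated_delay(phases[i], T_cycle, w),
        usp18_end_break = u_break,
        irf9_induction = st$irf9[2] - st$irf9[1])
    }
  }
  structure(list(cells = do.call(rbind, rows),
                 pre_durations = pre_durations, n_cells = n_cells,
                 gating = list(T_cycle = T_cycle, w = w), noise = noise,
                 break_h = break_h, second = second, horizon = horizon,
                 dt = dt, seed = seed),
            class = "ifn_cohort")
}

#' @export
print.ifn_cohort <- function(x, ...) {
  cat(sprintf(
    "Stochastic cohort: %d cells x %d condition(s) (%s h pretreatment)\n",
    x$n_cells, length(x$pre_durations),
    paste(x$pre_durations, collapse = "/")))
  invisible(x)
}

#' Cohort summary statistics
#'
#' Per-condition means and coefficients of variation (CV = SD/mean) of USP18
#' at the end of the break and of IRF9 induction by the second input, plus
#' the pooled Pearson correlation between the two across all conditions.
#' A CV whose mean is not positive is flagged as `NA` (undefined) rather
#' than propagated.
#'
#' @param object an `ifn_cohort`.
#' @param ... unused.
#' @return An object of class `ifn_cohort_summary`: list with `by_condition`
#'   (data frame) and `pooled_correlation`.
#' @export
summary.ifn_cohort <- function(object, ...) {
  cells <- object$cells
  conds <- unique(cells$condition)
  cv <- function(v) {
    m <- mean(v)
    if (!(m > 0)) return(NA_real_)
    sd(v) / m
  }
  by_cond <- do.call(rbind, lapply(conds, function(cc) {
    s <- cells[cells$condition == cc, ]
    data.frame(condition = cc, n = nrow(s),
               mean_usp18 = mean(s$usp18_end_break),
               cv_usp18 = cv(s$usp18_end_break),
               mean_irf9_induction = mean(s$irf9_induction),
               cv_irf9_induction = cv(s$irf9_induction))
  }))
  pooled <- if (nrow(cells) >= 3 && sd(cells$usp18_end_break) > 0 &&
                sd(cells$irf9_induction) > 0)
    cor(cells$usp18_end_break, cells$irf9_induction)
  else NA_real_
  structure(list(by_condition = by_cond, pooled_correlation = pooled),
            class = "ifn_cohort_summary")
}

#' @export
print.ifn_cohort_summary <- function(x, ...) {
  cat("Cohort summary (per condition):\n")
  print(x$by_condition, row.names = FALSE, digits = 4)
  cat(sprintf(
    "Pooled Pearson correlation (USP18 end-of-break vs IRF9 induction): %.3f\n",
    x$pooled_correlation))
  invisible(x)
}

#' @export
plot.ifn_cohort <- function(x, ...) {
  cells <- x$cells
  conds <- unique(cells$condition)
  cols <- grDevices::hcl.colors(length(conds), "Dark 3")
  graphics::plot(cells$usp18_end_break, cells$irf9_induction,
                 col = cols[match(cells$condition, conds)], pch = 1,
                 xlab = "USP18 at end of break (a.u.)",
                 ylab = "IRF9 induction by second input (a.u.)", ...)
  graphics::legend("topright", legend = conds, col = cols, pch = 1, bty = "n")
  invisible(x)
}

#' Write cohort records and summary to disk
#'
#' Writes `cells.csv` (per-cell records), `summary.json` (per-condition CVs
#' and the pooled correlation) and `provenance.json` (seed, package version,
#' configuration) into `dir`.
#'
#' @param cohort an `ifn_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ifn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  s <- summary(cohort)
  jsonlite::write_json(
    list(by_condition = s$by_condition,
         pooled_correlation = s$pooled_correlation),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(
    list(package = "ifngate",
         version = as.character(packageVersion("ifngate")),
         seed = cohort$seed, n_cells = cohort$n_cells,
         pre_durations = cohort$pre_durations, gating = cohort$gating,
         noise = unclass(cohort$noise), dt = cohort$dt,
         break_h = cohort$break_h, horizon = cohort$horizon),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
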