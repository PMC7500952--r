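#' Gating policies for delayed USP18 induction
#'
#' The stepwise gate `Su(t)` multiplies USP18 production.  Four modes:
#'
#' * `"fixed_delay"`: `Su = 1` once the continuous exposure of the current ON
#'   episode reaches `tau` hours (closed boundary: exposure `>= tau`).
#' * `"cell_cycle"`: each ON episode draws its delay from the cell-cycle
#'   phase at that episode's onset — zero inside the open window, otherwise
#'   the waiting time to the next cycle start (see [gated_delay()]).  The
#'   phase advances continuously modulo `T` from the onset phase `t0`.
#' * `"always_on"`: `Su` identically 1.
#' * `"never_on"`: `Su` identically 0 (USP18-knockdown surrogate at the gate
#'   level).
#'
#' @param mode gate mode, one of `"fixed_delay"`, `"cell_cycle"`,
#'   `"always_on"`, `"never_on"`.
#' @param tau fixed delay (h), used in `"fixed_delay"` mode.
#' @param T_cycle full cell-cycle length (h), `"cell_cycle"` mode.
#' @param w open-window length (h), `0 <= w <= T_cycle`.
#' @param t0 cell-cycle phase at time 0 (h into the cycle), `0 <= t0 <
#'   T_cycle`.
#' @return An object of class `gating_policy`.
#' @examples
#' gating_policy("fixed_delay", tau = 8)
#' gating_policy("cell_cycle", T_cycle = 21.82, w = 7.3, t0 = 10)
#' @export
gating_policy <- function(mode = c("fixed_delay", "cell_cycle", "always_on",
                                   "never_on"),
                          tau = 8, T_cycle = 21.82, w = 7.3, t0 = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(tau), tau >= 0)
  if (mode == "cell_cycle") {
    if (!(T_cycle > 0)) stop("'T_cycle' must be > 0")
    if (w < 0 || w > T_cycle) stop("need 0 <= w <= T_cycle")
    if (t0 < 0 || t0 >= T_cycle) stop("need 0 <= t0 < T_cycle")
  }
  structure(list(mode = mode, tau = tau, T_cycle = T_cycle, w = w, t0 = t0),
            class = "gating_policy")
}

#' @export
print.gating_policy <- function(x, ...) {
  cat("Su gating policy:", x$mode, "\n")
  if (x$mode == "fixed_delay") cat(sprintf("  tau = %g h\n", x$tau))
  if (x$mode == "cell_cycle")
    cat(sprintf("  cycle T = %g h, window w = %g h, onset phase t0 = %g h\n",
                x$T_cycle, x$w, x$t0))
  invisible(x)
}

as_gating_policy <- function(x) {
  if (is.null(x)) return(gating_policy("fixed_delay"))
  if (inherits(x, "gating_policy")) return(x)
  if (is.list(x)) return(do.call(gating_policy, x))
  stop("cannot interpret 'policy'; use gating_policy()")
}

# per-episode gate delay implied by a policy (vectorized over episodes)
episode_delays <- function(policy, on_times) {
  switch(policy$mode,
         always_on = rep(0, length(on_times)),
         never_on = rep(Inf, length(on_times)),
         fixed_delay = rep(policy$tau, length(on_times)),
         cell_cycle = {
           ph <- (policy$t0 + on_times) %% policy$T_cycle
           ifelse(ph < policy$w, 0, policy$T_cycle - ph)
         })
}

#' Evaluate the Su gate
#'
#' Returns the 0/1 value of the stepwise gate at times `t` for a given input
#' program and policy: 1 iff the input is ON at `t` and the continuous
#' exposure of the current ON episode has reached that episode's delay.
#'
#' @param policy a [gating_policy()].
#' @param program an [input_program()].
#' @param t time(s) in hours (vectorized).
#' @return Integer 0/1 vector.
#' @examples
#' pol <- gating_policy("fixed_delay", tau = 8)
#' su_at(pol, input_program(0, 24), c(7.9, 8, 20))  # 0 1 1
#' @export
su_at <- function(policy, program, t) {
  policy <- as_gating_policy(policy)
  program <- as_input_program(program)
  stopifnot(is.numeric(t), all(t >= 0))
  res <- integer(length(t))
  if (nrow(program) == 0L) return(res)
  del <- episode_delays(policy, program[, "on"])
  for (i in seq_len(nrow(program))) {
    inside <- t >= program[i, "on"] & t < program[i, "off"]
    res[inside & (t - program[i, "on"] >= del[i])] <- 1L
  }
  res
}

#' Cell-cycle-gated delay of USP18 induction
#'
#' A cell at phase `t0` of its cycle (phase 0 = division) when a continuous
#' interferon input starts induces USP18 immediately if `t0` falls inside the
#' half-open open window `[0, w)`; otherwise induction waits for the window
#' to reopen at the next cycle start, giving a delay of `T - t0` hours.
#'
#' @param t0 onset phase(s), hours into the cycle, `0 <= t0 < T` (vectorized).
#' @param T_cycle full cycle length (h); the reference estimate is 21.82 h.
#' @param w open-window length (h); the reference estimate is 7.3 h.
#' @return Delay(s) in hours.
#' @examples
#' gated_delay(c(3, 10), T_cycle = 21.82, w = 7.3)  # 0, 11.82
#' @export
gated_delay <- function(t0, T_cycle = 21.82, w = 7.3) {
  stopifnot(is.numeric(t0), T_cycle > 0, w >= 0, w <= T_cycle)
  if (any(t0 < 0 | t0 >= T_cycle))
    stop("onset phase 't0' must lie in [0, T_cycle)")
  ifelse(t0 < w, 0, T_cycle - t0)
}

#' Sample uniform treatment-onset phases
#'
#' Onset phases of unsynchronized cells at treatment time are uniform over
#' the cycle `[0, T)`.
#'
#' @param n number of cells.
#' @param T_cycle cycle length (h).
#' @param seed optional integer seed (`set.seed()` is called when given).
#' @return Numeric vector of `n` phases in `[0, T_cycle)`.
#' @export
sample_onset_phases <- function(n, T_cycle = 21.82, seed = NULL) {
  stopifnot(is.numeric(n), n >= 1, T_cycle > 0)
  if (!is.null(seed)) set.seed(seed)
  runif(n, 0, T_cycle)
}

#' Analytic delay distribution under uniform onset phases
#'
#' With onset phase uniform on `[0, T)` and the gate of [gated_delay()], the
#' delay is 0 with probability `w/T` and otherwise uniform on `(0, T - w]`:
#' survival `P(delay > d) = (T - w - d)/T` for `0 <= d < T - w` and 0 beyond;
#' CDF `P(delay <= d) = (w + d)/T` on `[0, T - w)`; mean `(T - w)^2 / (2T)`.
#'
#' @param d delay value(s) in hours, `>= 0` (vectorized).
#' @param T_cycle cycle length (h).
#' @param w open-window length (h).
#' @return Probabilities (`delay_survival`, `delay_cdf`) or hours
#'   (`mean_gated_delay`).
#' @examples
#' delay_survival(10, 21.82, 7.3)  # ~0.207: the long-delay (Group-2) mass
#' mean_gated_delay(21.82, 7.3)    # ~4.83 h
#' @export
delay_survival <- function(d, T_cycle = 21.82, w = 7.3) {
  stopifnot(is.numeric(d), all(d >= 0), T_cycle > 0, w >= 0, w <= T_cycle)
  pmax(0, (T_cycle - w - d) / T_cycle)
}

#' @rdname delay_survival
#' @export
delay_cdf <- function(d, T_cycle = 21.82, w = 7.3) {
  1 - delay_survival(d, T_cycle, w)
}

#' @rdname delay_survival
#' @export
mean_gated_delay <- function(T_cycle = 21.82, w = 7.3) {
  stopifnot(T_cycle > 0, w >= 0, w <= T_cycle)
  (T_cycle - w)^2 / (2 * T_cycle)
}

#' Fit the open-window length to observed delay times
#'
#' Grid search for the window length `w` whose analytic delay CDF (see
#' [delay_cdf()]) is closest to the empirical CDF of the observed delays, in
#' the sup norm (Kolmogorov–Smirnov distance).  The grid runs over
#' `[0, T_cycle]` with step `grid_step`; ties are broken toward smaller `w`.
#'
#' @param delays observed delay times (h), within `[0, T_cycle]`; at least 20
#'   values are required for a meaningful fit.
#' @param T_cycle full cycle length (h), held fixed.
#' @param grid_step grid resolution for `w` (h).
#' @return An object of class `window_fit`: list with elements `w` (the
#'   estimate), `distance` (sup-norm CDF distance at the optimum), `T_cycle`,
#'   `grid_step`, `n`.
#' @examples
#' set.seed(1)
#' d <- gated_delay(runif(500, 0, 21.82))
#' fit_window(d)$w
#' @export
fit_window <- function(delays, T_cycle = 21.82, grid_step = 0.01) {
  stopifnot(is.numeric(delays), T_cycle > 0, grid_step > 0)
  if (length(delays) == 0L) stop("'delays' must not be empty")
  if (length(delays) < 20L)
    warning("fewer than 20 delay samples; the window estimate is unstable")
  if (any(delays < 0 | delays > T_cycle))
    stop("delays must lie within [0, T_cycle]")
  n <- length(delays)
  vals <- sort(unique(delays))
  f_hat <- cumsum(as.numeric(table(factor(delays, levels = vals)))) / n
  f_prev <- c(0, f_hat[-length(f_hat)])
  grid <- seq(0, T_cycle, by = grid_step)
  # sup |F_hat - F_w| over the empirical jump points, comparing the model CDF
  # from the right (its value) and from the left (its left limit: 0 at d = 0
  # because of the atom, continuous elsewhere)
  best_w <- 0; best_dist <- Inf
  for (w in grid) {
    f_mod <- pmin(1, (w + vals) / T_cycle)
    f_mod_left <- ifelse(vals <= 0, 0, f_mod)
    dist <- max(abs(f_mod - f_hat), abs(f_mod_left - f_prev))
    if (dist < best_dist - 1e-12) {
      best_dist <- dist; best_w <- w
    }
  }
  structure(list(w = best_w, distance = best_dist, T_cycle = T_cycle,
                 grid_step = grid_step, n = n),
            class = "window_fit")
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf(
    "Open-window fit: w = %g h (cycle T = %g h, n = %d, KS distance %.4f)\n",
    x$w, x$T_cycle, x$n, x$distance))
  invisible(x)
}

#' Fraction of delays exceeding a threshold
#'
#' The long-delay subpopulation fraction: delays strictly greater than the
#' threshold (10 h by convention separates Group 2 from Group 1).
#'
#' @param delays delay times (h).
#' @param threshold threshold (h), `>= 0`.
#' @return A single fraction in `[0, 1]`.
#' @examples
#' group_fraction_above(c(0, 0, 12), 10)  # 1/3
#' @export
group_fraction_above <- function(delays, threshold = 10) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  if (length(delays) == 0L) stop("'delays' must not be empty")
  mean(delays > threshold)
}
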