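#' Feedback functions of the kinetic model
#'
#' `positive_feedback()` is the saturating IRF9 drive
#' `pf = k1 * IRF9 / (k2 + IRF9)` (a rate in concentration/h, bounded by
#' `k1`).  `negative_feedback()` is the USP18 inhibition factor
#' `nf = k3 / (k3 + USP18)` (dimensionless, in `(0, 1]`).  Their product
#' `pf * nf` is the feedback-modulated production drive shared by both
#' species.
#'
#' @param irf9,usp18 non-negative concentrations (vectorized).
#' @param params an [ifn_params()] object.
#' @return Numeric vector of rates (`positive_feedback`) or dimensionless
#'   factors (`negative_feedback`).
#' @examples
#' p <- ifn_params(k1 = 10, k2 = 4, k3 = 5)
#' positive_feedback(c(0, 4, 36), p)  # 0, 5, 9
#' negative_feedback(c(0, 5, 495), p) # 1, 0.5, 0.01
#' @export
positive_feedback <- function(irf9, params) {
  params <- as_ifn_params(params)
  stopifnot(is.numeric(irf9))
  if (any(irf9 < 0)) stop("'irf9' must be non-negative")
  params$k1 * irf9 / (params$k2 + irf9)
}

#' @rdname positive_feedback
#' @export
negative_feedback <- function(usp18, params) {
  params <- as_ifn_params(params)
  stopifnot(is.numeric(usp18))
  if (any(usp18 < 0)) stop("'usp18' must be non-negative")
  params$k3 / (params$k3 + usp18)
}

#' Right-hand side of the model ODEs
#'
#' Evaluates the time derivatives of induced IRF9 and USP18 at state
#' `(irf9, usp18)` and time `t`:
#' `dIRF9/dt = I(t) * (k4 + pf * nf)` and
#' `dUSP18/dt = I(t) * Su(t) * (k5 + pf * nf)`, where `I` is the binary input
#' program and `Su` the delay gate.  Production is fully gated by the input
#' (and, for USP18, by `Su`); the model has no decay terms, so with the input
#' off both derivatives are exactly zero.  Variant ablations follow
#' [model_variant()].
#'
#' @param irf9,usp18 current state (non-negative concentrations).
#' @param t time (h).
#' @param params an [ifn_params()].
#' @param program an [input_program()].
#' @param policy a [gating_policy()]; default fixed delay with `params$tau`.
#' @param variant a [model_variant()]; default full model.
#' @param grouping `"gated"` keeps all production under `I(t)` (default);
#'   `"ungated"` is the alternative algebraic reading
#'   `I*k4 + pf*nf` / `I*Su*k5 + pf*nf`, exposed for sensitivity checks.
#' @return Named numeric vector `c(dirf9, dusp18)` (concentration/h).
#' @examples
#' p <- ifn_params()
#' ifn_derivatives(p$k2, 0, t = 9, p, input_program(0, 24))
#' @export
ifn_derivatives <- function(irf9, usp18, t, params, program, policy = NULL,
                            variant = NULL,
                            grouping = c("gated", "ungated")) {
  params <- as_ifn_params(params)
  program <- as_input_program(program)
  variant <- as_ifn_variant(variant)
  grouping <- match.arg(grouping)
  if (is.null(policy)) policy <- gating_policy("fixed_delay", tau = params$tau)
  policy <- as_gating_policy(policy)
  stopifnot(irf9 >= 0, usp18 >= 0, t >= 0)
  if (variant$usp18_knockdown) usp18 <- 0
  I <- input_at(program, t)
  Su <- su_at(policy, program, t)
  pf <- if (variant$positive_feedback) positive_feedback(irf9, params)
        else params$k1
  nf <- if (variant$negative_feedback && !variant$usp18_knockdown)
          negative_feedback(usp18, params) else 1
  drive <- pf * nf
  if (grouping == "gated") {
    d_irf9 <- I * (params$k4 + drive)
    d_usp18 <- I * Su * (params$k5 + drive)
  } else {
    d_irf9 <- I * params$k4 + drive
    d_usp18 <- I * Su * params$k5 + drive
  }
  if (variant$usp18_knockdown) d_usp18 <- 0
  c(dirf9 = d_irf9, dusp18 = d_usp18)
}

#' Simulate the deterministic or stochastic model
#'
#' Forward-Euler integration of the two-species model from state
#' `(irf9_0, usp18_0)` on the grid `0, dt, ..., t_end`.  With a
#' [noise_config()] supplied, an additive Gaussian term per step turns the
#' run into one realization of the stochastic single-cell model; the state
#' is clamped at zero after every step.  Without noise the scheme is the
#' plain Euler method and both series are non-negative and non-decreasing.
#'
#' @inheritParams ifn_derivatives
#' @param t_end end time (h), > 0.
#' @param dt Euler step (h); default 0.001.
#' @param noise `NULL` for the deterministic model, or a [noise_config()].
#' @param thin record every `thin`-th step (default 1: the full grid).
#' @param irf9_0,usp18_0 initial state; default `(0, 0)` (induction above
#'   baseline).
#' @return An object of class `ifn_trajectory`: a data frame with columns
#'   `time_h`, `irf9`, `usp18`, `input`, carrying the program, policy,
#'   variant and step size as attributes.
#' @examples
#' tr <- simulate_pathway(ifn_params(), pretreatment_program(24, 8, 10),
#'                        t_end = 42, thin = 100)
#' head(as.data.frame(tr))
#' @export
simulate_pathway <- function(params, program, policy = NULL, variant = NULL,
                             t_end, dt = 0.001, noise = NULL, thin = 1L,
                             irf9_0 = 0, usp18_0 = 0,
                             grouping = c("gated", "ungated")) {
  params <- as_ifn_params(params)
  program <- as_input_program(program)
  variant <- as_ifn_variant(variant)
  grouping <- match.arg(grouping)
  if (is.null(policy)) policy <- gating_policy("fixed_delay", tau = params$tau)
  policy <- as_gating_policy(policy)
  stopifnot(is.numeric(t_end), t_end > 0, is.numeric(dt), dt > 0)
  if (dt >= t_end) stop("'dt' must be smaller than 't_end'")
  thin <- as.integer(thin)
  stopifnot(thin >= 1L)
  stopifnot(irf9_0 >= 0, usp18_0 >= 0)

  gate_mode <- match(policy$mode,
                     c("always_on", "never_on", "fixed_delay", "cell_cycle")) -
    1L
  with_noise <- !is.null(noise)
  if (with_noise && !inherits(noise, "noise_config"))
    stop("'noise' must be a noise_config() or NULL")
  res <- euler_integrate_cpp(
    params$k1, params$k2, params$k3, params$k4, params$k5,
    program[, "on"], program[, "off"],
    gate_mode, policy$tau, policy$T_cycle, policy$w, policy$t0,
    variant$positive_feedback, variant$negative_feedback,
    variant$usp18_knockdown, grouping == "gated",
    t_end, dt, thin, irf9_0, usp18_0,
    if (with_noise) noise$sigma_irf9 else 0,
    if (with_noise) noise$sigma_usp18 else 0,
    with_noise && noise$convention == "euler_maruyama",
    with_noise)
  out <- data.frame(time_h = res$time_h, irf9 = res$irf9,
                    usp18 = res$usp18, input = res$input)
  structure(out, class = c("ifn_trajectory", "data.frame"),
            params = params, program = program, policy = policy,
            variant = variant, dt = dt, noise = if (with_noise) noise)
}

#' @export
print.ifn_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "Model trajectory: %d points over [0, %g] h (dt = %g%s)\n",
    n, x$time_h[n], attr(x, "dt"),
    if (is.null(attr(x, "noise"))) "" else ", stochastic"))
  cat(sprintf("  final IRF9 = %.4g, final USP18 = %.4g\n",
              x$irf9[n], x$usp18[n]))
  invisible(x)
}

#' @export
plot.ifn_trajectory <- function(x, ...) {
  old <- graphics::par(mar = c(4, 4, 1.5, 4))
  on.exit(graphics::par(old))
  graphics::plot(x$time_h, x$irf9, type = "l", col = "darkorange",
                 xlab = "time (h)", ylab = "IRF9 (a.u.)", ...)
  graphics::lines(x$time_h, x$usp18 * max(1e-12, max(x$irf9)) /
                    max(1e-12, max(x$usp18)), col = "steelblue")
  graphics::axis(4, at = pretty(c(0, max(x$irf9))),
                 labels = signif(pretty(c(0, max(x$irf9))) *
                                   max(1e-12, max(x$usp18)) /
                                   max(1e-12, max(x$irf9)), 2))
  graphics::mtext("USP18 (a.u.)", side = 4, line = 2.5)
  rug_on <- attr(x, "program")
  if (nrow(rug_on) > 0)
    graphics::segments(rug_on[, "on"], 0, rug_on[, "off"], 0, lwd = 4,
                       col = "grey40")
  invisible(x)
}

# state at arbitrary times, by nearest grid index
trajectory_at <- function(traj, times) {
  step <- traj$time_h[2] - traj$time_h[1]
  idx <- pmin(nrow(traj), pmax(1L, as.integer(round(times / step)) + 1L))
  traj[idx, c("irf9", "usp18")]
}

#' Induction between two pretreatment protocols
#'
#' Convenience wrapper: deterministic induced IRF9 over the second input of
#' the pretreatment protocol, normalized to the no-pretreatment control.
#'
#' @param params an [ifn_params()].
#' @param pre_durations pretreatment durations (h); 0 is the control and is
#'   always added.
#' @param break_h break between inputs (h).
#' @param second second-input duration (h).
#' @param dt Euler step (h).
#' @param ... passed to [simulate_pathway()] (e.g. `variant`, `policy`).
#' @return Named vector of control-normalized inductions, one per
#'   pretreatment duration (control itself equals 1).
#' @examples
#' normalized_induction(ifn_params(), c(2, 24), dt = 0.01)
#' @export
normalized_induction <- function(params, pre_durations = c(2, 10, 24),
                                 break_h = 8, second = 10, dt = 0.001, ...) {
  params <- as_ifn_params(params)
  pres <- sort(unique(c(0, pre_durations)))
  ind <- vapply(pres, function(p) {
    prog <- pretreatment_program(p, break_h, second)
    on2 <- p + break_h
    tr <- simulate_pathway(params, prog, t_end = on2 + second, dt = dt,
                           thin = max(1L, as.integer(round(0.1 / dt))), ...)
    st <- trajectory_at(tr, c(on2, on2 + second))
    st$irf9[2] - st$irf9[1]
  }, numeric(1))
  names(ind) <- paste0("pre_", pres, "h")
  ctrl <- ind[["pre_0h"]]
  if (!(ctrl > 0)) stop("control induction is not positive; cannot normalize")
  out <- ind / ctrl
  out[match(paste0("pre_", pre_durations, "h"), names(out))]
}
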