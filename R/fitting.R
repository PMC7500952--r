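#' Fitting dataset: reporter trace plus pretreatment endpoints
#'
#' Observations used for parameter estimation: a time trace of the
#' IRF9-reporter under sustained input (`trace`: columns `time_h`, `value`)
#' and endpoint inductions for the pretreatment protocol (`endpoints`:
#' columns `pre_duration_h`, `induction_norm`), where inductions are
#' normalized to the no-pretreatment control.  Endpoints carry a higher
#' weight than individual trace points (fits lean on the condition endpoints;
#' the simple model cannot reproduce every feature of the dynamic trace).
#' Trace residuals are additionally rescaled by the mean trace value so the
#' two observation blocks live on comparable scales.
#'
#' @param trace data frame with `time_h`, `value`.
#' @param endpoints data frame with `pre_duration_h`, `induction_norm`.
#' @param endpoint_weight weight of one endpoint observation relative to one
#'   (rescaled) trace observation; default 10.
#' @param break_h,second protocol constants of the endpoint conditions (h).
#' @return An object of class `ifn_dataset`.
#' @export
ifn_dataset <- function(trace, endpoints, endpoint_weight = 10, break_h = 8,
                        second = 10) {
  stopifnot(is.data.frame(trace), all(c("time_h", "value") %in% names(trace)),
            is.data.frame(endpoints),
            all(c("pre_duration_h", "induction_norm") %in% names(endpoints)))
  if (nrow(trace) + nrow(endpoints) < 1L)
    stop("dataset needs at least one observation")
  stopifnot(endpoint_weight > 0, break_h >= 0, second > 0)
  if (nrow(endpoints) > 0 && !0 %in% endpoints$pre_duration_h)
    stop("endpoints must include the 0-h (control) condition")
  trace <- trace[order(trace$time_h), , drop = FALSE]
  scale <- mean(abs(trace$value))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  structure(list(trace = trace, endpoints = endpoints,
                 trace_scale = scale, endpoint_weight = endpoint_weight,
                 break_h = break_h, second = second),
            class = "ifn_dataset")
}

#' @export
print.ifn_dataset <- function(x, ...) {
  cat(sprintf(
    "Fitting dataset: %d trace points (sustained input), %d endpoints (%s h pre)\n",
    nrow(x$trace), nrow(x$endpoints),
    paste(sort(x$endpoints$pre_duration_h), collapse = "/")))
  invisible(x)
}

# deterministic IRF9/USP18 readout at sorted observation times
# (fitting hot path: bypasses the trajectory container)
states_at_fast <- function(params, on, off, tau, variant, times, dt) {
  steps <- as.integer(round(times / dt))
  euler_integrate_cpp(params$k1, params$k2, params$k3, params$k4, params$k5,
                      on, off, 2L, tau, 21.82, 7.3, 0,
                      variant$positive_feedback, variant$negative_feedback,
                      variant$usp18_knockdown, TRUE,
                      max(times), dt, 1L, 0, 0, 0, 0, FALSE, FALSE, steps)
}

# weighted residual vector (y - yhat) * sqrt(w); simulation at fixed tau
dataset_residuals <- function(dataset, params, tau, variant = NULL,
                              dt = 0.001) {
  params <- as_ifn_params(params)
  variant <- as_ifn_variant(variant)
  res <- numeric(0)
  if (nrow(dataset$trace) > 0) {
    tt <- dataset$trace$time_h
    pred <- states_at_fast(params, 0, max(tt) + dt, tau, variant, tt,
                           dt)$irf9
    # relative residuals, floored: reporter noise scales with the signal,
    # so each trace point carries comparable information; the floor keeps
    # near-zero early samples from dominating
    denom <- pmax(abs(dataset$trace$value), dataset$trace_scale / 10)
    res <- c(res, (dataset$trace$value - pred) / denom)
  }
  if (nrow(dataset$endpoints) > 0) {
    pres <- sort(unique(c(0, dataset$endpoints$pre_duration_h)))
    ind <- vapply(pres, function(p) {
      prog <- pretreatment_program(p, dataset$break_h, dataset$second)
      on2 <- p + dataset$break_h
      st <- states_at_fast(params, prog[, "on"], prog[, "off"], tau,
                           variant, c(on2, on2 + dataset$second), dt)
      st$irf9[2] - st$irf9[1]
    }, numeric(1))
    ctrl <- ind[pres == 0]
    pred <- if (ctrl > 0) ind[match(dataset$endpoints$pre_duration_h, pres)] /
      ctrl else rep(1e6, nrow(dataset$endpoints))
    res <- c(res, sqrt(dataset$endpoint_weight) *
               (dataset$endpoints$induction_norm - pred))
  }
  res
}

#' Weighted sum-of-squares objective
#'
#' Simulates the model with the given parameters, delay and variant, extracts
#' predictions at the dataset's observation times/conditions and returns the
#' weighted sum of squared residuals.  Zero iff predictions match the
#' observations exactly.
#'
#' @param dataset an [ifn_dataset()].
#' @param params an [ifn_params()].
#' @param tau assigned USP18 delay (h).
#' @param variant a [model_variant()].
#' @param dt Euler step (h).
#' @return A single non-negative number.
#' @export
sse_objective <- function(dataset, params, tau, variant = NULL, dt = 0.001) {
  stopifnot(inherits(dataset, "ifn_dataset"))
  r <- dataset_residuals(dataset, params, tau, variant, dt)
  sum(r^2)
}

# free kinetic parameters per variant
free_param_names <- function(variant) {
  nm <- c("k1", "k2", "k3", "k4", "k5")
  if (!variant$positive_feedback) nm <- setdiff(nm, "k2")
  if (!variant$negative_feedback || variant$usp18_knockdown)
    nm <- setdiff(nm, "k3")
  if (variant$usp18_knockdown) nm <- setdiff(nm, "k5")
  nm
}

#' Fit the kinetic parameters at an assigned delay
#'
#' Nonlinear least squares over the variant's free kinetic constants with the
#' delay `tau` held fixed.  Optimization runs in log-parameter space (which
#' enforces positivity and removes the scale disparity between rate
#' constants) with Levenberg–Marquardt steps ([minpack.lm::nls.lm]), started
#' from `n_starts` seeded log-uniform points spanning four decades; the best
#' run is returned.  Parameters themselves may be weakly identified — the
#' contract is prediction-level: on noiseless data generated by the model the
#' refit reproduces the observations.
#'
#' @inheritParams sse_objective
#' @param n_starts number of multistart initial points.
#' @param start_decades log10 range of the multistart draws, default
#'   `c(1, 5)` (rates from 10 to 1e5).
#' @param seed optional integer seed for the start draws.
#' @param maxiter Levenberg–Marquardt iteration cap per start.
#' @param init optional extra warm start(s): a named kinetic-constant vector
#'   (or list of them) appended to the random starts.
#' @param triage_iters iteration cap of the cheap first pass over all
#'   starts; the best `polish_top` continue to the full `maxiter`.  With
#'   `triage_iters = 0` the starts are only evaluated (no triage
#'   optimization) and the best one is polished — the mode used for warm
#'   re-polish steps.
#' @param polish_top number of triaged starts polished at full `maxiter`.
#' @return An object of class `ifn_fit`: list with `params` (full
#'   [ifn_params()] including `tau`), `tau`, `sse`, `converged`, `variant`,
#'   `n_obs`, `free`, `starts`.
#' @examples
#' \donttest{
#' ds <- generate_fitting_dataset(ifn_params(), tau = 8, seed = 1, dt = 0.01)
#' fit <- fit_kinetics(ds, tau = 8, n_starts = 2, seed = 1, dt = 0.01)
#' coef(fit)
#' }
#' @export
fit_kinetics <- function(dataset, tau, variant = NULL, n_starts = 10,
                         start_decades = c(1, 5), seed = NULL, dt = 0.001,
                         maxiter = 60, init = NULL, triage_iters = 15,
                         polish_top = 2) {
  stopifnot(inherits(dataset, "ifn_dataset"), tau >= 0, n_starts >= 0,
            n_starts >= 1 || length(init) > 0)
  variant <- as_ifn_variant(variant)
  if (!is.null(seed)) set.seed(seed)
  free <- free_param_names(variant)
  base <- as_ifn_params(ifn_params())  # fixed values for non-free parameters

  LOGK_LIM <- log(1e12)  # keeps exp(par) finite while LM explores
  resid_fn <- function(logk) {
    kl <- unclass(base)
    kl[free] <- as.list(exp(pmin(pmax(logk, -LOGK_LIM), LOGK_LIM)))
    kl$tau <- tau
    class(kl) <- "ifn_params"
    r <- dataset_residuals(dataset, kl, tau, variant, dt)
    r[!is.finite(r)] <- 1e6
    r
  }
  run_lm <- function(par0, iters) {
    tryCatch({
      fit <- suppressWarnings(
        minpack.lm::nls.lm(par = par0, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = iters, ptol = 1e-8, ftol = 1e-10)))
      list(logk = fit$par, sse = sum(fit$fvec^2), info = fit$info)
    }, error = function(e) NULL)
  }

  starts <- matrix(log(10) * runif(n_starts * length(free),
                                   start_decades[1], start_decades[2]),
                   nrow = n_starts, ncol = length(free))
  if (!is.null(init)) {
    init <- lapply(if (is.list(init)) init else list(init), function(kv)
      log(pmax(unlist(kv)[free], 1e-12)))
    starts <- rbind(starts, do.call(rbind, init))
  }
  # cheap triage pass over every start, then polish the most promising ones
  triage <- if (triage_iters > 0) {
    lapply(seq_len(nrow(starts)),
           function(s) run_lm(starts[s, ], min(triage_iters, maxiter)))
  } else {
    lapply(seq_len(nrow(starts)), function(s)
      tryCatch(list(logk = starts[s, ], sse = sum(resid_fn(starts[s, ])^2),
                    info = 0L),
               error = function(e) NULL))
  }
  triage <- Filter(Negate(is.null), triage)
  if (!length(triage))
    stop(sprintf(
      "all %d optimization starts failed for tau = %g (variant: %s)",
      nrow(starts), tau, paste(free, collapse = ",")))
  ord <- order(vapply(triage, `[[`, numeric(1), "sse"))
  best <- NULL
  for (s in utils::head(ord, polish_top)) {
    fit <- run_lm(triage[[s]]$logk, maxiter)
    if (is.null(fit)) fit <- triage[[s]]
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  kl <- as.list(base)
  kl[free] <- as.list(pmax(exp(pmin(best$logk, LOGK_LIM)), 1e-300))
  kl$tau <- tau
  structure(list(params = do.call(ifn_params, kl), tau = tau,
                 sse = best$sse, converged = best$info %in% 1:4,
                 variant = variant,
                 n_obs = nrow(dataset$trace) + nrow(dataset$endpoints),
                 free = free, starts = n_starts, dt = dt),
            class = "ifn_fit")
}

#' @export
print.ifn_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit at tau = %g h (%s)\n", x$tau,
              paste(x$free, collapse = ", ")))
  print(x$params)
  cat(sprintf("  weighted SSE = %.6g over %d observations (converged: %s)\n",
              x$sse, x$n_obs, x$converged))
  invisible(x)
}

#' @export
coef.ifn_fit <- function(object, ...) {
  p <- object$params
  c(k1 = p$k1, k2 = p$k2, k3 = p$k3, k4 = p$k4, k5 = p$k5, tau = p$tau)
}

#' @export
logLik.ifn_fit <- function(object, ...) {
  ll <- gaussian_loglik_sse(object$sse, object$n_obs)
  attr(ll, "df") <- length(object$free) + 1  # + sigma (MLE)
  attr(ll, "nobs") <- object$n_obs
  class(ll) <- "logLik"
  ll
}

#' @export
summary.ifn_fit <- function(object, ...) {
  object
}

#' Gaussian log-likelihood of a residual vector
#'
#' With independent Gaussian errors of standard deviation `sigma`, the
#' log-likelihood of residuals `r` is
#' `-(n/2) log(2 pi sigma^2) - SSE / (2 sigma^2)`.  With `sigma = "mle"` the
#' variance is profiled out (`sigma^2 = SSE/n`), giving
#' `-(n/2) (log(2 pi SSE / n) + 1)`.
#'
#' @param residuals numeric residual vector.
#' @param sigma positive error SD, or `"mle"` to profile it.
#' @return The log-likelihood (a single number).
#' @examples
#' gaussian_loglik(0, sigma = 1)  # -log(2*pi)/2
#' @export
gaussian_loglik <- function(residuals, sigma = "mle") {
  stopifnot(is.numeric(residuals), length(residuals) >= 1)
  n <- length(residuals)
  sse <- sum(residuals^2)
  if (identical(sigma, "mle")) return(gaussian_loglik_sse(sse, n))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive number or \"mle\"")
  -(n / 2) * log(2 * pi * sigma^2) - sse / (2 * sigma^2)
}

gaussian_loglik_sse <- function(sse, n) {
  if (sse <= 0) sse <- .Machine$double.xmin  # guard exact fits
  -(n / 2) * (log(2 * pi * sse / n) + 1)
}

#' Scan the assigned USP18 delay
#'
#' Refits all free kinetic parameters at each assigned delay on the grid
#' (reference grid: integers 1 to 20 h) and reports the fitting error curve.
#' The delay with the smallest error is the scan's estimate; ties break
#' toward the smallest delay.
#'
#' @inheritParams fit_kinetics
#' @param taus delay grid (h), non-empty.
#' @return An object of class `tau_scan`: list with `results` (data frame
#'   `tau`, `sse`, `converged`), `fits` (list of `ifn_fit`), `best_tau`.
#' @export
scan_tau <- function(dataset, taus = 1:20, variant = NULL, n_starts = 10,
                     seed = NULL, dt = 0.001, maxiter = 60) {
  stopifnot(length(taus) >= 1)
  taus <- sort(unique(taus))
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", length(taus))
  warm <- NULL
  # ascending pass with warm starts, then a descending refinement pass that
  # re-polishes each delay from its neighbour's optimum; this keeps the
  # error curve smooth at modest multistart sizes
  for (i in seq_along(taus)) {
    fits[[i]] <- fit_kinetics(dataset, tau = taus[i], variant = variant,
                              n_starts = n_starts, dt = dt,
                              maxiter = maxiter, init = warm)
    warm <- list(coef(fits[[i]])[1:5])
  }
  n_tau <- length(taus)
  refine <- function(order_idx) {
    improved <- FALSE
    for (i in order_idx) {
      inits <- list(coef(fits[[i]])[1:5])
      if (i > 1) inits <- c(inits, list(coef(fits[[i - 1]])[1:5]))
      if (i < n_tau) inits <- c(inits, list(coef(fits[[i + 1]])[1:5]))
      refit <- fit_kinetics(dataset, tau = taus[i], variant = variant,
                            n_starts = 0, dt = dt,
                            maxiter = min(40, maxiter), init = inits,
                            triage_iters = 0, polish_top = 1)
      if (refit$sse < fits[[i]]$sse * (1 - 1e-6)) {
        fits[[i]] <- refit
        improved <- TRUE
      } else if (refit$sse < fits[[i]]$sse) fits[[i]] <- refit
    }
    improved
  }
  for (round in 1:2) {
    imp_dn <- refine(rev(seq_len(n_tau)))
    imp_up <- refine(seq_len(n_tau))
    if (!imp_dn && !imp_up) break
  }
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  best <- taus[which.min(sse)]  # which.min takes the first (smallest tau)
  structure(list(results = data.frame(
    tau = taus, sse = sse,
    converged = vapply(fits, `[[`, logical(1), "converged")),
    fits = fits, best_tau = best),
    class = "tau_scan")
}

#' @export
print.tau_scan <- function(x, ...) {
  cat(sprintf("Delay scan over %d values; minimum fitting error at tau = %g h\n",
              nrow(x$results), x$best_tau))
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.tau_scan <- function(x, ...) {
  graphics::plot(x$results$tau, x$results$sse, type = "b", pch = 16,
                 xlab = "assigned delay tau (h)",
                 ylab = "weighted fitting error (SSE)", ...)
  graphics::abline(v = x$best_tau, lty = 2, col = "grey50")
  invisible(x)
}

#' Compare model variants by AIC
#'
#' Fits the full model and the two loop ablations (no positive feedback, no
#' negative feedback) to the same dataset at the same assigned delay, and
#' ranks them by `AIC = 2k - 2 ln L`, where the Gaussian likelihood profiles
#' the error SD (`sigma^2 = SSE/n`) and `k` counts the fitted kinetic
#' constants plus the profiled `sigma`.
#'
#' @inheritParams fit_kinetics
#' @return An object of class `aic_comparison`: list with `table` (data
#'   frame: `variant`, `k`, `sse`, `loglik`, `aic`, `delta_aic`), `best`
#'   (variant label with the smallest AIC) and `fits`.
#' @export
compare_models_aic <- function(dataset, tau, n_starts = 10, seed = NULL,
                               dt = 0.001, maxiter = 60) {
  if (!is.null(seed)) set.seed(seed)
  variants <- list(
    full = model_variant(),
    no_positive_feedback = model_variant(positive_feedback = FALSE),
    no_negative_feedback = model_variant(negative_feedback = FALSE))
  fits <- lapply(variants, function(v)
    fit_kinetics(dataset, tau = tau, variant = v, n_starts = n_starts,
                 dt = dt, maxiter = maxiter))
  # the ablations are boundary cases of the full model (pf -> k1 as k2 -> 0,
  # nf -> 1 as k3 -> Inf); re-polish the full fit from their optima so the
  # comparison respects nestedness even when the full multistart is unlucky
  warm_full <- list(
    coef(fits$full)[1:5],
    replace(coef(fits$no_positive_feedback)[1:5], "k2", 1e-6),
    replace(coef(fits$no_negative_feedback)[1:5], "k3", 1e11))
  refull <- fit_kinetics(dataset, tau = tau, variant = variants$full,
                         n_starts = 0, dt = dt, maxiter = maxiter,
                         init = warm_full, triage_iters = 0, polish_top = 2)
  if (refull$sse < fits$full$sse) fits$full <- refull
  # a full fit that only ties an ablation usually sat down on that
  # ablation's boundary plateau; retry its interior with fresh starts
  abl_min <- min(fits$no_positive_feedback$sse, fits$no_negative_feedback$sse)
  if (fits$full$sse >= 0.999 * abl_min) {
    retry <- fit_kinetics(dataset, tau = tau, variant = variants$full,
                          n_starts = n_starts + 2, dt = dt,
                          maxiter = maxiter, init = warm_full)
    if (retry$sse < fits$full$sse) fits$full <- retry
  }
  k <- vapply(fits, function(f) length(f$free) + 1L, integer(1))
  ll <- vapply(fits, function(f) gaussian_loglik_sse(f$sse, f$n_obs),
               numeric(1))
  aic <- 2 * k - 2 * ll
  tab <- data.frame(variant = names(variants), k = k, sse =
                      vapply(fits, `[[`, numeric(1), "sse"),
                    loglik = ll, aic = aic, delta_aic = aic - min(aic),
                    row.names = NULL)
  # ties (within numerical noise) go to the smaller parameter count
  o <- order(round(tab$aic, 10), tab$k)
  structure(list(table = tab, best = tab$variant[o[1]], fits = fits),
            class = "aic_comparison")
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat("AIC model comparison (AIC = 2k - 2 lnL, sigma profiled):\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat("Best variant:", x$best, "\n")
  invisible(x)
}
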