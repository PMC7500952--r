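#' Kinetic parameters of the interferon feedback model
#'
#' Bundles the five kinetic constants of the two-species model and the USP18
#' induction delay.  The model tracks induced IRF9 (positive feedback, fast)
#' and USP18 (negative feedback, delayed) above their pre-treatment baselines,
#' in arbitrary fluorescence-like concentration units.
#'
#' The defaults are the package's reference parameter set.  They were chosen
#' from the structure of the model (see the methods vignette) and verified to
#' reproduce the qualitative response pattern to interferon pretreatments:
#' priming after 2-h and 10-h pretreatments, desensitization after 24 h.
#'
#' @param k1 maximal positive-feedback production rate (concentration/h).
#' @param k2 IRF9 half-saturation level of the positive feedback
#'   (concentration).
#' @param k3 USP18 half-inhibition level of the negative feedback
#'   (concentration).
#' @param k4 basal interferon-driven IRF9 production rate (concentration/h).
#' @param k5 basal interferon-driven USP18 production rate (concentration/h).
#' @param tau delay of USP18 production after interferon onset (h); the gate
#'   opens once continuous exposure reaches `tau`.
#'
#' @return An object of class `ifn_params` (a named list).
#' @examples
#' p <- ifn_params()
#' positive_feedback(p$k2, p)  # half-saturation: k1/2
#' @export
ifn_params <- function(k1 = 2000, k2 = 2000, k3 = 10000, k4 = 20, k5 = 50,
                       tau = 8) {
  for (nm in c("k1", "k2", "k3", "k4", "k5", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  if (k2 <= 0) stop("'k2' must be > 0")
  if (k3 <= 0) stop("'k3' must be > 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, tau = tau),
            class = "ifn_params")
}

#' @export
print.ifn_params <- function(x, ...) {
  cat("Interferon feedback model parameters\n")
  cat(sprintf("  k1 = %g (max positive-feedback rate, conc/h)\n", x$k1))
  cat(sprintf("  k2 = %g (IRF9 half-saturation, conc)\n", x$k2))
  cat(sprintf("  k3 = %g (USP18 half-inhibition, conc)\n", x$k3))
  cat(sprintf("  k4 = %g (basal IRF9 rate, conc/h)\n", x$k4))
  cat(sprintf("  k5 = %g (basal USP18 rate, conc/h)\n", x$k5))
  cat(sprintf("  tau = %g h (USP18 induction delay)\n", x$tau))
  invisible(x)
}

as_ifn_params <- function(x) {
  if (inherits(x, "ifn_params")) return(x)
  if (is.list(x) || is.numeric(x)) return(do.call(ifn_params, as.list(x)))
  stop("cannot interpret 'params'; use ifn_params()")
}

#' Model variants (loop ablations)
#'
#' The full model couples a saturating positive feedback through IRF9 with a
#' delayed negative feedback through USP18.  For model comparison the package
#' supports cutting either loop, and a USP18-knockdown surrogate in which
#' USP18 is held at zero (so the negative feedback is inert).
#'
#' * `positive_feedback = FALSE`: the saturating drive `pf` is replaced by the
#'   constant `k1` (the dependence on IRF9 is cut; `k2` becomes unused).
#' * `negative_feedback = FALSE`: the inhibition factor `nf` is fixed at 1
#'   (`k3` unused).
#' * `usp18_knockdown = TRUE`: USP18 is clamped at 0 for the whole run, which
#'   also forces `nf = 1`.
#'
#' Combining `usp18_knockdown = TRUE` with `negative_feedback = FALSE` is
#' rejected: the two encode the same ablation at different levels and the
#' double request is almost certainly a configuration mistake.
#'
#' @param positive_feedback logical; keep the IRF9 positive feedback loop?
#' @param negative_feedback logical; keep the USP18 negative feedback loop?
#' @param usp18_knockdown logical; clamp USP18 at zero (knockdown surrogate)?
#' @return An object of class `ifn_variant`.
#' @examples
#' model_variant()                       # full model
#' model_variant(usp18_knockdown = TRUE) # USP18-KD cells
#' @export
model_variant <- function(positive_feedback = TRUE, negative_feedback = TRUE,
                          usp18_knockdown = FALSE) {
  stopifnot(is.logical(positive_feedback), length(positive_feedback) == 1L,
            is.logical(negative_feedback), length(negative_feedback) == 1L,
            is.logical(usp18_knockdown), length(usp18_knockdown) == 1L)
  if (usp18_knockdown && !negative_feedback)
    stop("invalid variant combination: usp18_knockdown already disables the ",
         "negative feedback; do not also set negative_feedback = FALSE")
  structure(list(positive_feedback = positive_feedback,
                 negative_feedback = negative_feedback,
                 usp18_knockdown = usp18_knockdown),
            class = "ifn_variant")
}

#' @export
print.ifn_variant <- function(x, ...) {
  lab <- if (x$usp18_knockdown) "USP18 knockdown"
         else if (x$positive_feedback && x$negative_feedback) "full model"
         else if (!x$positive_feedback) "no positive feedback"
         else "no negative feedback"
  cat("Model variant:", lab, "\n")
  invisible(x)
}

as_ifn_variant <- function(x) {
  if (is.null(x)) return(model_variant())
  if (inherits(x, "ifn_variant")) return(x)
  if (is.list(x)) return(do.call(model_variant, x))
  stop("cannot interpret 'variant'; use model_variant()")
}

#' Expression-noise configuration for stochastic simulation
#'
#' Additive white-noise terms on the two production equations.  The default
#' standard deviations (250 for IRF9, 1000 for USP18, concentration units)
#' follow the scale at which cell-to-cell expression scatter is visible in
#' single-cell reporter data.  Two discretization conventions are supported:
#' `"plain_euler"` adds `sigma * dt * N(0,1)` per Euler step (a plain Euler
#' loop with a Gaussian noise term tacked onto the derivative), while
#' `"euler_maruyama"` adds `sigma * sqrt(dt) * N(0,1)` (the standard SDE
#' scaling).  The default is `"plain_euler"`; see the methods vignette for
#' the rationale.
#'
#' @param sigma_irf9 noise scale for IRF9 (concentration units).
#' @param sigma_usp18 noise scale for USP18 (concentration units).
#' @param convention `"plain_euler"` or `"euler_maruyama"`.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sigma_irf9 = 250, sigma_usp18 = 1000,
                         convention = c("plain_euler", "euler_maruyama")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(sigma_irf9), length(sigma_irf9) == 1L, sigma_irf9 >= 0,
            is.numeric(sigma_usp18), length(sigma_usp18) == 1L,
            sigma_usp18 >= 0)
  structure(list(sigma_irf9 = sigma_irf9, sigma_usp18 = sigma_usp18,
                 convention = convention),
            class = "noise_config")
}
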