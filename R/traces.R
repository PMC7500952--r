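#' Smoothed time derivative of a reporter trace
#'
#' Centered moving-average smoothing (odd `window`, edge-padded) followed by
#' central differences; one-sided differences at the endpoints.  The trace
#' must be uniformly sampled.
#'
#' @param value reporter values.
#' @param time sample times (h), uniformly spaced, same length as `value`.
#' @param window moving-average width in samples (odd, >= 3, <= trace
#'   length).
#' @return Numeric vector of derivatives (a.u./h), same length as `value`.
#' @examples
#' t <- seq(0, 10, by = 0.5)
#' smoothed_derivative(3 * t + 2, t)  # ~3 everywhere
#' @export
smoothed_derivative <- function(value, time, window = 5) {
  stopifnot(is.numeric(value), is.numeric(time),
            length(value) == length(time), length(value) >= 3)
  if (window %% 2 != 1 || window < 3) stop("'window' must be odd and >= 3")
  if (window > length(value)) stop("'window' longer than the trace")
  dtv <- diff(time)
  if (any(abs(dtv - dtv[1]) > 1e-6 * max(dtv)))
    stop("trace must be uniformly sampled")
  h <- dtv[1]
  half <- (window - 1) / 2
  padded <- c(rep(value[1], half), value, rep(value[length(value)], half))
  sm <- as.numeric(stats::filter(padded, rep(1 / window, window),
                                 sides = 2))
  sm <- sm[(half + 1):(half + length(value))]
  n <- length(sm)
  d <- numeric(n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (2 * h)
  d[1] <- (sm[2] - sm[1]) / h
  d[n] <- (sm[n] - sm[n - 1]) / h
  d
}

#' Call the activation time of a reporter trace
#'
#' The activation time is the time, after treatment onset, at which the
#' reporter starts to be upregulated.  Detection rule: the smoothed
#' derivative ([smoothed_derivative()]) must exceed a threshold (baseline
#' mean + `k_sd` baseline SDs of the derivative) for at least `persist`
#' consecutive samples; the reported activation time is then anchored to the
#' first sample near the crossing whose raw value exceeds the raw baseline
#' level (baseline mean + `k_sd` baseline SDs), which places the call within
#' one sampling interval of the true ramp start on clean traces.  Baseline
#' statistics come from the pre-onset samples; censored (`NA`) if no
#' persistent crossing occurs.
#'
#' @param value reporter values.
#' @param time sample times (h), uniformly spaced; must include pre-onset
#'   baseline samples.
#' @param onset treatment onset time (h).
#' @param window smoothing window (samples), odd.
#' @param persist required consecutive above-threshold samples.
#' @param k_sd threshold stringency in baseline SDs.
#' @return An object of class `activation_call`: list with `time` (hours
#'   since onset, or `NA`), `censored` (logical), `threshold`, and the rule
#'   parameters.
#' @examples
#' t <- seq(-2, 20, by = 1 / 3)
#' v <- 100 + pmax(t - 5, 0) * 800
#' call_activation_time(v, t)$time  # ~5
#' @export
call_activation_time <- function(value, time, onset = 0, window = 5,
                                 persist = 3, k_sd = 3) {
  stopifnot(length(value) == length(time), persist >= 1)
  pre <- time < onset
  if (!any(pre)) stop("no pre-onset baseline samples in the trace")
  d <- smoothed_derivative(value, time, window)
  thr <- mean(d[pre]) + k_sd * max(sd(d[pre]), 0, na.rm = TRUE)
  raw_thr <- mean(value[pre]) + k_sd * max(sd(value[pre]), 0, na.rm = TRUE)

  post <- which(time >= onset)
  above <- d[post] > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= persist)
  out <- list(time = NA_real_, censored = TRUE, threshold = thr,
              window = window, persist = persist, k_sd = k_sd)
  if (length(hit)) {
    i_det <- post[ends[hit[1]] - runs$lengths[hit[1]] + 1L]  # crossing index
    # anchor to the raw-trace rise near the crossing
    lo <- max(min(post), i_det - window)
    hi <- min(length(value), i_det + persist + window)
    cand <- lo:hi
    rise <- cand[value[cand] > raw_thr & time[cand] >= onset]
    t_act <- if (length(rise)) time[rise[1]] else time[i_det]
    out$time <- t_act - onset
    out$censored <- FALSE
  }
  class(out) <- "activation_call"
  out
}

#' @export
print.activation_call <- function(x, ...) {
  if (x$censored) cat("Activation call: censored (no upregulation detected)\n")
  else cat(sprintf("Activation call: %.3f h after onset\n", x$time))
  invisible(x)
}

#' Delay time between USP18 and IRF9 activation
#'
#' The per-cell delay is the USP18-reporter activation time minus the
#' IRF9-reporter activation time.  Kept raw: measurement noise can make it
#' negative, and negative delays fall into the short-delay group.  Censored
#' (`NA`) if either call is censored.
#'
#' @param act_irf9,act_usp18 [call_activation_time()] results (or plain
#'   activation times in hours).
#' @return Delay in hours, or `NA` if censored.
#' @examples
#' delay_time(7.9008, 12.1620)  # 4.2612
#' @export
delay_time <- function(act_irf9, act_usp18) {
  g <- function(a) {
    if (inherits(a, "activation_call"))
      return(if (a$censored) NA_real_ else a$time)
    as.numeric(a)
  }
  g(act_usp18) - g(act_irf9)
}

#' Percent of cell-cycle progression at treatment onset
#'
#' The fraction of the current cycle elapsed when treatment starts, from the
#' bracketing division times: `100 * (onset - previous division) /
#' (next division - previous division)`.  Censored (with a reason) when the
#' onset is not bracketed by two observed divisions.
#'
#' @param onset treatment onset time (h), on the same clock as `divisions`.
#' @param divisions observed division times (h) of the cell.
#' @return List with `percent` (in `[0, 100)`, or `NA`), `censored`,
#'   `reason`, and the bracketing `cycle_start`/`cycle_end`.
#' @examples
#' percent_progression(20, c(10, 30))$percent        # 50
#' percent_progression(7.3, c(0, 21.82))$percent     # ~33.5
#' @export
percent_progression <- function(onset, divisions) {
  stopifnot(is.numeric(onset), length(onset) == 1L, is.numeric(divisions))
  divisions <- sort(divisions)
  i <- findInterval(onset, divisions)
  if (i < 1L || i >= length(divisions))
    return(list(percent = NA_real_, censored = TRUE,
                reason = "onset not bracketed by two observed divisions",
                cycle_start = NA_real_, cycle_end = NA_real_))
  lo <- divisions[i]; hi <- divisions[i + 1L]
  list(percent = 100 * (onset - lo) / (hi - lo), censored = FALSE,
       reason = NULL, cycle_start = lo, cycle_end = hi)
}

#' Classify cells into short- and long-delay groups
#'
#' Group 1: delay `<=` threshold (including negative measured delays);
#' Group 2: delay strictly greater than the threshold (10 h by convention).
#' `NA` delays stay unclassified.
#'
#' @param delays delay times (h).
#' @param threshold group boundary (h).
#' @return List with `labels` (factor `group1`/`group2`), `fractions`
#'   (named vector over non-missing delays), `threshold`.
#' @examples
#' classify_delay_groups(c(2, 11, 12, 3))$fractions  # 0.5 / 0.5
#' @export
classify_delay_groups <- function(delays, threshold = 10) {
  stopifnot(length(delays) >= 1, is.numeric(threshold), threshold >= 0)
  lab <- factor(ifelse(is.na(delays), NA,
                       ifelse(delays > threshold, "group2", "group1")),
                levels = c("group1", "group2"))
  n_ok <- sum(!is.na(lab))
  fr <- if (n_ok) table(lab) / n_ok else c(group1 = NA, group2 = NA)
  list(labels = lab,
       fractions = c(group1 = unname(fr["group1"]),
                     group2 = unname(fr["group2"])),
       threshold = threshold)
}

#' Induction amount over a time window
#'
#' Baseline-subtracted induction: the trace value at `window_end` minus the
#' value at `window_start` (linear interpolation between samples).  Use
#' `reference` to express it relative to a control condition's amount.
#'
#' @param value reporter values.
#' @param time sample times (h).
#' @param window_start,window_end window bounds (h), inside the trace span.
#' @param reference optional control amount; when given, the returned value
#'   is `amount / reference`.
#' @return A single number (a.u., or dimensionless when normalized).
#' @examples
#' t <- 0:10
#' induction_amount(5 * t, t, 2, 8)  # 30
#' @export
induction_amount <- function(value, time, window_start, window_end,
                             reference = NULL) {
  stopifnot(length(value) == length(time), window_start < window_end)
  if (window_start < min(time) || window_end > max(time))
    stop("induction window lies outside the trace")
  v <- approx(time, value, xout = c(window_start, window_end))$y
  amt <- v[2] - v[1]
  if (!is.null(reference)) {
    stopifnot(is.numeric(reference), reference != 0)
    amt <- amt / reference
  }
  amt
}

#' Quantify a cohort of dual-reporter traces
#'
#' Applies [call_activation_time()] to both reporter channels of every cell,
#' derives the delay time and the percent of cell-cycle progression at
#' onset, and returns one record per cell.
#'
#' @param traces tidy trace table: `cell_id`, `time_h`, `channel`
#'   (`reporter_irf9` / `reporter_usp18`), `value`.
#' @param divisions division table: `cell_id`, `division_time_h`; optional
#'   (`NULL` skips progression).
#' @param onset treatment onset time (h).
#' @param ... activation-rule parameters passed to
#'   [call_activation_time()].
#' @return Data frame with `cell_id`, `act_irf9_h`, `act_usp18_h`,
#'   `delay_h`, `censored_irf9`, `censored_usp18`, `progression_pct`.
#' @export
analyze_traces <- function(traces, divisions = NULL, onset = 0, ...) {
  stopifnot(all(c("cell_id", "time_h", "channel", "value") %in%
                  names(traces)))
  ids <- unique(traces$cell_id)
  one <- function(id) {
    s <- traces[traces$cell_id == id, ]
    call_ch <- function(ch) {
      cc <- s[s$channel == ch, ]
      cc <- cc[order(cc$time_h), ]
      if (nrow(cc) < 3) return(list(time = NA_real_, censored = TRUE))
      call_activation_time(cc$value, cc$time_h, onset = onset, ...)
    }
    ai <- call_ch("reporter_irf9")
    au <- call_ch("reporter_usp18")
    prog <- if (!is.null(divisions)) {
      dv <- divisions$division_time_h[divisions$cell_id == id]
      percent_progression(onset, dv)$percent
    } else NA_real_
    data.frame(cell_id = id, act_irf9_h = ai$time, act_usp18_h = au$time,
               delay_h = delay_time(ai$time, au$time),
               censored_irf9 = ai$censored, censored_usp18 = au$censored,
               progression_pct = prog)
  }
  do.call(rbind, lapply(ids, one))
}

#' Summary statistics of per-cell quantifications
#'
#' Means with normal-approximation 95% confidence intervals, coefficients of
#' variation, the long-delay (Group-2) fraction at the given threshold, and
#' Pearson correlations for requested column pairs.
#'
#' @param records per-cell data frame (e.g. from [analyze_traces()]).
#' @param columns columns to summarize; default the activation and delay
#'   columns present.
#' @param threshold Group-2 delay threshold (h).
#' @param cor_pairs optional list of 2-element character vectors naming
#'   column pairs to correlate.
#' @return List with `stats` (data frame: column, n, mean, ci_lo, ci_hi,
#'   cv), `group2_fraction`, `correlations`.
#' @export
cohort_summary <- function(records, columns = intersect(
  c("act_irf9_h", "act_usp18_h", "delay_h"), names(records)),
  threshold = 10, cor_pairs = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  stat1 <- function(colnm) {
    v <- records[[colnm]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2)
      return(data.frame(column = colnm, n = n, mean = mean(v),
                        ci_lo = NA_real_, ci_hi = NA_real_, cv = NA_real_))
    m <- mean(v); se <- sd(v) / sqrt(n)
    data.frame(column = colnm, n = n, mean = m,
               ci_lo = m - qnorm(0.975) * se, ci_hi = m + qnorm(0.975) * se,
               cv = if (m > 0) sd(v) / m else NA_real_)
  }
  stats_df <- do.call(rbind, lapply(columns, stat1))
  g2 <- if ("delay_h" %in% names(records) &&
            any(!is.na(records$delay_h)))
    classify_delay_groups(records$delay_h, threshold)$fractions[["group2"]]
  else NA_real_
  cors <- NULL
  if (!is.null(cor_pairs))
    cors <- vapply(cor_pairs, function(pr) {
      ok <- stats::complete.cases(records[, pr])
      cor(records[[pr[1]]][ok], records[[pr[2]]][ok])
    }, numeric(1))
  list(stats = stats_df, group2_fraction = g2, correlations = cors)
}
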