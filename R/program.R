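#' Piecewise-constant binary interferon input programs
#'
#' An input program is an ordered set of half-open intervals `[on, off)` (in
#' hours) during which the interferon input `I(t)` equals 1; outside them it
#' is 0.  Intervals must be sorted, non-overlapping and non-degenerate;
#' adjacent intervals with zero gap are merged on construction.
#'
#' @param on,off numeric vectors of equal length: interval start and end
#'   times (h), with `on < off` elementwise.
#' @return An object of class `input_program`: a two-column matrix with
#'   columns `on` and `off`.
#' @examples
#' input_program(c(0, 10), c(2, 20))
#' pulse_program(5, 8, 8)
#' pretreatment_program(24, 8, 10)
#' @export
input_program <- function(on = numeric(), off = numeric()) {
  stopifnot(is.numeric(on), is.numeric(off), length(on) == length(off))
  if (anyNA(on) || anyNA(off)) stop("interval times must not be NA")
  if (any(on < 0)) stop("interval start times must be >= 0")
  if (any(on >= off)) stop("each interval needs on < off")
  o <- order(on)
  on <- on[o]; off <- off[o]
  if (length(on) > 1L && any(on[-1L] < off[-length(off)]))
    stop("input intervals must not overlap")
  # merge zero-gap neighbours
  if (length(on) > 1L) {
    keep_on <- c(TRUE, on[-1L] > off[-length(off)])
    grp <- cumsum(keep_on)
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  structure(cbind(on = as.numeric(on), off = as.numeric(off)),
            class = "input_program")
}

#' @export
print.input_program <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Input program: never on\n")
  } else {
    cat(sprintf("Input program: %d ON interval(s), total ON time %g h\n",
                nrow(x), sum(x[, "off"] - x[, "on"])))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%g, %g)\n", x[i, "on"], x[i, "off"]))
  }
  invisible(x)
}

as_input_program <- function(x) {
  if (inherits(x, "input_program")) return(x)
  if (is.matrix(x) && ncol(x) == 2L) return(input_program(x[, 1L], x[, 2L]))
  if (is.data.frame(x)) return(input_program(x[[1L]], x[[2L]]))
  stop("cannot interpret 'program'; use input_program()")
}

#' Interferon pretreatment protocol
#'
#' Builds the two-phase stimulation protocol used throughout: a pretreatment
#' of `pre` hours, a break of `break_h` hours with no input, then a second
#' input of `second` hours.  With `pre = 0` the program is the single
#' interval `[break_h, break_h + second)`, so that every condition shares the
#' same second-input clock.
#'
#' @param pre pretreatment duration (h), may be 0.
#' @param break_h break duration between the two inputs (h).
#' @param second second-input duration (h).
#' @return An `input_program`.
#' @examples
#' pretreatment_program(24, 8, 10)  # [0,24) then [32,42)
#' pretreatment_program(0, 8, 10)   # control: [8,18)
#' @export
pretreatment_program <- function(pre, break_h = 8, second = 10) {
  stopifnot(is.numeric(pre), pre >= 0, is.numeric(break_h), break_h >= 0,
            is.numeric(second), second >= 0)
  on <- c(if (pre > 0) 0, pre + break_h)
  off <- c(if (pre > 0) pre, pre + break_h + second)
  keep <- off > on
  input_program(on[keep], off[keep])
}

#' Pulsatile interferon input
#'
#' `n` pulses of `on_h` hours separated by gaps of `off_h` hours, starting at
#' time 0; total ON time is `n * on_h`.  Zero-gap pulses collapse into one
#' sustained interval.
#'
#' @param n number of pulses (>= 1).
#' @param on_h pulse duration (h).
#' @param off_h gap between pulses (h); may be 0.
#' @return An `input_program`.
#' @examples
#' pulse_program(5, 8, 8)   # 5 x 8-h pulses, 50% duty cycle
#' pulse_program(1, 40, 0)  # a single 40-h sustained input
#' @export
pulse_program <- function(n, on_h, off_h) {
  stopifnot(is.numeric(n), n >= 1, n == round(n),
            is.numeric(on_h), on_h > 0, is.numeric(off_h), off_h >= 0)
  starts <- (seq_len(n) - 1) * (on_h + off_h)
  input_program(starts, starts + on_h)
}

#' Input indicator and continuous exposure
#'
#' `input_at()` evaluates the binary input `I(t)`: 1 iff `t` lies in some
#' half-open ON interval.  `exposure_at()` returns the continuous exposure of
#' the current ON episode — `t - on` for the interval containing `t`, and 0
#' whenever the input is off.  The exposure clock therefore resets at every
#' input OFF, which is what makes the delay gate require an uninterrupted
#' stimulation.
#'
#' @param program an `input_program`.
#' @param t time(s) in hours, >= 0 (vectorized).
#' @return `input_at()`: integer 0/1 vector; `exposure_at()`: numeric hours.
#' @examples
#' p <- pretreatment_program(24, 8, 10)
#' input_at(p, c(12, 24, 28, 35))     # 1 0 0 1
#' exposure_at(p, c(10, 28, 35))      # 10 0 3
#' @export
input_at <- function(program, t) {
  program <- as_input_program(program)
  stopifnot(is.numeric(t), all(t >= 0))
  if (nrow(program) == 0L) return(integer(length(t)))
  res <- integer(length(t))
  for (i in seq_len(nrow(program)))
    res[t >= program[i, "on"] & t < program[i, "off"]] <- 1L
  res
}

#' @rdname input_at
#' @export
exposure_at <- function(program, t) {
  program <- as_input_program(program)
  stopifnot(is.numeric(t), all(t >= 0))
  res <- numeric(length(t))
  if (nrow(program) == 0L) return(res)
  for (i in seq_len(nrow(program))) {
    inside <- t >= program[i, "on"] & t < program[i, "off"]
    res[inside] <- t[inside] - program[i, "on"]
  }
  res
}
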