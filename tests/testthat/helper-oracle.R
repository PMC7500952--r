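# Independent high-accuracy reference integrator for the deterministic model
# (adaptive Runge-Kutta via deSolve, integrating piecewise between the input
# and gate switch times so the discontinuous I/Su factors are exact).
# Supports the fixed-delay gate; used to validate the Euler scheme.
oracle_trajectory <- function(params, program, tau, t_end, times) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  on <- program[, "on"]; off <- program[, "off"]
  brk <- sort(unique(pmin(pmax(c(0, on, off, on + tau, t_end), 0), t_end)))
  rhs <- function(t, y, parms) {
    pf <- params$k1 * y[1] / (params$k2 + y[1])
    nf <- params$k3 / (params$k3 + y[2])
    drive <- pf * nf
    list(c(parms$I * (params$k4 + drive),
           parms$I * parms$Su * (params$k5 + drive)))
  }
  out_t <- numeric(0); out_i <- numeric(0); out_u <- numeric(0)
  y <- c(0, 0)
  for (s in seq_len(length(brk) - 1)) {
    a <- brk[s]; b <- brk[s + 1]
    if (b - a < 1e-12) next
    mid <- (a + b) / 2
    I <- as.numeric(input_at(program, mid))
    Su <- as.numeric(su_at(gating_policy("fixed_delay", tau = tau),
                           program, mid))
    tt <- sort(unique(c(a, times[times >= a & times < b], b)))
    sol <- deSolve::ode(y = y, times = tt, func = rhs,
                        parms = list(I = I, Su = Su), method = "ode45",
                        rtol = 1e-10, atol = 1e-8)
    keep <- sol[, 1] %in% times & sol[, 1] < b
    out_t <- c(out_t, sol[keep, 1])
    out_i <- c(out_i, sol[keep, 2])
    out_u <- c(out_u, sol[keep, 3])
    y <- as.numeric(sol[nrow(sol), 2:3])
  }
  if (t_end %in% times) {
    out_t <- c(out_t, t_end); out_i <- c(out_i, y[1]); out_u <- c(out_u, y[2])
  }
  keep <- !duplicated(out_t)
  data.frame(time_h = out_t[keep], irf9 = out_i[keep], usp18 = out_u[keep])
}

# log-uniform random parameter draw in moderately stiff ranges
random_params <- function() {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  ifn_params(k1 = lu(100, 3000), k2 = lu(500, 5000), k3 = lu(1000, 2e4),
             k4 = lu(10, 100), k5 = lu(10, 200), tau = 8)
}
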