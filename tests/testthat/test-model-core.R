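test_that("feedback functions follow their closed forms and reject bad input", {
  p <- ifn_params(k1 = 12, k2 = 3, k3 = 7)
  expect_equal(positive_feedback(0, p), 0)
  expect_equal(positive_feedback(p$k2, p), p$k1 / 2)
  expect_equal(positive_feedback(9 * p$k2, p), 0.9 * p$k1)
  expect_lt(positive_feedback(1e9, p), p$k1)
  expect_error(positive_feedback(-1, p), "non-negative")

  expect_equal(negative_feedback(0, p), 1)
  expect_equal(negative_feedback(p$k3, p), 0.5)
  expect_equal(negative_feedback(99 * p$k3, p), 0.01)
  expect_error(negative_feedback(-0.1, p), "non-negative")
})

test_that("parameter and variant constructors validate their invariants", {
  expect_error(ifn_params(k1 = -1), "non-negative")
  expect_error(ifn_params(k2 = 0), "k2")
  expect_error(ifn_params(k3 = 0), "k3")
  expect_error(ifn_params(tau = -2), "non-negative")
  expect_error(model_variant(usp18_knockdown = TRUE,
                             negative_feedback = FALSE),
               "invalid variant combination")
})

test_that("input programs use the half-open convention and merge zero gaps", {
  prog <- input_program(0, 24)
  expect_equal(input_at(prog, c(0, 12, 23.999, 24, 30)), c(1, 1, 1, 0, 0))
  prog2 <- input_program(c(0, 10), c(2, 20))
  expect_equal(input_at(prog2, c(1, 5, 15)), c(1, 0, 1))
  expect_error(input_program(5, 5))             # degenerate
  expect_error(input_program(c(0, 1), c(3, 4))) # overlap
  merged <- input_program(c(0, 1), c(1, 2))
  expect_equal(nrow(merged), 1L)
  expect_equal(unclass(merged)[1, ], c(on = 0, off = 2))
})

test_that("continuous exposure tracks the current ON episode and resets", {
  prog <- input_program(c(0, 32), c(24, 42))
  expect_equal(exposure_at(prog, 35), 3)
  expect_equal(exposure_at(prog, 10), 10)
  expect_equal(exposure_at(prog, 28), 0)  # during the break
  expect_equal(exposure_at(prog, 24), 0)  # off boundary is OFF
})

test_that("the Su gate opens at tau of continuous exposure (closed boundary)", {
  pol <- gating_policy("fixed_delay", tau = 8)
  prog <- input_program(0, 24)
  expect_equal(su_at(pol, prog, c(7.9, 8, 8.1)), c(0, 1, 1))
  # 8-h pulses never accumulate 8 h of exposure under the half-open rule
  pulses <- pulse_program(5, 8, 8)
  tt <- seq(0, 72, by = 0.37)
  expect_true(all(su_at(pol, pulses, tt) == 0))
  expect_true(all(su_at(gating_policy("never_on"), prog, tt) == 0))
  expect_true(all(su_at(gating_policy("always_on"), prog, c(0, 5)) ==
                    input_at(prog, c(0, 5))))
})

test_that("cell-cycle gate delays each ON episode by the phase-dependent wait", {
  pol <- gating_policy("cell_cycle", T_cycle = 20, w = 5, t0 = 10)
  prog <- input_program(c(0, 32), c(24, 42))
  # first episode: phase 10 -> delay 10; second: phase (10+32) mod 20 = 2 -> 0
  expect_equal(su_at(pol, prog, c(5, 9.99, 10, 20)), c(0, 0, 1, 1))
  expect_equal(su_at(pol, prog, c(32, 40)), c(1, 1))
})

test_that("derivatives implement the gated production model", {
  p <- ifn_params(k1 = 100, k2 = 50, k3 = 10, k4 = 7, k5 = 3, tau = 8)
  prog <- input_program(0, 24)
  # no input: both derivatives vanish regardless of state
  expect_equal(unname(ifn_derivatives(500, 500, 30, p, prog)), c(0, 0))
  # input on, gate closed
  expect_equal(unname(ifn_derivatives(0, 0, 1, p, prog)), c(p$k4, 0))
  # input on, gate open, state (k2, 0): pf = k1/2, nf = 1
  expect_equal(unname(ifn_derivatives(p$k2, 0, 9, p, prog)),
               c(p$k4 + p$k1 / 2, p$k5 + p$k1 / 2))
  # ungated grouping keeps the feedback drive alive without input
  expect_equal(unname(ifn_derivatives(p$k2, 0, 30, p, prog,
                                      grouping = "ungated")),
               c(p$k1 / 2, p$k1 / 2))
})

test_that("variant ablations cut the intended terms", {
  p <- ifn_params(k1 = 100, k2 = 50, k3 = 10, k4 = 7, k5 = 3, tau = 0)
  prog <- input_program(0, 24)
  # no positive feedback: pf term becomes the constant k1 even at state 0
  expect_equal(unname(ifn_derivatives(0, 0, 1, p, prog,
                                      variant = model_variant(
                                        positive_feedback = FALSE)))[1],
               p$k4 + p$k1)
  # no negative feedback: nf = 1 at any USP18
  d <- ifn_derivatives(p$k2, 1e6, 1, p, prog,
                       variant = model_variant(negative_feedback = FALSE))
  expect_equal(unname(d), c(p$k4 + p$k1 / 2, p$k5 + p$k1 / 2))
  # knockdown: USP18 frozen at zero
  dk <- ifn_derivatives(p$k2, 0, 1, p, prog,
                        variant = model_variant(usp18_knockdown = TRUE))
  expect_equal(unname(dk[2]), 0)
})

test_that("integration matches closed forms in the linear regime", {
  # empty program: nothing happens
  tr0 <- simulate_pathway(ifn_params(), input_program(), t_end = 5, dt = 0.01)
  expect_true(all(tr0$irf9 == 0) && all(tr0$usp18 == 0))
  # k1 = 0, gate never open: IRF9 = k4 * min(t, 10), USP18 = 0
  p <- ifn_params(k1 = 0, k4 = 50, tau = 8)
  tr <- simulate_pathway(p, input_program(0, 10),
                         policy = gating_policy("never_on"),
                         t_end = 20, dt = 0.001, thin = 1000)
  expect_equal(tr$irf9, 50 * pmin(tr$time_h, 10), tolerance = 1e-6)
  expect_true(all(tr$usp18 == 0))
  expect_error(simulate_pathway(p, input_program(0, 10), t_end = 1, dt = 2),
               "dt")
})

test_that("deterministic trajectories are monotone, bounded and input-gated", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    prog <- pretreatment_program(10, 8, 10)
    tr <- simulate_pathway(p, prog, t_end = 28, dt = 0.01)
    expect_true(all(diff(tr$irf9) >= 0))
    expect_true(all(diff(tr$usp18) >= 0))
    expect_true(all(tr$irf9 >= 0) && all(tr$usp18 >= 0))
    # slope bound: dIRF9/dt <= k4 + k1, dUSP18/dt <= k5 + k1
    expect_true(all(diff(tr$irf9) <= (p$k4 + p$k1) * 0.01 + 1e-9))
    expect_true(all(diff(tr$usp18) <= (p$k5 + p$k1) * 0.01 + 1e-9))
    # state frozen during the break [10, 18)
    brk <- tr$time_h >= 10 & tr$time_h <= 18
    expect_equal(length(unique(tr$irf9[brk])), 1L)
  }
})

test_that("USP18 knockdown reproduces the no-negative-feedback IRF9 path", {
  p <- ifn_params()
  prog <- input_program(0, 30)
  kd <- simulate_pathway(p, prog, variant = model_variant(
    usp18_knockdown = TRUE), t_end = 30, dt = 0.01, thin = 100)
  nn <- simulate_pathway(p, prog, variant = model_variant(
    negative_feedback = FALSE), t_end = 30, dt = 0.01, thin = 100)
  expect_equal(kd$irf9, nn$irf9)
  expect_true(all(kd$usp18 == 0))
})

test_that("protocol builders produce the reference interval layouts", {
  expect_equal(unclass(pretreatment_program(24, 8, 10)),
               unclass(input_program(c(0, 32), c(24, 42))))
  expect_equal(unclass(pretreatment_program(2, 8, 10)),
               unclass(input_program(c(0, 10), c(2, 20))))
  expect_equal(unclass(pretreatment_program(0, 8, 10)),
               unclass(input_program(8, 18)))
  expect_equal(unclass(pulse_program(5, 8, 8)),
               unclass(input_program(c(0, 16, 32, 48, 64),
                                     c(8, 24, 40, 56, 72))))
  expect_equal(unclass(pulse_program(1, 40, 0)),
               unclass(input_program(0, 40)))
  expect_equal(nrow(pulse_program(2, 1, 0)), 1L)  # zero-gap merge
  expect_error(pretreatment_program(-1, 8, 10))
})

test_that("pulsatile input out-induces sustained input unless USP18 is absent", {
  p <- ifn_params()
  final_irf9 <- function(prog, variant = NULL) {
    tr <- simulate_pathway(p, prog, variant = variant, t_end = 72,
                           dt = 0.005, thin = 2000)
    tr$irf9[nrow(tr)]
  }
  pulses <- pulse_program(5, 8, 8)
  sustained <- pulse_program(1, 40, 0)
  expect_gt(final_irf9(pulses), final_irf9(sustained))
  kd <- model_variant(usp18_knockdown = TRUE)
  expect_equal(final_irf9(pulses, kd), final_irf9(sustained, kd),
               tolerance = 1e-9)
})
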