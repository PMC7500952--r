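test_that("zero noise reproduces the deterministic trajectory exactly", {
  p <- ifn_params()
  prog <- pretreatment_program(10, 8, 10)
  pol <- gating_policy("cell_cycle", T_cycle = 21.82, w = 7.3, t0 = 12)
  set.seed(1)
  sde <- simulate_cell(p, prog, pol, noise = noise_config(0, 0),
                       t_end = 28, dt = 0.01, thin = 10)
  det <- simulate_pathway(p, prog, policy = pol, t_end = 28, dt = 0.01,
                          thin = 10)
  expect_equal(sde$irf9, det$irf9)
  expect_equal(sde$usp18, det$usp18)
})

test_that("stochastic runs are seed-reproducible and non-negative", {
  p <- ifn_params()
  prog <- input_program(0, 20)
  pol <- gating_policy("fixed_delay", tau = 8)
  run <- function() simulate_cell(p, prog, pol, noise = noise_config(),
                                  t_end = 20, dt = 0.01, thin = 10)
  set.seed(99); a <- run()
  set.seed(99); b <- run()
  expect_identical(a$irf9, b$irf9)
  expect_identical(a$usp18, b$usp18)
  set.seed(100); c <- run()
  expect_false(identical(a$irf9, c$irf9))
  expect_true(all(a$irf9 >= 0) && all(a$usp18 >= 0))
})

test_that("without input the noise-only state stays clamped near zero", {
  p <- ifn_params()
  set.seed(5)
  finals <- replicate(100, {
    tr <- simulate_cell(p, input_program(), gating_policy("always_on"),
                        noise = noise_config(250, 1000),
                        t_end = 5, dt = 0.01, thin = 500)
    tr$irf9[nrow(tr)]
  })
  expect_true(all(finals >= 0))
  # reflected-at-zero random walk: endpoints stay on the noise scale
  # (sigma * dt * sqrt(n_steps)), far below any induced signal
  walk_sd <- 250 * 0.01 * sqrt(5 / 0.01)
  expect_lt(mean(finals), 3 * walk_sd)
})

test_that("the two noise conventions scale increments as dt vs sqrt(dt)", {
  p <- ifn_params(k1 = 0, k4 = 0, k5 = 0)  # pure noise around a high state
  prog <- input_program()
  pol <- gating_policy("always_on")
  final_dev <- function(conv) {
    tr <- simulate_pathway(p, prog, policy = pol, t_end = 0.1, dt = 0.01,
                           noise = noise_config(100, 0, convention = conv),
                           thin = 10, irf9_0 = 1e6)
    tr$irf9[nrow(tr)] - 1e6
  }
  set.seed(8)
  pe <- replicate(150, final_dev("plain_euler"))
  em <- replicate(150, final_dev("euler_maruyama"))
  # var ratio should be ~dt = 0.01 (10 steps of (sigma*dt)^2 vs sigma^2*dt)
  ratio <- stats::var(pe) / stats::var(em)
  expect_gt(ratio, 0.004)
  expect_lt(ratio, 0.025)
})

test_that("a fully open gate with zero noise gives identical cells", {
  coh <- simulate_cohort(ifn_params(), pre_durations = c(2, 24),
                         n_cells = 15, gating = list(T_cycle = 21.82,
                                                     w = 21.82),
                         noise = noise_config(0, 0), dt = 0.02, seed = 3,
                         horizon = 20)
  for (cc in unique(coh$cells$condition)) {
    s <- coh$cells[coh$cells$condition == cc, ]
    expect_equal(length(unique(s$usp18_end_break)), 1L)
    expect_equal(length(unique(s$irf9_induction)), 1L)
    expect_true(all(s$delay_h == 0))
  }
})

test_that("longer pretreatment opens the gate in more cells", {
  coh <- simulate_cohort(ifn_params(), pre_durations = c(2, 10, 24),
                         n_cells = 150, noise = noise_config(0, 0),
                         dt = 0.02, seed = 4, horizon = 20)
  m <- tapply(coh$cells$usp18_end_break, coh$cells$condition, mean)
  m <- m[c("pre_2h", "pre_10h", "pre_24h")]
  expect_true(all(diff(m) > 0))
})

test_that("cohort summaries compute CV and correlation correctly", {
  fake <- structure(list(cells = data.frame(
    condition = rep(c("a", "b"), each = 4), cell_id = rep(1:4, 2),
    onset_phase_h = 0, delay_h = 0,
    usp18_end_break = c(rep(5, 4), 1:4),
    irf9_induction = c(rep(2, 4), 4:1))), class = "ifn_cohort")
  s <- summary(fake)
  expect_equal(s$by_condition$cv_usp18[s$by_condition$condition == "a"], 0)
  expect_equal(s$by_condition$cv_irf9_induction[
    s$by_condition$condition == "a"], 0)
  # condition b lies on an exact anticorrelated line
  sb <- fake$cells[fake$cells$condition == "b", ]
  expect_equal(cor(sb$usp18_end_break, sb$irf9_induction), -1)
  # zero-mean CV flagged undefined, not NaN
  fake$cells$usp18_end_break <- 0
  expect_true(is.na(summary(fake)$by_condition$cv_usp18[1]))
})
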