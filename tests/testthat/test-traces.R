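test_that("smoothed derivatives recover slopes of simple traces", {
  t <- seq(0, 10, by = 0.5)
  d <- smoothed_derivative(3 * t + 2, t)
  # exact away from the edge-padded region (half-window + 1 samples)
  expect_equal(d[4:(length(d) - 3)], rep(3, length(d) - 6), tolerance = 1e-9)
  expect_equal(smoothed_derivative(rep(4, 21), t), rep(0, 21))
  expect_error(smoothed_derivative(1:5, (1:5)^2), "uniform")
  expect_error(smoothed_derivative(1:5, 1:5, window = 4), "odd")
  expect_error(smoothed_derivative(1:5, 1:5, window = 7), "longer")
  # smoothing suppresses noise in the derivative
  set.seed(1)
  tn <- seq(0, 40, by = 0.25)
  noisy <- 5 * tn + rnorm(length(tn), 0, 3)
  expect_lt(sd(smoothed_derivative(noisy, tn, window = 9)),
            sd(smoothed_derivative(noisy, tn, window = 3)))
})

test_that("activation calls land on the ramp start and censor flat traces", {
  t <- seq(-2, 30, by = 1 / 3)
  ramp <- 100 + pmax(t - 5.1, 0) * 800
  call <- call_activation_time(ramp, t)
  expect_false(call$censored)
  expect_lt(abs(call$time - 5.1), 1 / 3 + 1e-9)
  flat <- call_activation_time(rep(100, length(t)), t)
  expect_true(flat$censored)
  expect_true(is.na(flat$time))
  expect_error(call_activation_time(ramp, t + 10), "baseline")
})

test_that("delay times subtract activation calls and propagate censoring", {
  expect_equal(delay_time(7.9008, 12.1620), 4.2612)
  expect_equal(delay_time(3, 3), 0)
  t <- seq(-2, 30, by = 0.5)
  a <- call_activation_time(100 + pmax(t - 4, 0) * 500, t)
  b <- call_activation_time(rep(100, length(t)), t)
  expect_true(is.na(delay_time(a, b)))
  expect_lt(abs(delay_time(a, call_activation_time(
    100 + pmax(t - 9, 0) * 500, t)) - 5), 1 + 1e-9)
})

test_that("cell-cycle progression uses the bracketing divisions", {
  expect_equal(percent_progression(20, c(10, 30))$percent, 50)
  expect_equal(percent_progression(10, c(10, 30))$percent, 0)
  expect_equal(percent_progression(7.3, c(0, 21.82))$percent, 33.5,
               tolerance = 0.01)
  out <- percent_progression(40, c(10, 30))
  expect_true(out$censored)
  expect_match(out$reason, "bracketed")
  # shift invariance
  expect_equal(percent_progression(20, c(10, 30))$percent,
               percent_progression(120, c(110, 130))$percent)
})

test_that("delay-group classification splits at the threshold", {
  g <- classify_delay_groups(c(2, 11, 12, 3), 10)
  expect_equal(unname(g$fractions["group2"]), 0.5)
  expect_equal(as.character(g$labels), c("group1", "group2", "group2",
                                         "group1"))
  expect_equal(classify_delay_groups(rep(0, 5))$fractions[["group2"]], 0)
  # negative measured delays stay in group 1; NA delays stay unclassified
  g2 <- classify_delay_groups(c(-1, NA, 15), 10)
  expect_equal(as.character(g2$labels), c("group1", NA, "group2"))
  expect_equal(unname(g2$fractions["group2"]), 0.5)
  # fractions are monotone non-increasing in the threshold
  d <- c(0, 0, 3, 8, 11, 14, 20)
  fr <- sapply(c(0, 5, 10, 15), function(th)
    classify_delay_groups(d, th)$fractions[["group2"]])
  expect_true(all(diff(fr) <= 0))
})

test_that("induction amounts difference the window ends and normalize", {
  t <- 0:20
  expect_equal(induction_amount(rep(7, 21), t, 2, 8), 0)
  expect_equal(induction_amount(5 * t, t, 2, 8), 30)
  expect_equal(induction_amount(5 * t, t, 2, 8, reference = 30), 1)
  expect_error(induction_amount(5 * t, t, -1, 8), "outside")
})

test_that("cohort summaries report means, CIs, CVs and group fractions", {
  rec <- data.frame(act_irf9_h = c(5, 5, 5), act_usp18_h = c(7, 7, 7),
                    delay_h = c(2, 2, 2))
  s <- cohort_summary(rec)
  row <- s$stats[s$stats$column == "act_irf9_h", ]
  expect_equal(row$cv, 0)
  expect_equal(row$ci_lo, row$ci_hi)
  expect_equal(s$group2_fraction, 0)
  rec2 <- data.frame(a = c(1, 2, 3), b = c(3, 2, 1))
  s2 <- cohort_summary(rec2, columns = "a",
                       cor_pairs = list(c("a", "b")))
  expect_equal(unname(s2$correlations), -1)
})
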