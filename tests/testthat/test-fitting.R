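# fits in unit tests run at a coarser Euler step and tiny multistart;
# accuracy-sensitive recovery checks live in the acceptance suite
DT <- 0.005

test_that("the objective is zero at the generating parameters and scales with weights", {
  p <- ifn_params()
  ds <- generate_fitting_dataset(p, tau = 8, dt = DT)
  expect_equal(sse_objective(ds, p, 8, dt = DT), 0)
  # wrong parameters give a positive error
  expect_gt(sse_objective(ds, ifn_params(k4 = 200), 8, dt = DT), 0)
  # doubling the endpoint weight doubles the endpoint block of the SSE
  ds1 <- ifn_dataset(ds$trace[0, ], ds$endpoints, endpoint_weight = 10)
  ds2 <- ifn_dataset(ds$trace[0, ], ds$endpoints, endpoint_weight = 20)
  bad <- ifn_params(k3 = 500)
  expect_equal(2 * sse_objective(ds1, bad, 8, dt = DT),
               sse_objective(ds2, bad, 8, dt = DT))
})

test_that("single-observation residuals square as expected", {
  p <- ifn_params()
  t_obs <- 6
  pred <- simulate_pathway(p, input_program(0, 10), t_end = 10,
                           dt = DT, thin = 1200)$irf9[2]  # state at t = 6
  v <- pred + 500
  ds <- ifn_dataset(data.frame(time_h = t_obs, value = v),
                    data.frame(pre_duration_h = numeric(),
                               induction_norm = numeric()))
  # residual is scaled by the mean trace value (here the observation itself)
  expect_equal(sse_objective(ds, p, 8, dt = DT), (500 / v)^2,
               tolerance = 1e-6)
})

test_that("gaussian log-likelihood matches its closed forms", {
  expect_equal(gaussian_loglik(0, sigma = 1), -0.5 * log(2 * pi))
  expect_equal(gaussian_loglik(0, sigma = sqrt(1 / (2 * pi))), 0)
  r <- c(0.3, -1.2, 0.8, 2.1)
  n <- length(r); sse <- sum(r^2)
  expect_equal(gaussian_loglik(r, sigma = "mle"),
               -(n / 2) * (log(2 * pi * sse / n) + 1))
  expect_equal(gaussian_loglik(r, sigma = 2),
               -(n / 2) * log(2 * pi * 4) - sse / 8)
  expect_error(gaussian_loglik(r, sigma = -1), "positive")
})

test_that("noiseless parameter recovery reproduces the data at the prediction level", {
  p <- ifn_params()
  ds <- generate_fitting_dataset(p, tau = 8, dt = DT)
  fit <- fit_kinetics(ds, tau = 8, n_starts = 8, seed = 42, dt = DT)
  # observation magnitude in residual units (relative trace residuals are
  # O(1) per point), so this is a prediction-level recovery bound
  wsum <- nrow(ds$trace) +
    ds$endpoint_weight * sum(ds$endpoints$induction_norm^2)
  expect_lt(fit$sse, 1e-6 * wsum)
  expect_s3_class(fit$params, "ifn_params")
  expect_true(all(coef(fit)[1:5] >= 0))
})

test_that("the full model never fits worse than its ablations (nested on clean data)", {
  p <- ifn_params()
  ds <- generate_fitting_dataset(p, tau = 8, dt = DT)
  full <- fit_kinetics(ds, tau = 8, n_starts = 8, seed = 1, dt = DT)
  no_pf <- fit_kinetics(ds, tau = 8, n_starts = 8, seed = 1, dt = DT,
                        variant = model_variant(positive_feedback = FALSE))
  no_nf <- fit_kinetics(ds, tau = 8, n_starts = 8, seed = 1, dt = DT,
                        variant = model_variant(negative_feedback = FALSE))
  expect_lte(full$sse, no_pf$sse + 1e-8)
  expect_lte(full$sse, no_nf$sse + 1e-8)
  # the ablated fits drop the corresponding kinetic constant
  expect_false("k2" %in% no_pf$free)
  expect_false("k3" %in% no_nf$free)
})

test_that("the delay scan picks the generating delay on a local grid", {
  p <- ifn_params()
  ds <- generate_fitting_dataset(p, tau = 8, dt = DT)
  sc <- scan_tau(ds, taus = c(5, 8, 11), n_starts = 4, seed = 2, dt = DT)
  expect_equal(sc$best_tau, 8)
  expect_equal(nrow(sc$results), 3L)
  expect_true(all(diff(sc$results$tau) > 0))
  expect_equal(min(sc$results$sse), sc$results$sse[sc$results$tau == 8])
})

test_that("AIC comparison is internally consistent and favours the generator", {
  p <- ifn_params()
  ds <- generate_fitting_dataset(p, tau = 8, noise_frac = 0.05, seed = 9,
                                 dt = DT)
  cmp <- compare_models_aic(ds, tau = 8, n_starts = 6, seed = 9, dt = DT)
  tab <- cmp$table
  expect_equal(tab$aic, 2 * tab$k - 2 * tab$loglik)
  expect_equal(tab$k[tab$variant == "full"], 6)          # 5 kinetic + sigma
  expect_true(all(tab$k[tab$variant != "full"] == 5))
  expect_equal(cmp$best, tab$variant[which.min(tab$aic)])
  expect_equal(cmp$best, "full")
  # likelihood/SSE consistency: same data, same n -> SSE order = -lnL order
  expect_equal(order(tab$sse), order(-tab$loglik))
})
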