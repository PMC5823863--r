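test_that("model evaluation matches closed forms", {
  m <- fcs_model("3D", total_n = 0.241, tau_d = 140e-6, S = 5)
  # amplitude definition at tau = 0
  expect_equal(eval_model(m, 0), 1 / 0.241)
  # at tau = tau_D: (1/2) (1 + 1/S^2)^(-1/2) = 0.49029.../N
  expect_equal(eval_model(m, 140e-6), 0.4902903378 / 0.241, tolerance = 1e-9)
  m2 <- fcs_model("2D", total_n = 2, tau_d = 1e-3)
  expect_equal(eval_model(m2, 1e-3), 0.5 / 2)
  # offset shifts uniformly
  m3 <- fcs_model("3D", total_n = 1, tau_d = 1e-4, S = 5, offset = 0.1)
  expect_equal(eval_model(m3, 0), 1.1)
})

test_that("a 3D+2D model with zero 2D fraction equals the pure 3D model", {
  taus <- 10^seq(-6, 0, length.out = 60)
  pure <- fcs_model("3D", total_n = 0.5, tau_d = 140e-6, S = 5)
  mixed <- fcs_model(c("3D", "2D"), total_n = 0.5, tau_d = c(140e-6, 2e-2),
                     fractions = c(1, 0), S = 5)
  expect_equal(eval_model(mixed, taus), eval_model(pure, taus))
})

test_that("G decreases strictly in lag and approaches the offset", {
  m <- fcs_model(c("3D", "2D"), total_n = 1, tau_d = c(1e-4, 1e-2),
                 fractions = c(0.6, 0.4), S = 5, offset = 0)
  taus <- 10^seq(-7, 2, length.out = 200)
  g <- eval_model(m, taus)
  expect_true(all(diff(g) < 0))
  expect_lt(g[length(g)], 1e-3)
})

test_that("noiseless single-3D curves are recovered exactly", {
  truth <- fcs_model("3D", total_n = 0.241, tau_d = 140e-6, S = 5)
  curve <- analytic_acf(truth, 10^seq(-5.5, -0.5, length.out = 80))
  fit <- fit_acf(curve, "3D", fixed = list(S = 5, offset = 0))
  expect_true(fit$converged)
  expect_equal(fit$model$total_n, 0.241, tolerance = 1e-6)
  expect_equal(fit$model$tau_d, 140e-6, tolerance = 1e-6)
})

test_that("fits on noisy analytic curves recover N and tau_D within 5%", {
  truth <- fcs_model("3D", total_n = 0.241, tau_d = 140e-6, S = 5)
  taus <- 10^seq(-5.5, -0.5, length.out = 80)
  g0 <- eval_model(truth, taus)
  set.seed(11)
  res <- replicate(20, {
    curve <- acf_curve(taus, g0 * (1 + rnorm(length(g0), 0, 0.01)))
    fit <- fit_acf(curve, "3D", fixed = list(S = 5))
    c(fit$model$total_n, fit$model$tau_d)
  })
  expect_lt(abs(median(res[1, ]) / 0.241 - 1), 0.05)
  expect_lt(abs(median(res[2, ]) / 140e-6 - 1), 0.05)
})

test_that("fixed 3D dwell time is honoured and recorded", {
  truth <- fcs_model(c("3D", "2D"), total_n = 1, tau_d = c(140e-6, 2e-2),
                     fractions = c(0.5, 0.5), S = 5)
  curve <- analytic_acf(truth, 10^seq(-5.5, 0.5, length.out = 90))
  fit <- fit_acf(curve, c("3D", "2D"),
                 fixed = list(tau_d = c(140e-6, NA), S = 5, offset = 0))
  expect_equal(fit$model$tau_d[1], 140e-6)
  expect_equal(fit$fixed$tau_d[1], 140e-6)
  expect_equal(fit$model$tau_d[2], 2e-2, tolerance = 1e-4)
  expect_equal(fit$model$fractions[2], 0.5, tolerance = 1e-4)
})

test_that("fitting is invariant under uniform lag rescaling", {
  truth <- fcs_model("3D", total_n = 0.8, tau_d = 140e-6, S = 5)
  taus <- 10^seq(-5.5, -1, length.out = 60)
  f1 <- fit_acf(analytic_acf(truth, taus), "3D", fixed = list(S = 5, offset = 0))
  # same curve with lags in ms-equivalent scaled seconds
  scaled <- acf_curve(taus * 1000, eval_model(truth, taus))
  f2 <- fit_acf(scaled, "3D", fixed = list(S = 5, offset = 0))
  expect_equal(f2$model$total_n, f1$model$total_n, tolerance = 1e-5)
  expect_equal(f2$model$tau_d / 1000, f1$model$tau_d, tolerance = 1e-5)
})

test_that("fit refuses under-determined problems", {
  truth <- fcs_model("3D", total_n = 1, tau_d = 1e-4, S = 5)
  curve <- analytic_acf(truth, 10^seq(-5, -2, length.out = 6))
  expect_error(fit_acf(curve, "3D", fixed = list(S = 5)), "5 more lags")
})

test_that("model selection prefers one 2D component on parsimony", {
  truth <- fcs_model(c("3D", "2D"), total_n = 1, tau_d = c(140e-6, 2e-2),
                     fractions = c(0.4, 0.6), S = 5)
  curve <- analytic_acf(truth, 10^seq(-5.5, 0.5, length.out = 90))
  sel <- select_membrane_model(curve, fixed_tau3d = 140e-6, S = 5)
  expect_identical(sel$selection$chosen, "3D+2D")
  expect_match(sel$selection$rationale, "1x2D")
})

test_that("model selection finds a second, well-separated 2D component", {
  truth <- fcs_model(c("3D", "2D", "2D"), total_n = 1,
                     tau_d = c(140e-6, 5e-3, 2e-1),
                     fractions = c(0.2, 0.4, 0.4), S = 5)
  taus <- 10^seq(-5.5, 0.7, length.out = 110)
  g0 <- eval_model(truth, taus)
  set.seed(4)
  picks <- replicate(10, {
    curve <- acf_curve(taus, g0 * (1 + rnorm(length(g0), 0, 0.02)))
    sel <- select_membrane_model(curve, fixed_tau3d = 140e-6, S = 5)
    identical(sel$selection$chosen, "3D+2D+2D")
  })
  expect_gte(mean(picks), 0.8)
})
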