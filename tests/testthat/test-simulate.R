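test_that("config validation enforces the physical contracts", {
  expect_error(solution_sim_config(-1), "concentration")
  expect_error(solution_sim_config(1.8, duration = 0.01), "1000 bins")
  expect_error(solution_sim_config(1.8, box_scale = 2), "box_scale")
  expect_error(membrane_sim_config(1.8, surface_density = -1), "surface_density")
  expect_error(membrane_sim_config(1.8, brightness_ratio = 0), "brightness_ratio")
  # resource guard against runaway particle-bin updates
  expect_error(
    simulate_solution_trace(
      solution_sim_config(5e4, duration = 20, bin_width = 1e-5)),
    "1e9")
})

test_that("zero brightness yields pure Poisson background counts", {
  cfg <- solution_sim_config(1.8, brightness_eps = 0, background_rate = 5e4,
                             duration = 2, seed = 8)
  tr <- simulate_solution_trace(cfg)
  lambda <- 5e4 * cfg$bin_width
  n <- length(tr$counts)
  expect_lt(abs(mean(tr$counts) - lambda), 4 * sqrt(lambda / n))
  # index of dispersion ~ 1 for Poisson
  expect_lt(abs(var(tr$counts) / mean(tr$counts) - 1), 0.05)
})

test_that("simulation is byte-identical for identical seeds", {
  cfg <- quick_solution_config(20, seed = 123, duration = 1)
  t1 <- simulate_solution_trace(cfg)
  t2 <- simulate_solution_trace(cfg)
  expect_identical(t1$counts, t2$counts)
  t3 <- simulate_solution_trace(quick_solution_config(20, seed = 124,
                                                      duration = 1))
  expect_false(identical(t1$counts, t3$counts))
})

test_that("mean trace rate matches the detection-profile expectation", {
  # <rate> = eps * lambda_box * <W>_box + background, averaged over seeds
  cfg0 <- quick_solution_config(20, duration = 1)
  w0 <- cfg0$beam_waist_w0; z0 <- cfg0$axial_radius_z0
  box <- c(2 * 4 * w0, 2 * 4 * w0, 2 * 4 * z0)
  v_box <- prod(box)
  lam <- 20 * 1e-9 * 1e3 * 6.02214076e23 * v_box
  mean_w <- (pi / 2)^1.5 * w0^2 * z0 / v_box   # boundary truncation negligible
  expected <- cfg0$brightness_eps * lam * mean_w
  rates <- sapply(1:20, function(s)
    mean_rate(simulate_solution_trace(quick_solution_config(20, seed = 500 + s,
                                                            duration = 1))))
  expect_lt(abs(mean(rates) - expected), 3 * sd(rates) / sqrt(20))
})

test_that("doubling concentration doubles the mean intensity", {
  r1 <- sapply(1:15, function(s)
    mean_rate(simulate_solution_trace(quick_solution_config(10, seed = 700 + s,
                                                            duration = 1))))
  r2 <- sapply(1:15, function(s)
    mean_rate(simulate_solution_trace(quick_solution_config(20, seed = 900 + s,
                                                            duration = 1))))
  ratio <- mean(r2) / mean(r1)
  se <- ratio * sqrt((sd(r2) / mean(r2))^2 + (sd(r1) / mean(r1))^2) / sqrt(15)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("simulated ACF matches the analytic curve within the sampling bound", {
  cfg <- solution_sim_config(45.7, duration = 20, seed = 31)
  tr <- simulate_solution_trace(cfg)
  mt <- multitau_autocorrelate(tr)
  truth <- fcs_model("3D", total_n = expected_particle_numbers(cfg)$n_3d,
                     tau_d = cfg$beam_waist_w0^2 / (4 * cfg$diffusion_coeff),
                     S = cfg$axial_radius_z0 / cfg$beam_waist_w0)
  keep <- mt$lags < 0.05
  dif <- abs(mt$g[keep] - eval_model(truth, mt$lags[keep]))
  expect_lt(max(dif) / eval_model(truth, 0), 0.1)
})

test_that("membrane simulation with zero surface density equals solution", {
  mcfg <- membrane_sim_config(20, surface_density = 0, duration = 1, seed = 77)
  scfg <- quick_solution_config(20, seed = 77, duration = 1)
  expect_identical(simulate_membrane_trace(mcfg)$counts,
                   simulate_solution_trace(scfg)$counts)
})

test_that("mixed membrane traces yield the brightness-weighted apparent fraction", {
  # equal molecular brightness, N_3D = 0.241, N_2D = 0.36: the lateral-only
  # detection of the planar species raises its apparent per-particle
  # brightness by sqrt(2), so the amplitude share is 2*N2/(N1 + 2*N2) = 0.749
  w0 <- 0.2e-6
  res <- sapply(1:5, function(s) {
    cfg <- membrane_sim_config(1.8, surface_density = 0.36 / (pi * w0^2),
                               diffusion_coeff_2d = 5e-13, brightness_ratio = 1,
                               duration = 20, seed = 40 + s, box_scale = 8)
    fit <- fit_acf(multitau_autocorrelate(simulate_membrane_trace(cfg)),
                   c("3D", "2D"), fixed = list(tau_d = c(140e-6, NA), S = 5))
    c(fit$model$fractions[2], fit$model$tau_d[2])
  })
  phi_true <- 2 * 0.36 / (0.241 + 2 * 0.36)
  expect_lt(abs(median(res[1, ]) / phi_true - 1), 0.2)
  expect_lt(abs(median(res[2, ]) / 0.02 - 1), 0.2)
})

test_that("brightness-corrected membrane particle numbers recover the truth", {
  # molecular ratio 9.1 -> apparent ratio sqrt(2)*9.1; the bright membrane
  # species dominates the amplitude and its corrected number is recoverable
  # (the dim 3D species carries <1% of the amplitude at this contrast)
  w0 <- 0.2e-6
  n2s <- sapply(1:5, function(s) {
    cfg <- membrane_sim_config(1.8, surface_density = 0.36 / (pi * w0^2),
                               diffusion_coeff_2d = 5e-13,
                               brightness_ratio = 9.1,
                               duration = 20, seed = 240 + s, box_scale = 8)
    fit <- fit_acf(multitau_autocorrelate(simulate_membrane_trace(cfg)),
                   c("3D", "2D"), fixed = list(tau_d = c(140e-6, NA), S = 5))
    correct_two_species_numbers(fit$model$total_n, fit$model$fractions[2],
                                r = sqrt(2) * 9.1)$n_2d
  })
  expect_lt(abs(median(n2s) / 0.36 - 1), 0.2)
})

test_that("a 2D-only membrane trace recovers the 2D dwell time", {
  d2 <- 5e-13
  sigma <- 1.5 / (pi * (0.2e-6)^2)   # ~1.5 particles in the detection area
  res <- sapply(1:5, function(s) {
    cfg <- membrane_sim_config(0, surface_density = sigma,
                               diffusion_coeff_2d = d2, duration = 20,
                               seed = 130 + s)
    fit <- fit_acf(multitau_autocorrelate(simulate_membrane_trace(cfg)), "2D")
    c(fit$model$tau_d, fit$model$total_n)
  })
  tau_true <- (0.2e-6)^2 / (4 * d2)   # 20 ms
  expect_lt(abs(median(res[1, ]) / tau_true - 1), 0.2)
  expect_lt(abs(median(res[2, ]) / 1.5 - 1), 0.35)
})
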