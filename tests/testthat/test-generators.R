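test_that("noise-free gradient equals the configured true curve exactly", {
  cfg <- gradient_config(noise_cv = 0, seed = 2)
  d <- suppressWarnings(generate_gradient_dataset(cfg))
  high <- d[d$condition == "receptor_high" & d$time_min == 120, ]
  # at the 2-um reference distance and final time: exactly c_near
  expect_equal(unique(high$conc_nM[high$distance_um == 2]), 45.7)
  # exponential decay towards c_bulk with the configured length
  expected <- 1.5 + (45.7 - 1.5) * exp(-(high$distance_um - 2) / 15)
  expect_equal(high$conc_nM, expected, tolerance = 1e-12)
})

test_that("gradient means decrease with distance and rise over time", {
  cfg <- gradient_config(seed = 4)
  d <- generate_gradient_dataset(cfg)
  for (cond in unique(d$condition)) {
    prof <- build_profile(d, cond, axis = "distance", at = 120)
    # true means are monotone; sample means within a tolerant envelope
    expect_lt(prof$mean_conc[nrow(prof)], prof$mean_conc[1])
    tprof <- build_profile(d, cond, axis = "time", at = 2)
    if (cond != "no_cell")
      expect_gt(tprof$mean_conc[nrow(tprof)], 0.6 * tprof$mean_conc[1])
  }
  # noise-free check of strict monotonicity of the generating curves
  cfg0 <- gradient_config(noise_cv = 0, seed = 4)
  d0 <- suppressWarnings(generate_gradient_dataset(cfg0))
  p0 <- build_profile(d0, "receptor_high", axis = "distance", at = 120)
  expect_true(all(diff(p0$mean_conc) <= 0))
  t0 <- build_profile(d0, "receptor_high", axis = "time", at = 2)
  expect_true(all(diff(t0$mean_conc) >= 0))
})

test_that("far-field gradient approaches the bulk concentration", {
  cfg <- gradient_config(noise_cv = 0,
                         distances = c(2, 50, 500, 5000), seed = 1)
  d <- suppressWarnings(generate_gradient_dataset(cfg))
  far <- d[d$condition == "receptor_high" & d$distance_um == 5000 &
             d$time_min == 120, ]
  expect_equal(unique(far$conc_nM), 1.5, tolerance = 1e-6)
})

test_that("default generator reproduces the printed near/bulk levels", {
  d <- generate_gradient_dataset(gradient_config(seed = 6))
  prof <- build_profile(d, "receptor_high", axis = "distance", at = 120)
  near <- prof[prof$position == 2, ]
  bulk <- prof[prof$position == 200, ]
  expect_equal(near$n, 13)
  expect_lt(abs(near$mean_conc - 45.7), 2 * near$sem_conc)
  expect_lt(abs(bulk$mean_conc - 1.5), max(2 * bulk$sem_conc, 0.3))
})

test_that("gradient generation is seed-stable and extends without reshuffling", {
  cfg <- gradient_config(seed = 9)
  d1 <- generate_gradient_dataset(cfg)
  d2 <- generate_gradient_dataset(cfg)
  expect_identical(d1, d2)
  # growing n_cells must not change earlier cells' draws
  conds <- default_gradient_conditions()
  conds$n_cells <- conds$n_cells + 5L
  bigger <- generate_gradient_dataset(gradient_config(conditions = conds,
                                                      seed = 9))
  small_cells <- unique(d1$cell_id)
  expect_identical(d1$conc_nM,
                   bigger$conc_nM[bigger$cell_id %in% small_cells])
})

test_that("concentration floor clips with a warning", {
  conds <- default_gradient_conditions()[3, ]
  cfg <- gradient_config(conditions = conds, noise_cv = 0.9999)
  expect_error(gradient_config(conditions = conds, noise_cv = 1), "noise_cv")
  cfg <- gradient_config(conditions = conds, noise_cv = 0.95,
                         conc_floor_nM = 1, seed = 3)
  expect_warning(d <- generate_gradient_dataset(cfg), "clipped")
  expect_true(all(d$conc_nM >= 1))
})

test_that("association generator obeys the binding identities", {
  cfg <- binding_config(noise_sd = 0, seed = 1)
  # kon implied by koff/kd
  expect_equal(cfg$kon, 0.04 / 1.8e-9, tolerance = 1e-12)
  tcs <- generate_association_timecourses(cfg)
  at_kd <- tcs[[which(sapply(tcs, `[[`, "ligand_conc_nM") == 1.8)]]
  spec <- specific_binding(at_kd$ratio_total, at_kd$ratio_nsb)
  # half-saturation plateau at L = kd
  expect_equal(spec[length(spec)], 400 / 2 * (1 - exp(-2 * 0.04 * 60)),
               tolerance = 1e-9)
  # observed rate at L = kd is exactly 2*koff
  kob <- oracle_kob(at_kd$times_min, spec)
  expect_equal(kob, 2 * 0.04, tolerance = 1e-3)
})

test_that("noiseless saturation data round-trips through the fitter", {
  cfg <- binding_config(noise_sd = 0, seed = 1)
  sat <- generate_saturation_dataset(cfg)
  fit <- fit_saturation(sat)
  expect_true(fit$converged)
  expect_equal(fit$kd, 1.8, tolerance = 1e-6)
  expect_equal(fit$bmax, 400, tolerance = 1e-6)
  # specific signal at kd is half the plateau
  idx <- which.min(abs(sat$ligand_concs_nM - 1.8))
  spec <- specific_binding(sat$totals, sat$nsbs)
})

test_that("binding generators are deterministic in the seed", {
  c1 <- generate_saturation_dataset(binding_config(seed = 5))
  c2 <- generate_saturation_dataset(binding_config(seed = 5))
  expect_identical(c1, c2)
  a1 <- generate_association_timecourses(binding_config(seed = 5))
  a2 <- generate_association_timecourses(binding_config(seed = 5))
  expect_identical(a1, a2)
})

test_that("noisy saturation data recover kd near 1.8 nM over seeds", {
  kds <- sapply(1:60, function(s) {
    fit_saturation(generate_saturation_dataset(binding_config(seed = s)))$kd
  })
  expect_lt(abs(median(kds) / 1.8 - 1), 0.10)
})
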