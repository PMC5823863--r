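# Shared fixtures and independent oracles used across the test files.

V_EFF_GAUSS_L <- pi^1.5 * (0.2e-6)^2 * 1e-6 * 1e3  # 0.2227 fL reference volume

# short, fast solution config used where the physics, not the precision,
# is under test
quick_solution_config <- function(conc = 20, seed = 1L, duration = 2, ...) {
  solution_sim_config(conc, duration = duration, seed = seed, ...)
}

# fit a solution trace and return the calibrated concentration (nM), using
# the true simulation geometry for the effective volume
recover_concentration <- function(conc, seed, duration = 20) {
  cfg <- solution_sim_config(conc, duration = duration, seed = seed)
  fit <- fit_acf(multitau_autocorrelate(simulate_solution_trace(cfg)),
                 "3D", fixed = list(S = 5))
  concentration_from_N(fit$model$total_n, V_EFF_GAUSS_L)
}

# brute-force forward map of the two-species brightness-weighted amplitudes:
# apparent per-component amplitudes of an equal-brightness fit applied to a
# mixture with true numbers (n1, n2) and brightness ratio r
apparent_amplitudes <- function(n1, n2, r) {
  tot <- n1 + r * n2
  c(a1 = n1 / tot^2, a2 = n2 * r^2 / tot^2)
}

# independent single-curve observed-rate oracle: dense grid scan over kob
# with plateau solved linearly at each candidate
oracle_kob <- function(times, y, grid = 10^seq(-4, 2, length.out = 4000)) {
  rss <- vapply(grid, function(kob) {
    basis <- 1 - exp(-kob * times)
    amp <- sum(basis * y) / sum(basis^2)
    sum((y - amp * basis)^2)
  }, numeric(1))
  grid[which.min(rss)]
}
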