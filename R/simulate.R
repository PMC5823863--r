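#' Configuration for a solution-phase trace simulation
#'
#' Physical stand-in for an FCS read in bulk solution: point emitters at
#' concentration `concentration_nM` diffuse by Brownian steps (per-axis step
#' SD `sqrt(2 D dt)`) in a periodic box, are weighted by the 3D Gaussian
#' detection profile `exp(-2(x^2+y^2)/w0^2 - 2 z^2/z0^2)`, and the summed
#' emission rate is Poisson-sampled per bin. The number of particles in the
#' box is drawn once per trace as `Poisson(C N_A V_box)` (open-system
#' statistics), so the expected amplitude is exactly `1/(C N_A V_eff)`.
#'
#' @param concentration_nM ligand concentration in nM (> 0).
#' @param diffusion_coeff diffusion coefficient in m^2/s (> 0).
#' @param beam_waist_w0 lateral 1/e^2 radius in m (default 0.2e-6).
#' @param axial_radius_z0 axial 1/e^2 radius in m (default 1e-6).
#' @param brightness_eps molecular brightness at focus, counts/s/molecule.
#' @param background_rate uncorrelated background, counts/s (default 0).
#' @param bin_width sampling bin in s (default 40e-6).
#' @param duration trace length in s (>= 1000 bins).
#' @param box_scale box half-width as a multiple of w0 (lateral) and z0
#'   (axial); >= 4 so the detection profile is negligible at the boundary.
#' @param seed integer RNG seed; the simulation stream is fully determined by
#'   it.
#' @return list of class `solution_sim_config`.
#' @export
solution_sim_config <- function(concentration_nM,
                                diffusion_coeff = 7.14e-11,
                                beam_waist_w0 = 0.2e-6,
                                axial_radius_z0 = 1e-6,
                                brightness_eps = 5e4,
                                background_rate = 0,
                                bin_width = 40e-6,
                                duration = 20,
                                box_scale = 4,
                                seed = 1L) {
  cfg <- list(concentration_nM = concentration_nM,
              diffusion_coeff = diffusion_coeff,
              beam_waist_w0 = beam_waist_w0,
              axial_radius_z0 = axial_radius_z0,
              brightness_eps = brightness_eps,
              background_rate = background_rate,
              bin_width = bin_width, duration = duration,
              box_scale = box_scale, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "solution_sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("concentration_nM", "diffusion_coeff", "beam_waist_w0",
           "axial_radius_z0", "brightness_eps", "bin_width", "duration")
  for (f in pos) {
    v <- cfg[[f]]
    ok <- if (f %in% c("concentration_nM", "brightness_eps")) v >= 0 else v > 0
    if (!is.numeric(v) || length(v) != 1L || !ok)
      stop(sprintf("invalid %s", f))
  }
  if (cfg$background_rate < 0) stop("background_rate must be >= 0")
  if (cfg$duration < 1000 * cfg$bin_width)
    stop("duration must be at least 1000 bins")
  if (cfg$box_scale < 4)
    stop("box_scale must be >= 4 (detection profile negligible at boundary)")
  invisible(cfg)
}

#' Configuration for a membrane-positioned trace simulation
#'
#' Extends [solution_sim_config()] with 2D diffusers confined to the focal
#' plane `z = 0` (the membrane), with their own diffusion coefficient and a
#' molecular brightness of `brightness_eps * brightness_ratio`.
#'
#' @inheritParams solution_sim_config
#' @param surface_density 2D diffuser density in molecules/m^2 (>= 0).
#' @param diffusion_coeff_2d 2D diffusion coefficient in m^2/s (> 0).
#' @param brightness_ratio brightness of the membrane species relative to the
#'   solution species (> 0); the measured aqueous/membrane quantum-yield
#'   ratio for BODIPY-labelled ligands is about 9.1.
#' @return list of class `membrane_sim_config` (also inherits
#'   `solution_sim_config`).
#' @export
membrane_sim_config <- function(concentration_nM,
                                surface_density = 0,
                                diffusion_coeff_2d = 5e-13,
                                brightness_ratio = 1,
                                ...) {
  base <- solution_sim_config(concentration_nM, ...)
  if (surface_density < 0) stop("surface_density must be >= 0")
  if (diffusion_coeff_2d <= 0) stop("diffusion_coeff_2d must be positive")
  if (brightness_ratio <= 0) stop("brightness_ratio must be positive")
  cfg <- c(unclass(base),
           list(surface_density = surface_density,
                diffusion_coeff_2d = diffusion_coeff_2d,
                brightness_ratio = brightness_ratio))
  structure(cfg, class = c("membrane_sim_config", "solution_sim_config"))
}

sim_box <- function(cfg) {
  list(half_xy = cfg$box_scale * cfg$beam_waist_w0,
       half_z = cfg$box_scale * cfg$axial_radius_z0)
}

run_sim <- function(cfg, lambda2, diff2, eps2) {
  box <- sim_box(cfg)
  n_bins <- as.integer(round(cfg$duration / cfg$bin_width))
  v_box_m3 <- (2 * box$half_xy)^2 * (2 * box$half_z)
  lambda3 <- molecules_per_m3(cfg$concentration_nM) * v_box_m3
  expected_updates <- (lambda3 + lambda2) * n_bins
  if (expected_updates > 1e9)
    stop("configuration implies > 1e9 particle-bin updates; reduce duration, ",
         "bin rate, box or concentration")
  if (lambda3 + lambda2 <= 0 && cfg$brightness_eps > 0)
    stop("zero particles in box with non-zero brightness")
  res <- .sim_trace_cpp(n_bins, cfg$bin_width,
                        lambda3, cfg$diffusion_coeff, cfg$brightness_eps,
                        lambda2, diff2, eps2,
                        cfg$beam_waist_w0, cfg$axial_radius_z0,
                        box$half_xy, box$half_z,
                        cfg$background_rate, cfg$seed)
  intensity_trace(res$counts, cfg$bin_width,
                  metadata = list(config = unclass(cfg), seed = cfg$seed,
                                  background_rate = cfg$background_rate,
                                  n_particles_3d = res$n_particles_3d,
                                  n_particles_2d = res$n_particles_2d))
}

#' Simulate a solution-phase photon trace
#'
#' @param config a [solution_sim_config()].
#' @return an [intensity_trace()]; metadata records the config, seed and the
#'   drawn particle numbers.
#' @examples
#' \donttest{
#' cfg <- solution_sim_config(1.8, duration = 1, seed = 7)
#' tr <- simulate_solution_trace(cfg)
#' }
#' @export
simulate_solution_trace <- function(config) {
  stopifnot(inherits(config, "solution_sim_config"))
  validate_sim_config(config)
  run_sim(config, lambda2 = 0, diff2 = 1e-13, eps2 = 0)
}

#' Simulate a membrane-positioned photon trace
#'
#' As [simulate_solution_trace()] plus 2D diffusers confined to `z = 0`.
#' With `surface_density = 0` the output is identical to the solution
#' simulation under the same seed.
#'
#' @param config a [membrane_sim_config()].
#' @return an [intensity_trace()].
#' @export
simulate_membrane_trace <- function(config) {
  stopifnot(inherits(config, "membrane_sim_config"))
  validate_sim_config(config)
  box <- sim_box(config)
  a_box <- (2 * box$half_xy)^2
  run_sim(config,
          lambda2 = config$surface_density * a_box,
          diff2 = config$diffusion_coeff_2d,
          eps2 = config$brightness_eps * config$brightness_ratio)
}

#' Expected effective particle numbers for a simulation config
#'
#' Ground-truth apparent particle numbers for recovery checks:
#' `N_3D = C N_A V_eff` with `V_eff = pi^{3/2} w0^2 z0`, and for membrane
#' configs `N_2D = sigma pi w0^2` (the effective detection area).
#'
#' @param config a [solution_sim_config()] or [membrane_sim_config()].
#' @return list with `n_3d` and (membrane) `n_2d`.
#' @export
expected_particle_numbers <- function(config) {
  v_eff_L <- pi^1.5 * config$beam_waist_w0^2 * config$axial_radius_z0 * 1e3
  out <- list(n_3d = particles_from_concentration(config$concentration_nM, v_eff_L))
  if (inherits(config, "membrane_sim_config"))
    out$n_2d <- config$surface_density * pi * config$beam_waist_w0^2
  out
}
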