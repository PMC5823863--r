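#' Calibrate the confocal detection volume from a reference dye fit
#'
#' Given a converged single-component 3D fit of a calibration dye with known
#' diffusion coefficient, recovers the beam waist from `w0 = sqrt(4 D tau_D)`,
#' the axial radius `z0 = S w0`, and the effective volume under the chosen
#' convention: `gaussian` (the standard FCS definition
#' `V_eff = pi^{3/2} w0^2 z0`) or `cylinder` (`V = pi w0^2 (2 z0)`, the
#' cylinder spanning the focal waist often quoted as the "~0.25 fL" volume).
#'
#' @param dye_fit an `fcs_fit` from [fit_acf()] with a single 3D component, or
#'   a named list with elements `tau_d` and `S` (seconds / dimensionless).
#' @param dye_D literature diffusion coefficient of the dye in m^2/s
#'   (e.g. 3.16e-10 for Cy5 in water).
#' @param convention `"gaussian"` (default) or `"cylinder"`.
#' @param session optional session identifier recorded in the result.
#' @return An object of class `fcs_calibration`: `w0`, `S`, `z0` (m),
#'   `v_eff_L` (litres), `convention`, `calibration_dye_D`, `session`.
#' @examples
#' calibrate_volume(list(tau_d = 31.65e-6, S = 5), dye_D = 3.16e-10)
#' @export
calibrate_volume <- function(dye_fit, dye_D, convention = c("gaussian", "cylinder"),
                             session = NA_character_) {
  convention <- match.arg(convention)
  if (dye_D <= 0) stop("dye_D must be positive")
  if (inherits(dye_fit, "fcs_fit")) {
    if (!dye_fit$converged) stop("calibration fit did not converge")
    if (length(dye_fit$model$kinds) != 1L || dye_fit$model$kinds != "3D")
      stop("calibration requires a single-component 3D fit")
    tau_d <- dye_fit$model$tau_d
    S <- dye_fit$model$S
  } else {
    tau_d <- dye_fit$tau_d
    S <- dye_fit$S
  }
  if (is.null(tau_d) || tau_d <= 0 || is.null(S) || S <= 1)
    stop("need tau_d > 0 and S > 1")
  w0 <- sqrt(4 * dye_D * tau_d)
  z0 <- S * w0
  v_m3 <- switch(convention,
                 gaussian = pi^1.5 * w0^2 * z0,
                 cylinder = pi * w0^2 * 2 * z0)
  structure(list(w0 = w0, S = S, z0 = z0, v_eff_L = v_m3 * 1e3,
                 convention = convention, calibration_dye_D = dye_D,
                 session = session),
            class = "fcs_calibration")
}

#' @export
print.fcs_calibration <- function(x, ...) {
  cat(sprintf("<fcs_calibration> w0 = %.4g um, z0 = %.4g um, S = %.3g, V_eff = %.4g fL (%s)\n",
              x$w0 * 1e6, x$z0 * 1e6, x$S, x$v_eff_L * 1e15, x$convention))
  invisible(x)
}

#' Molar concentration from a particle number
#'
#' `C = N / (N_A V_eff)`, reported in nanomolar.
#'
#' @param n mean particle number in the effective volume (>= 0).
#' @param v_eff effective detection volume in litres (> 0), or an
#'   [calibrate_volume()] result.
#' @return concentration in nM.
#' @examples
#' concentration_from_N(0.241, 0.223e-15) # ~1.8 nM
#' @export
concentration_from_N <- function(n, v_eff) {
  if (inherits(v_eff, "fcs_calibration")) v_eff <- v_eff$v_eff_L
  if (any(n < 0)) stop("n must be non-negative")
  if (v_eff <= 0) stop("v_eff must be positive")
  n / (AVOGADRO * v_eff) / 1e-9
}

#' Particle number from a molar concentration
#'
#' Inverse of [concentration_from_N()]: `N = C N_A V_eff`.
#'
#' @param c_nM concentration in nM (>= 0).
#' @param v_eff effective volume in litres, or an [calibrate_volume()] result.
#' @return dimensionless particle number.
#' @export
particles_from_concentration <- function(c_nM, v_eff) {
  if (inherits(v_eff, "fcs_calibration")) v_eff <- v_eff$v_eff_L
  if (any(c_nM < 0)) stop("concentration must be non-negative")
  if (v_eff <= 0) stop("v_eff must be positive")
  c_nM * 1e-9 * AVOGADRO * v_eff
}

#' Diffusion coefficient from a dwell time
#'
#' `D = w0^2 / (4 tau_D)` for lateral transit through a Gaussian waist.
#'
#' @param tau_d dwell time in seconds (> 0).
#' @param w0 beam waist in metres (> 0).
#' @return diffusion coefficient in m^2/s.
#' @examples
#' diffusion_from_dwell(140e-6, 0.2e-6) # 7.14e-11 m^2/s
#' @export
diffusion_from_dwell <- function(tau_d, w0) {
  if (any(tau_d <= 0) || any(w0 <= 0)) stop("tau_d and w0 must be positive")
  w0^2 / (4 * tau_d)
}

#' Molecular brightness (counts per molecule)
#'
#' `cpm = (mean rate - background) / (gamma N)`, the detected photon rate per
#' molecule at the focus. The shape factor gamma converts the
#' profile-averaged rate implied by the FCS particle number into peak
#' brightness: `2^(-3/2)` for a species sampled by the full 3D Gaussian,
#' `1/2` for a planar species seen by the lateral Gaussian only, or 1 to
#' report the raw mean-rate-per-particle. Environments with different quantum
#' yield (aqueous vs membrane) give different cpm; their ratio feeds
#' [correct_two_species_numbers()].
#'
#' @param trace an [intensity_trace()].
#' @param n fitted particle number attributed to the species (> 0).
#' @param background_rate detector background in counts/s (default: the
#'   trace's `metadata$background_rate`, else 0).
#' @param environment label, e.g. `"aqueous"` or `"membrane"`.
#' @param geometry detection geometry of the species: `"3d_gaussian"`
#'   (default), `"2d_gaussian"` (membrane plane), or `"none"` (gamma = 1).
#' @param reference optional reference `brightness_result`; when supplied the
#'   result carries `ratio = cpm / reference cpm` (component 2 / component 1).
#' @return An object of class `brightness_result`: `cpm`, `environment`,
#'   `ratio` (or `NA`).
#' @export
brightness_cpm <- function(trace, n, background_rate = NULL,
                           environment = "aqueous",
                           geometry = c("3d_gaussian", "2d_gaussian", "none"),
                           reference = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  geometry <- match.arg(geometry)
  if (n <= 0) stop("n must be positive")
  bg <- background_rate %||% trace$metadata$background_rate %||% 0
  gamma <- switch(geometry, "3d_gaussian" = 2^-1.5, "2d_gaussian" = 0.5,
                  none = 1)
  cpm <- (mean_rate(trace) - bg) / (gamma * n)
  if (cpm <= 0) stop("non-positive net rate; check background_rate")
  ratio <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "brightness_result"))
    ratio <- cpm / reference$cpm
  }
  structure(list(cpm = cpm, environment = environment, ratio = ratio),
            class = "brightness_result")
}

#' @export
print.brightness_result <- function(x, ...) {
  cat(sprintf("<brightness_result> %.4g kHz/molecule (%s)%s\n",
              x$cpm / 1e3, x$environment,
              if (is.na(x$ratio)) "" else sprintf(", ratio %.3g", x$ratio)))
  invisible(x)
}

#' Brightness-correct apparent two-species particle numbers
#'
#' An equal-brightness autocorrelation fit of a mixture of a dim species (1,
#' e.g. free 3D ligand) and a bright species (2, e.g. membrane-bound, with
#' brightness ratio r = eps_2/eps_1) misattributes amplitude: the true
#' per-species amplitudes are
#' \deqn{A_i = \frac{N_i \epsilon_i^2}{(\sum_j N_j \epsilon_j)^2}.}
#' Writing `T = N_1 + r N_2` (total intensity in units of `eps_1`), the
#' forward map gives `A_1 = N_1 / T^2`, `A_2 = N_2 r^2 / T^2`, and summing
#' intensities yields the closed-form inversion
#' \deqn{T = \frac{1}{A_1 + A_2/r},\quad N_1 = A_1 T^2,\quad N_2 = A_2 T^2 / r^2.}
#' With r = 1 this returns the uncorrected split exactly; with a single
#' species present the apparent number is already correct (brightness cancels)
#' and is passed through.
#'
#' Note that r is the ratio of *apparent* per-particle brightnesses in the
#' amplitude system, i.e. molecular brightness times the detection-profile
#' shape factor (eps/2 for a planar species under the lateral Gaussian,
#' eps/2^(3/2) for a 3D species). A molecular ratio of 9.1 between membrane
#' and aqueous environments therefore enters as `sqrt(2) * 9.1`; an in-situ
#' ratio of uncorrected counts-per-particle ([brightness_cpm()] with
#' `geometry = "none"`) can be used directly.
#'
#' @param n_apparent_total total apparent particle number from the
#'   equal-brightness fit (> 0).
#' @param fraction_2d apparent fraction of the bright (2D) species in `[0, 1]`.
#' @param r apparent brightness ratio, bright (2D) over dim (3D) species (> 0).
#' @return list with `n_3d`, `n_2d` (corrected particle numbers) and the
#'   echoed inputs.
#' @examples
#' correct_two_species_numbers(1, 0.5, r = 1)     # identity split
#' correct_two_species_numbers(1, 0.5, r = 9.1)
#' @export
correct_two_species_numbers <- function(n_apparent_total, fraction_2d, r) {
  if (n_apparent_total <= 0) stop("n_apparent_total must be positive")
  if (fraction_2d < 0 || fraction_2d > 1) stop("fraction_2d must be in [0, 1]")
  if (r <= 0) stop("brightness ratio must be positive")
  a1 <- (1 - fraction_2d) / n_apparent_total
  a2 <- fraction_2d / n_apparent_total
  if (fraction_2d == 0 || fraction_2d == 1) {
    # single species: 1/G(0) is the true number irrespective of brightness
    return(list(n_3d = if (fraction_2d == 0) n_apparent_total else 0,
                n_2d = if (fraction_2d == 1) n_apparent_total else 0,
                n_apparent_total = n_apparent_total,
                fraction_2d = fraction_2d, r = r))
  }
  tot <- 1 / (a1 + a2 / r)
  list(n_3d = a1 * tot^2,
       n_2d = a2 * tot^2 / r^2,
       n_apparent_total = n_apparent_total,
       fraction_2d = fraction_2d, r = r)
}

#' Membrane-phase concentration from a corrected 2D particle number
#'
#' The membrane-bound particle number is referred to a cylinder with the area
#' of the focal waist and the height of the lipid bilayer:
#' `V_cyl = pi w0^2 h`, `C_mem = N_2D / (N_A V_cyl)`. Only `w0` and `h` enter;
#' the axial extent of the detection volume is irrelevant for a planar species.
#'
#' @param n2d_corrected brightness-corrected 2D particle number (> 0).
#' @param w0 beam waist in metres (> 0).
#' @param h cylinder height in metres; default `5e-9` (bilayer thickness).
#' @param n2d_apparent optional uncorrected number, echoed for the record.
#' @param r optional brightness ratio used, echoed for the record.
#' @return object of class `membrane_estimate`: `n2d_corrected`,
#'   `cylinder_height`, `cylinder_volume_L`, `conc_membrane_nM`, plus echoes.
#' @examples
#' membrane_concentration(0.278, w0 = 0.2e-6) # ~734 nM
#' @export
membrane_concentration <- function(n2d_corrected, w0, h = 5e-9,
                                   n2d_apparent = NA_real_, r = NA_real_) {
  if (n2d_corrected <= 0 || w0 <= 0 || h <= 0)
    stop("all inputs must be positive")
  v_L <- pi * w0^2 * h * 1e3
  structure(list(
    n2d_apparent = n2d_apparent, brightness_ratio = r,
    n2d_corrected = n2d_corrected, cylinder_height = h,
    cylinder_volume_L = v_L,
    conc_membrane_nM = n2d_corrected / (AVOGADRO * v_L) / 1e-9),
    class = "membrane_estimate")
}

#' @export
print.membrane_estimate <- function(x, ...) {
  cat(sprintf("<membrane_estimate> N_2D = %.4g in %.4g fL cylinder (h = %g nm) -> %.4g nM\n",
              x$n2d_corrected, x$cylinder_volume_L * 1e15,
              x$cylinder_height * 1e9, x$conc_membrane_nM))
  invisible(x)
}
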