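#' Configuration for the near-membrane concentration-gradient generator
#'
#' Emulates distance- and time-resolved single-cell concentration tables: a
#' monotone spatial gradient from a near-membrane concentration at the 2-um
#' reference distance down to the bulk value, with per-condition near values,
#' a time build-up model, and multiplicative log-normal cell-to-cell noise.
#' The true mean is
#' \deqn{C(z, t) = c_{bulk} + (c_{near}(t) - c_{bulk}) e^{-(z - 2)/\lambda}}
#' with `c_near(t)` constant, linear, or saturating (normalized so the final
#' time point reaches the condition's `c_near`).
#'
#' Default condition parameters follow printed near-membrane values for a
#' beta2-adrenoceptor antagonist ligand added at 1.8 nM: ~5.1 nM close to a
#' bare coverslip, 19.2 nM above non-expressing cells, 45.7 nM above
#' receptor-expressing cells and 27.1 nM with a blocking antagonist present.
#' These are emulation knobs, not inferences of any measured curve shape.
#'
#' @param conditions data frame with columns `condition`, `c_near` (nM),
#'   `c_bulk` (nM), `n_cells`, `time_model` (`constant`/`linear`/`saturating`).
#'   Default: the four experimental conditions described above.
#' @param decay_length spatial decay length in um (default 15).
#' @param distances measurement distances in um (default the instrument
#'   ladder 2, 3, 4, 5, 6, 7, 9, 11, 21, 31, 41, 51, 101, 151, 200).
#' @param timepoints incubation times in min (default 15, 30, 60, 90, 120).
#' @param time_halflife half-time of the saturating build-up in min (default 45).
#' @param noise_cv cell-to-cell coefficient of variation (default 0.25).
#' @param diff_coeff_mean mean reported diffusion coefficient, m^2/s.
#' @param diff_coeff_cv CV of the reported diffusion coefficient.
#' @param conc_floor_nM floor applied to generated concentrations (default
#'   0.01 nM); values below it are clipped with a warning.
#' @param seed integer root seed. Per-cell sub-seeds are pre-drawn from the
#'   root in cell order, so increasing `n_cells` never reshuffles the draws
#'   of earlier cells.
#' @return list of class `gradient_config`.
#' @export
gradient_config <- function(conditions = default_gradient_conditions(),
                            decay_length = 15,
                            distances = c(2, 3, 4, 5, 6, 7, 9, 11, 21, 31,
                                          41, 51, 101, 151, 200),
                            timepoints = c(15, 30, 60, 90, 120),
                            time_halflife = 45,
                            noise_cv = 0.25,
                            diff_coeff_mean = 7.14e-11,
                            diff_coeff_cv = 0.15,
                            conc_floor_nM = 0.01,
                            seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "c_near", "c_bulk", "n_cells", "time_model")
                %in% names(conditions)))
  if (any(conditions$c_bulk <= 0) || any(conditions$c_near < conditions$c_bulk))
    stop("need c_near >= c_bulk > 0 for every condition")
  if (!all(conditions$time_model %in% c("constant", "linear", "saturating")))
    stop("time_model must be constant, linear or saturating")
  if (decay_length <= 0) stop("decay_length must be positive")
  if (noise_cv < 0 || noise_cv >= 1) stop("noise_cv must be in [0, 1)")
  if (time_halflife <= 0) stop("time_halflife must be positive")
  if (any(distances < 0) || is.unsorted(distances, strictly = TRUE))
    stop("distances must be non-negative and strictly increasing")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  structure(list(conditions = conditions, decay_length = decay_length,
                 distances = distances, timepoints = timepoints,
                 time_halflife = time_halflife, noise_cv = noise_cv,
                 diff_coeff_mean = diff_coeff_mean,
                 diff_coeff_cv = diff_coeff_cv,
                 conc_floor_nM = conc_floor_nM, seed = as.integer(seed)),
            class = "gradient_config")
}

#' @rdname gradient_config
#' @export
default_gradient_conditions <- function() {
  data.frame(
    condition = c("no_cell", "receptor_none", "receptor_high",
                  "receptor_high_ICI"),
    c_near = c(5.1, 19.2, 45.7, 27.1),
    c_bulk = c(0.8, 1.5, 1.5, 1.5),
    n_cells = c(8L, 10L, 13L, 7L),
    time_model = c("constant", "linear", "saturating", "linear"),
    stringsAsFactors = FALSE)
}

# c_near(t), normalized so the final timepoint reaches c_near exactly
c_near_at_time <- function(c_near, c_bulk, t, t_final, model, t_half) {
  span <- c_near - c_bulk
  frac <- switch(model,
                 constant = rep(1, length(t)),
                 linear = t / t_final,
                 saturating = (1 - 2^(-t / t_half)) / (1 - 2^(-t_final / t_half)))
  c_bulk + span * frac
}

true_gradient_mean <- function(cfg, condition, distance_um, time_min) {
  row <- cfg$conditions[cfg$conditions$condition == condition, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown condition: ", condition)
  cn <- c_near_at_time(row$c_near, row$c_bulk, time_min, max(cfg$timepoints),
                       row$time_model, cfg$time_halflife)
  row$c_bulk + (cn - row$c_bulk) * exp(-(distance_um - 2) / cfg$decay_length)
}

#' Generate a synthetic distance/time concentration measurement table
#'
#' One row per (cell, condition, distance, timepoint) with multiplicative
#' log-normal noise of the configured CV applied per cell-position (mean-one
#' noise, so profile means converge to the true curve). Reported diffusion
#' coefficients are distance-independent draws around `diff_coeff_mean`.
#'
#' @param config a [gradient_config()].
#' @return data frame with columns `cell_id`, `condition`, `distance_um`,
#'   `time_min`, `conc_nM`, `diff_coeff_m2s`, plus attribute
#'   `reference_frame` (`"membrane"`/`"coverslip"` per condition column
#'   `frame`).
#' @export
generate_gradient_dataset <- function(config) {
  stopifnot(inherits(config, "gradient_config"))
  cfg <- config
  # mean-one log-normal noise
  sdl <- sqrt(log(1 + cfg$noise_cv^2))
  mul <- -0.5 * sdl^2
  sdl_d <- sqrt(log(1 + cfg$diff_coeff_cv^2))
  mul_d <- -0.5 * sdl_d^2

  out <- list()
  clipped <- 0L
  for (ci in seq_len(nrow(cfg$conditions))) {
    row <- cfg$conditions[ci, ]
    # pre-draw per-cell sub-seeds so earlier cells are stable under n_cells
    set.seed(cfg$seed + 104729L * ci)
    cell_seeds <- sample.int(.Machine$integer.max - 1L, row$n_cells)
    for (cell in seq_len(row$n_cells)) {
      set.seed(cell_seeds[cell])
      grid <- expand.grid(distance_um = cfg$distances,
                          time_min = cfg$timepoints,
                          KEEP.OUT.ATTRS = FALSE)
      mu <- true_gradient_mean(cfg, row$condition, grid$distance_um,
                               grid$time_min)
      conc <- mu * rlnorm(nrow(grid), meanlog = mul, sdlog = sdl)
      low <- conc < cfg$conc_floor_nM
      clipped <- clipped + sum(low)
      conc[low] <- cfg$conc_floor_nM
      dcoef <- cfg$diff_coeff_mean *
        rlnorm(nrow(grid), meanlog = mul_d, sdlog = sdl_d)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = sprintf("%s_cell%02d", row$condition, cell),
        condition = row$condition,
        distance_um = grid$distance_um,
        time_min = grid$time_min,
        conc_nM = conc,
        diff_coeff_m2s = dcoef,
        stringsAsFactors = FALSE)
    }
  }
  if (clipped > 0L)
    warning(sprintf("%d generated concentration(s) clipped at the %.3g nM floor",
                    clipped, cfg$conc_floor_nM))
  res <- do.call(rbind, out)
  attr(res, "reference_frame") <-
    c(no_cell = "coverslip", receptor_none = "membrane",
      receptor_high = "membrane", receptor_high_ICI = "membrane")
  attr(res, "seed") <- cfg$seed
  res
}

#' Configuration for the TR-FRET binding-data generator
#'
#' Emulates plate-reader saturation and association experiments on a ligand
#' with equilibrium dissociation constant `kd` and dissociation rate `koff`
#' (`kon = koff/kd` by construction). Signals are in TR-FRET ratio units
#' (665/620 emission ratio x 10,000). Total binding carries a linear
#' non-specific component `ns_slope * L` over `baseline`; the matched NSB
#' series carries only that component.
#'
#' @param kd equilibrium dissociation constant in nM (default 1.8).
#' @param bmax_signal specific signal at saturation, ratio units (default 400).
#' @param koff dissociation rate in 1/min (default 0.04).
#' @param ligand_concs ligand concentrations in nM; association default
#'   `kd * c(1/3, 1, 3, 9)` (four rising concentrations).
#' @param times association sampling times in min (default every 0.5 min for
#'   60 min).
#' @param ns_slope non-specific signal per nM of ligand (default 1.5).
#' @param baseline assay baseline, ratio units (default 100).
#' @param noise_sd additive Gaussian noise SD, ratio units (default 8,
#'   i.e. 2% of the default `bmax_signal`).
#' @param seed integer seed.
#' @return list of class `binding_config`.
#' @export
binding_config <- function(kd = 1.8, bmax_signal = 400, koff = 0.04,
                           ligand_concs = 1.8 * c(1 / 3, 1, 3, 9),
                           times = seq(0.5, 60, by = 0.5),
                           ns_slope = 1.5, baseline = 100,
                           noise_sd = 8, seed = 1L) {
  if (kd <= 0 || koff <= 0) stop("kd and koff must be positive")
  if (any(ligand_concs <= 0)) stop("ligand concentrations must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(kd = kd, bmax_signal = bmax_signal, koff = koff,
                 kon = koff / (kd * 1e-9),  # M^-1 min^-1
                 ligand_concs = ligand_concs, times = times,
                 ns_slope = ns_slope, baseline = baseline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "binding_config")
}

#' Generate synthetic association time courses
#'
#' Per ligand concentration `L` (nM), total signal
#' `baseline + ns_slope*L + bmax*(L/(L+kd))*(1 - exp(-(kon*L + koff) t))`
#' plus noise, and a matched non-specific series `baseline + ns_slope*L`
#' plus noise. `kon = koff/kd`.
#'
#' @param config a [binding_config()].
#' @return list of `binding_timecourse` objects (fields `ligand_conc_nM`,
#'   `times_min`, `ratio_total`, `ratio_nsb`, `label`).
#' @export
generate_association_timecourses <- function(config) {
  stopifnot(inherits(config, "binding_config"))
  if (length(config$ligand_concs) < 2L)
    stop("need at least 2 ligand concentrations")
  set.seed(config$seed)
  lapply(config$ligand_concs, function(L) {
    kob <- config$kon * (L * 1e-9) + config$koff
    spec <- config$bmax_signal * L / (L + config$kd) *
      (1 - exp(-kob * config$times))
    ns <- config$baseline + config$ns_slope * L
    structure(list(
      ligand_conc_nM = L,
      times_min = config$times,
      ratio_total = ns + spec + rnorm(length(config$times), 0, config$noise_sd),
      ratio_nsb = ns + rnorm(length(config$times), 0, config$noise_sd),
      label = sprintf("L=%.3g nM", L)),
      class = "binding_timecourse")
  })
}

#' Generate a synthetic equilibrium saturation dataset
#'
#' Equilibrium total/non-specific pairs over a concentration range spanning
#' `kd`: `total = baseline + ns_slope*L + bmax*L/(L+kd) + noise`,
#' `nsb = baseline + ns_slope*L + noise`.
#'
#' @param config a [binding_config()].
#' @param ligand_concs concentrations in nM; default 12 log-spaced points
#'   from 0.001 to 300 nM.
#' @return list of class `saturation_dataset` with `ligand_concs_nM`,
#'   `totals`, `nsbs`.
#' @export
generate_saturation_dataset <- function(config,
                                        ligand_concs =
                                          10^seq(log10(0.001), log10(300),
                                                 length.out = 12)) {
  stopifnot(inherits(config, "binding_config"))
  if (min(ligand_concs) >= config$kd || max(ligand_concs) <= config$kd)
    stop("concentration range must span kd")
  set.seed(config$seed + 1L)
  ns <- config$baseline + config$ns_slope * ligand_concs
  spec <- config$bmax_signal * ligand_concs / (ligand_concs + config$kd)
  structure(list(
    ligand_concs_nM = sort(ligand_concs),
    totals = (ns + spec + rnorm(length(ligand_concs), 0, config$noise_sd)
              )[order(ligand_concs)],
    nsbs = (ns + rnorm(length(ligand_concs), 0, config$noise_sd)
            )[order(ligand_concs)]),
    class = "saturation_dataset")
}
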