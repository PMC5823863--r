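#' TR-FRET emission ratio
#'
#' `10000 * em665 / em620`: acceptor (ligand, 665 nm) over donor (terbium
#' label, 620 nm) emission, scaled by the conventional factor of 10,000.
#'
#' @param em665 acceptor-channel counts (>= 0).
#' @param em620 donor-channel counts (> 0).
#' @return dimensionless ratio (vectors recycled as usual).
#' @examples
#' tr_fret_ratio(500, 50000) # 100
#' @export
tr_fret_ratio <- function(em665, em620) {
  if (any(em620 <= 0)) stop("em620 must be positive")
  10000 * em665 / em620
}

#' Specific binding by non-specific subtraction
#'
#' Elementwise `total - nsb`. Low-signal negatives are preserved, not
#' clipped, so that noise stays symmetric for downstream fits.
#'
#' @param total total-binding series.
#' @param nsb matched non-specific series (same length).
#' @return specific binding, same units.
#' @export
specific_binding <- function(total, nsb) {
  if (length(total) != length(nsb)) stop("total and nsb must be aligned")
  total - nsb
}

#' Fit an equilibrium saturation binding curve
#'
#' Least-squares fit of `specific = Bmax * L / (Kd + L)` to total-minus-NSB
#' signals. A fit whose relative Kd standard error exceeds 1 is flagged as
#' poorly constrained (typically the concentration range does not span Kd).
#'
#' @param data a `saturation_dataset` (see [generate_saturation_dataset()])
#'   or a list with `ligand_concs_nM`, `totals`, `nsbs`.
#' @return object of class `saturation_fit`: `kd` (nM), `bmax`, `se`
#'   (named), `converged`, `poorly_constrained`, `rss`.
#' @export
fit_saturation <- function(data) {
  L <- data$ligand_concs_nM
  if (length(L) < 6L) stop("need at least 6 concentrations")
  y <- specific_binding(data$totals, data$nsbs)
  start <- list(bmax = max(y), kd = stats::median(L))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bmax * L / (kd + L), start = start,
                      lower = c(bmax = 0, kd = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, bmax = NA_real_,
                          se = c(bmax = NA_real_, kd = NA_real_),
                          converged = FALSE, poorly_constrained = TRUE,
                          rss = NA_real_),
                     class = "saturation_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bmax = NA_real_, kd = NA_real_))
  structure(list(kd = unname(est["kd"]), bmax = unname(est["bmax"]),
                 se = se, converged = TRUE,
                 poorly_constrained = isTRUE(unname(se["kd"] / est["kd"]) > 1),
                 rss = sum(stats::resid(fit)^2)),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> Kd = %.4g nM (SE %.3g), Bmax = %.4g%s\n",
              x$kd, x$se["kd"], x$bmax,
              if (x$poorly_constrained) " [poorly constrained]" else ""))
  invisible(x)
}

# Brute-force single-curve observed-rate estimate: scan kob on a log grid,
# solving the plateau by linear least squares at each kob, refine by optimize.
# Used for starting values (and as an independent oracle in tests).
kob_scan <- function(times, y, grid = 10^seq(-3, 1.5, length.out = 60)) {
  rss_at <- function(kob) {
    basis <- 1 - exp(-kob * times)
    denom <- sum(basis^2)
    if (denom == 0) return(sum(y^2))
    amp <- sum(basis * y) / denom
    sum((y - amp * basis)^2)
  }
  rss <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(rss_at, c(lo, hi))
  kob <- opt$minimum
  basis <- 1 - exp(-kob * times)
  list(kob = kob, y_eq = sum(basis * y) / sum(basis^2), rss = opt$objective)
}

#' Globally fit association time courses for kon and koff
#'
#' Fits `specific(t; L) = Y_eq(L) * (1 - exp(-(kon*L + koff) t))` jointly
#' over two or more ligand concentrations, sharing `kon` and `koff` and
#' leaving one plateau `Y_eq` free per concentration. With a single
#' concentration the dissociation rate is not identifiable from an
#' amplitude-free fit, so at least two distinct concentrations are required.
#'
#' Starting values come from per-curve observed rates `kob` (brute-force
#' 1-D scan) regressed on `L` (`kob = kon*L + koff`); a log-spaced multi-start
#' fallback guards against poor starts.
#'
#' @param datasets list of `binding_timecourse` objects (>= 2 distinct
#'   ligand concentrations).
#' @param use_total if `TRUE`, fit the total signal with a shared linear
#'   non-specific term (`baseline + ns_slope*L`) instead of pre-subtracted
#'   specific signals.
#' @return object of class `kinetic_fit`: `kon` (M^-1 min^-1), `koff`
#'   (1/min), `kd_kinetic_nM = koff/kon` (nM), `t_half_min = ln2/koff`,
#'   `y_eq` (per-dataset plateaus), `se`, `converged`, `rss`.
#' @export
fit_association_global <- function(datasets, use_total = FALSE) {
  if (inherits(datasets, "binding_timecourse")) datasets <- list(datasets)
  concs <- vapply(datasets, function(d) d$ligand_conc_nM, numeric(1))
  if (length(unique(concs)) < 2L)
    stop("global association fitting needs >= 2 distinct ligand ",
         "concentrations; koff is not identifiable from a single curve ",
         "with a free plateau")
  nd <- length(datasets)

  ys <- lapply(datasets, function(d) {
    if (use_total) d$ratio_total else specific_binding(d$ratio_total, d$ratio_nsb)
  })
  ts <- lapply(datasets, function(d) d$times_min)

  # starting values from per-curve kob scans
  scans <- Map(function(t, y) kob_scan(t, y), ts, ys)
  kobs <- vapply(scans, `[[`, numeric(1), "kob")
  slope_fit <- lm(kobs ~ I(concs * 1e-9))
  kon0 <- max(unname(stats::coef(slope_fit)[2]), 1e4)
  koff0 <- max(unname(stats::coef(slope_fit)[1]), 1e-4)
  yeq0 <- pmax(vapply(scans, `[[`, numeric(1), "y_eq"), 1e-6)

  n_extra <- if (use_total) 2L else 0L
  resid_fn <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2])
    yeq <- p[2L + seq_len(nd)]
    extra <- if (use_total) p[2L + nd + 1:2] else c(0, 0)
    unlist(Map(function(t, y, L, ye) {
      pred <- ye * (1 - exp(-(kon * L * 1e-9 + koff) * t)) +
        if (use_total) extra[1] + extra[2] * L else 0
      pred - y
    }, ts, ys, as.list(concs), as.list(yeq)))
  }

  starts <- list(c(log(kon0), log(koff0), yeq0,
                   if (use_total) c(0, 0)))
  for (f in c(0.1, 10)) {
    starts[[length(starts) + 1L]] <-
      c(log(kon0 * f), log(koff0 / f), yeq0, if (use_total) c(0, 0))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("global association fit failed from all starts")
  fit <- best$fit
  p <- fit$par
  kon <- exp(p[1]); koff <- exp(p[2])

  nobs <- sum(lengths(ys))
  npar <- length(p)
  sigma2 <- best$rss / max(nobs - npar, 1L)
  jac <- num_jacobian(resid_fn, p)
  cov <- tryCatch(sigma2 * solve(crossprod(jac)), error = function(e) NULL)
  se_kon <- se_koff <- NA_real_
  if (!is.null(cov)) {
    # delta method from log scale
    se_kon <- kon * sqrt(max(cov[1, 1], 0))
    se_koff <- koff * sqrt(max(cov[2, 2], 0))
  }

  structure(list(
    kon = kon, koff = koff,
    kd_kinetic_nM = koff / kon / 1e-9,
    t_half_min = log(2) / koff,
    y_eq = setNames(p[2L + seq_len(nd)], sprintf("L=%.3g nM", concs)),
    se = c(kon = se_kon, koff = se_koff),
    converged = fit$info %in% 1:3,
    rss = best$rss, n_obs = nobs),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> kon = %.4g M^-1 min^-1, koff = %.4g min^-1, Kd = %.4g nM, t1/2 = %.4g min\n",
    x$kon, x$koff, x$kd_kinetic_nM, x$t_half_min))
  invisible(x)
}

#' Residence half-life from a dissociation rate
#'
#' `t_half = ln(2) / koff`.
#'
#' @param koff dissociation rate in 1/min (> 0).
#' @return half-life in minutes.
#' @examples
#' half_life(0.04) # ~17 min
#' @export
half_life <- function(koff) {
  if (any(koff <= 0)) stop("koff must be positive")
  log(2) / koff
}
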