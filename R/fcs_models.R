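#' FCS diffusion model specification
#'
#' Describes a normalized autocorrelation model
#' \deqn{G(\tau) = G_\infty + \frac{1}{N} \sum_i \phi_i g_i(\tau)}
#' with per-component decay terms
#' \deqn{g_{3D}(\tau) = (1+\tau/\tau_D)^{-1} (1+\tau/(S^2\tau_D))^{-1/2}}
#' for free 3D diffusion through a Gaussian volume of structure parameter
#' `S = z0/w0`, and \deqn{g_{2D}(\tau) = (1+\tau/\tau_D)^{-1}} for diffusion
#' confined to the membrane plane. Amplitudes assume equal molecular
#' brightness across components; unequal brightness is corrected downstream
#' with [correct_two_species_numbers()].
#'
#' @param kinds character vector of component kinds, each `"3D"` or `"2D"`
#'   (1 to 3 components, at most one 3D component).
#' @param total_n total apparent particle number N (> 0).
#' @param tau_d dwell times in seconds, one per component (> 0).
#' @param fractions component fractions, non-negative, summing to 1. Default:
#'   equal split.
#' @param S structure parameter z0/w0 (> 1); required if any 3D component.
#' @param offset long-time offset `G_inf` (default 0).
#' @return An object of class `fcs_model`.
#' @examples
#' m <- fcs_model("3D", total_n = 0.241, tau_d = 140e-6, S = 5)
#' eval_model(m, c(1e-6, 140e-6))
#' @export
fcs_model <- function(kinds, total_n, tau_d, fractions = NULL, S = NULL,
                      offset = 0) {
  kinds <- toupper(as.character(kinds))
  k <- length(kinds)
  if (k < 1L || k > 3L) stop("1 to 3 components supported")
  if (!all(kinds %in% c("3D", "2D"))) stop("component kinds must be '3D' or '2D'")
  if (sum(kinds == "3D") > 1L) stop("at most one 3D component")
  if (length(tau_d) != k || any(tau_d <= 0)) stop("one positive tau_d per component")
  if (is.null(fractions)) fractions <- rep(1 / k, k)
  if (length(fractions) != k || any(fractions < 0))
    stop("fractions must be non-negative, one per component")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (any(kinds == "3D")) {
    if (is.null(S)) stop("S (structure parameter) required for a 3D component")
    if (S <= 1) stop("S must exceed 1")
  }
  if (total_n <= 0) stop("total_n must be positive")
  structure(list(kinds = kinds, total_n = as.numeric(total_n),
                 tau_d = as.numeric(tau_d),
                 fractions = fractions / sum(fractions),
                 S = if (is.null(S)) NA_real_ else as.numeric(S),
                 offset = as.numeric(offset)),
            class = "fcs_model")
}

#' @export
print.fcs_model <- function(x, ...) {
  cat(sprintf("<fcs_model> %s | N = %.4g | tau_d = %s s | phi = %s | S = %.3g | Ginf = %.3g\n",
              paste(x$kinds, collapse = "+"), x$total_n,
              paste(signif(x$tau_d, 4), collapse = ", "),
              paste(signif(x$fractions, 3), collapse = ", "),
              x$S, x$offset))
  invisible(x)
}

# per-component decay term, amplitude 1 at tau = 0
g_component <- function(kind, tau, tau_d, S) {
  base <- 1 / (1 + tau / tau_d)
  if (kind == "3D") base / sqrt(1 + tau / (S^2 * tau_d)) else base
}

#' Evaluate an FCS model at given lags
#'
#' @param model an [fcs_model()].
#' @param lags lag times in seconds (>= 0).
#' @return numeric vector of G values.
#' @export
eval_model <- function(model, lags) {
  stopifnot(inherits(model, "fcs_model"))
  lags <- as.numeric(lags)
  if (any(lags < 0)) stop("lags must be non-negative")
  acc <- numeric(length(lags))
  for (i in seq_along(model$kinds)) {
    acc <- acc + model$fractions[i] *
      g_component(model$kinds[i], lags, model$tau_d[i], model$S)
  }
  model$offset + acc / model$total_n
}

#' Noise-free analytic autocorrelation curve
#'
#' Exact model evaluation on a lag grid, used as fitting ground truth.
#'
#' @param model an [fcs_model()].
#' @param lags strictly increasing positive lag times in seconds.
#' @return An [acf_curve()] tagged with the generating model.
#' @export
analytic_acf <- function(model, lags) {
  acf_curve(lags, eval_model(model, lags), source = list(model = model))
}

default_fit_bounds <- function() {
  list(amplitude = c(1e-8, 1e8),   # per-component amplitude a_i = phi_i/N
       tau_d = c(1e-6, 10),
       S = c(2, 10),
       offset = c(-0.5, 0.5))
}

# Internal parameterization: per-component amplitudes a_i >= 0 (so fractions
# are automatically in [0,1] and sum to 1, and N = 1/sum(a_i)), free dwell
# times on log scale handled by box bounds in nls.lm.
fit_param_pack <- function(kinds, a, tau_free_idx, tau, S_free, S, off_free, off) {
  c(a,
    if (length(tau_free_idx)) tau[tau_free_idx],
    if (S_free) S,
    if (off_free) off)
}

#' Fit an FCS diffusion model to an autocorrelation curve
#'
#' Weighted least squares via Levenberg-Marquardt ([minpack.lm::nls.lm()])
#' with box bounds and a multi-start strategy over free dwell times (>= 5
#' log-spaced starting values spanning the lag range). Internally the model is
#' parameterized by per-component amplitudes `a_i = phi_i / N`, which keeps
#' fractions in `[0, 1]` without explicit constraints; `N = 1/sum(a_i)`.
#'
#' @param acf an [acf_curve()].
#' @param kinds component kinds, e.g. `"3D"` or `c("3D", "2D")`.
#' @param fixed named list of fixed parameters: `tau_d` (vector, one per
#'   component, `NA` where free), `S` (scalar; fixed when supplied), `offset`
#'   (scalar; `NULL` means fitted). The paper-style membrane fit fixes the 3D
#'   dwell time from a same-day solution measurement.
#' @param weights optional per-lag weights, `"sd"` to use `1/g_sd^2` from the
#'   curve, or `NULL` (unweighted).
#' @param bounds optional overrides of the default box bounds, a named list
#'   with any of `amplitude`, `tau_d`, `S`, `offset` (each `c(lower, upper)`).
#' @param n_starts number of multi-start dwell-time seeds (default 5).
#' @return An object of class `fcs_fit` with elements `model` (fitted
#'   [fcs_model()]), `se` (named approximate standard errors, including
#'   delta-method SEs for `total_n` and fractions), `rss`, `aicc`, `n_lags`,
#'   `converged`, `at_bound`, and `fixed` (record of fixed parameters).
#' @export
fit_acf <- function(acf, kinds, fixed = list(), weights = NULL, bounds = NULL,
                    n_starts = 5L) {
  stopifnot(inherits(acf, "acf_curve"))
  kinds <- toupper(as.character(kinds))
  k <- length(kinds)
  has3d <- any(kinds == "3D")
  bnd <- modifyList(default_fit_bounds(), bounds %||% list())

  tau_fixed <- fixed$tau_d %||% rep(NA_real_, k)
  if (length(tau_fixed) == 1L && k > 1L && is.na(tau_fixed))
    tau_fixed <- rep(NA_real_, k)
  if (length(tau_fixed) != k)
    stop("fixed$tau_d must have one entry per component (NA = free)")
  tau_free_idx <- which(is.na(tau_fixed))
  S_fixed <- fixed$S
  S_free <- has3d && is.null(S_fixed)
  off_fixed <- fixed$offset
  off_free <- is.null(off_fixed)
  if (!has3d && !is.null(S_fixed)) S_fixed <- NULL

  n_free <- k + length(tau_free_idx) + as.integer(S_free) + as.integer(off_free)
  if (length(acf$lags) < n_free + 5L)
    stop("need at least 5 more lags than free parameters")

  w <- NULL
  if (identical(weights, "sd")) {
    if (is.null(acf$g_sd)) stop("curve carries no g_sd; cannot weight by 'sd'")
    w <- ifelse(is.na(acf$g_sd) | acf$g_sd == 0, 0, 1 / acf$g_sd^2)
  } else if (!is.null(weights)) {
    if (length(weights) != length(acf$lags)) stop("weights length mismatch")
    w <- as.numeric(weights)
  }
  keep <- if (is.null(w)) rep(TRUE, length(acf$lags)) else w > 0
  lags <- acf$lags[keep]; gobs <- acf$g[keep]
  sw <- if (is.null(w)) rep(1, length(lags)) else sqrt(w[keep])

  unpack <- function(p) {
    a <- p[seq_len(k)]
    tau <- tau_fixed
    pos <- k
    if (length(tau_free_idx)) {
      tau[tau_free_idx] <- p[pos + seq_along(tau_free_idx)]
      pos <- pos + length(tau_free_idx)
    }
    S <- if (S_free) p[pos <- pos + 1L] else (S_fixed %||% NA_real_)
    off <- if (off_free) p[pos + 1L] else off_fixed
    list(a = a, tau = tau, S = S, off = off)
  }
  model_values <- function(p, tau_eval) {
    q <- unpack(p)
    acc <- numeric(length(tau_eval))
    for (i in seq_len(k))
      acc <- acc + q$a[i] * g_component(kinds[i], tau_eval, q$tau[i], q$S)
    q$off + acc
  }
  resid_fn <- function(p) sw * (model_values(p, lags) - gobs)

  lower <- c(rep(bnd$amplitude[1], k), rep(bnd$tau_d[1], length(tau_free_idx)),
             if (S_free) bnd$S[1], if (off_free) bnd$offset[1])
  upper <- c(rep(bnd$amplitude[2], k), rep(bnd$tau_d[2], length(tau_free_idx)),
             if (S_free) bnd$S[2], if (off_free) bnd$offset[2])

  # multi-start seeds for free dwell times: log-spaced across the lag range
  amp0 <- max(gobs[1], 1e-4)
  tau_lo <- max(min(lags), bnd$tau_d[1])
  tau_hi <- min(max(lags) / 3, bnd$tau_d[2])
  base_starts <- exp(seq(log(tau_lo), log(tau_hi), length.out = max(n_starts, 2L)))

  best <- NULL
  for (s in base_starts) {
    tau0 <- tau_fixed
    if (length(tau_free_idx)) {
      # stagger multiple free dwell times by decades around the seed
      tau0[tau_free_idx] <- pmin(pmax(s * 10^(seq_along(tau_free_idx) - 1),
                                      bnd$tau_d[1]), bnd$tau_d[2])
    }
    p0 <- c(rep(amp0 / k, k),
            if (length(tau_free_idx)) tau0[tau_free_idx],
            if (S_free) 5,
            if (off_free) 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("all fit starts failed")

  fit <- best$fit
  p <- fit$par
  converged <- fit$info %in% 1:3
  q <- unpack(p)
  a_sum <- sum(q$a)
  total_n <- 1 / a_sum
  fractions <- q$a / a_sum

  # order 2D components by dwell time for a stable labelling
  if (sum(kinds == "2D") > 1L) {
    i2 <- which(kinds == "2D")
    o <- i2[order(q$tau[i2])]
    perm <- seq_len(k); perm[i2] <- o
    kinds <- kinds[perm]; q$tau <- q$tau[perm]
    fractions <- fractions[perm]; q$a <- q$a[perm]
    tau_fixed <- tau_fixed[perm]
  }

  n_obs <- length(lags)
  npar <- length(p)
  dof <- n_obs - npar
  sigma2 <- best$rss / max(dof, 1L)
  jac <- num_jacobian(resid_fn, p)
  cov <- tryCatch(sigma2 * solve(crossprod(jac)), error = function(e) NULL)
  se <- rep(NA_real_, npar)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  names(se) <- param_names(kinds, tau_free_idx, S_free, off_free)

  # delta method: N = 1/sum(a); phi_i = a_i/sum(a)
  se_n <- NA_real_; se_phi <- rep(NA_real_, k)
  if (!is.null(cov)) {
    grad_n <- c(rep(-1 / a_sum^2, k), rep(0, npar - k))
    se_n <- sqrt(max(drop(t(grad_n) %*% cov %*% grad_n), 0))
    for (i in seq_len(k)) {
      gphi <- rep(0, npar)
      gphi[seq_len(k)] <- -q$a[i] / a_sum^2
      gphi[i] <- gphi[i] + 1 / a_sum
      se_phi[i] <- sqrt(max(drop(t(gphi) %*% cov %*% gphi), 0))
    }
  }

  at_bound <- any(abs(p - lower) < 1e-8 * pmax(abs(lower), 1)) ||
    any(abs(p - upper) < 1e-8 * pmax(abs(upper), 1))

  aicc <- n_obs * log(best$rss / n_obs) + 2 * npar +
    if (n_obs - npar - 1 > 0) 2 * npar * (npar + 1) / (n_obs - npar - 1) else Inf

  model <- fcs_model(kinds, total_n = total_n, tau_d = q$tau,
                     fractions = fractions,
                     S = if (has3d) q$S else NULL, offset = q$off)
  structure(list(
    model = model,
    se = c(se, total_n = se_n, setNames(se_phi, paste0("phi_", seq_len(k)))),
    rss = best$rss, aicc = aicc, n_lags = n_obs,
    converged = converged, at_bound = at_bound,
    fixed = list(tau_d = tau_fixed, S = S_fixed, offset = off_fixed),
    message = fit$message
  ), class = "fcs_fit")
}

param_names <- function(kinds, tau_free_idx, S_free, off_free) {
  c(paste0("a_", seq_along(kinds)),
    if (length(tau_free_idx)) paste0("tau_d_", tau_free_idx),
    if (S_free) "S",
    if (off_free) "offset")
}

num_jacobian <- function(fn, p, eps = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1e-8)
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> %s | converged: %s | RSS %.4g | AICc %.4g\n",
              paste(x$model$kinds, collapse = "+"),
              x$converged, x$rss, x$aicc))
  print(x$model)
  invisible(x)
}

#' Choose between one and two membrane (2D) components
#'
#' Fits `3D + 1x2D` and `3D + 2x2D` models with the 3D dwell time fixed (to a
#' same-day solution value, per standard practice) and returns the fit with
#' the lower corrected AIC. If the AICc difference is below 2, the simpler
#' model is preferred.
#'
#' @param acf an [acf_curve()] from a membrane-positioned measurement.
#' @param fixed_tau3d 3D dwell time in seconds to fix.
#' @param S structure parameter to fix (from calibration). Default 5.
#' @param ... further arguments passed to [fit_acf()].
#' @return The selected `fcs_fit`, with a `selection` element recording both
#'   AICc values and the rationale.
#' @export
select_membrane_model <- function(acf, fixed_tau3d, S = 5, ...) {
  f1 <- tryCatch(
    fit_acf(acf, c("3D", "2D"),
            fixed = list(tau_d = c(fixed_tau3d, NA), S = S), ...),
    error = function(e) e)
  f2 <- tryCatch(
    fit_acf(acf, c("3D", "2D", "2D"),
            fixed = list(tau_d = c(fixed_tau3d, NA, NA), S = S), ...),
    error = function(e) e)
  ok1 <- inherits(f1, "fcs_fit") && f1$converged
  ok2 <- inherits(f2, "fcs_fit") && f2$converged
  if (!ok1 && !ok2)
    stop("both membrane model fits failed: [1x2D] ",
         conditionMessage_or(f1), " | [2x2D] ", conditionMessage_or(f2))
  pick <- if (ok1 && !ok2) {
    list(fit = f1, why = "2x2D fit failed")
  } else if (ok2 && !ok1) {
    list(fit = f2, why = "1x2D fit failed")
  } else if (f2$aicc < f1$aicc - 2) {
    list(fit = f2, why = sprintf("AICc(2x2D) lower by %.2f", f1$aicc - f2$aicc))
  } else {
    list(fit = f1, why = sprintf("1x2D preferred (delta AICc %.2f < 2 or in favour)",
                                 if (ok2) f2$aicc - f1$aicc else NA))
  }
  out <- pick$fit
  out$selection <- list(
    aicc_1x2d = if (ok1) f1$aicc else NA_real_,
    aicc_2x2d = if (ok2) f2$aicc else NA_real_,
    chosen = paste(out$model$kinds, collapse = "+"),
    rationale = pick$why)
  out
}

conditionMessage_or <- function(x) {
  if (inherits(x, "condition")) conditionMessage(x)
  else if (inherits(x, "fcs_fit")) "did not converge"
  else "unknown failure"
}
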