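#' Normalized intensity autocorrelation curve
#'
#' Lag times and normalized autocorrelation values
#' G(tau) = <dI(t) dI(t+tau)> / <I>^2, optionally with a per-lag standard
#' deviation. Lag zero (the pure shot-noise point) is never included.
#'
#' @param lags strictly increasing vector of lag times in seconds (all > 0).
#' @param g autocorrelation values, same length as `lags`.
#' @param g_sd optional per-lag standard deviations (>= 0, NA allowed).
#' @param source named list identifying the origin (trace id or model id).
#' @return An object of class `acf_curve`.
#' @export
acf_curve <- function(lags, g, g_sd = NULL, source = list()) {
  lags <- as.numeric(lags); g <- as.numeric(g)
  if (length(lags) != length(g)) stop("lags and g must have equal length")
  if (any(lags <= 0)) stop("lags must be positive (lag 0 is excluded)")
  if (is.unsorted(lags, strictly = TRUE)) stop("lags must be strictly increasing")
  if (!is.null(g_sd)) {
    g_sd <- as.numeric(g_sd)
    if (length(g_sd) != length(g)) stop("g_sd must match g in length")
    if (any(g_sd < 0, na.rm = TRUE)) stop("g_sd must be non-negative")
  }
  structure(list(lags = lags, g = g, g_sd = g_sd, source = source),
            class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("<acf_curve> %d lags, %.3g s .. %.3g s, G(first lag) = %.4g\n",
              length(x$lags), min(x$lags), max(x$lags), x$g[1]))
  invisible(x)
}

# Symmetrically normalized autocorrelation of x at integer lags `ks`:
# G(k) = [ sum_i x_i x_{i+k} / (n-k) ] / (mean_head * mean_tail) - 1,
# mean_head over i in 1..n-k, mean_tail over i in k+1..n. The symmetric
# normalization (separate head/tail means) reduces bias from slow drift
# relative to dividing by the square of the global mean.
acf_at_lags <- function(x, ks) {
  n <- length(x)
  vapply(ks, function(k) {
    head <- x[seq_len(n - k)]
    tail <- x[seq.int(k + 1L, n)]
    mh <- mean(head); mt <- mean(tail)
    if (mh == 0 || mt == 0)
      stop("autocorrelation undefined: zero mean intensity in a segment")
    sum(head * tail) / ((n - k) * mh * mt) - 1
  }, numeric(1))
}

#' Brute-force autocorrelation at every integer lag
#'
#' Direct O(n * max_lag) evaluation of the symmetrically normalized
#' autocorrelation at every lag 1..`max_lag_bins`. Intended as the exact
#' reference estimator; use [multitau_autocorrelate()] for long traces.
#'
#' @param trace an [intensity_trace()].
#' @param max_lag_bins largest lag in bins (< trace length).
#' @return An [acf_curve()] with `max_lag_bins` lags.
#' @examples
#' tr <- intensity_trace(rep(c(2L, 0L), 5), 1e-3)
#' direct_autocorrelate(tr, 2)$g   # -1, 1 for a period-2 trace
#' @export
direct_autocorrelate <- function(trace, max_lag_bins) {
  stopifnot(inherits(trace, "intensity_trace"))
  max_lag_bins <- as.integer(max_lag_bins)
  n <- length(trace$counts)
  if (max_lag_bins < 1L || max_lag_bins >= n)
    stop("max_lag_bins must be in 1..(length - 1)")
  if (all(trace$counts == 0))
    stop("autocorrelation undefined for an all-zero trace")
  x <- as.numeric(trace$counts)
  ks <- seq_len(max_lag_bins)
  acf_curve(ks * trace$bin_width, acf_at_lags(x, ks),
            source = list(estimator = "direct",
                          trace = trace$metadata$id %||% NA))
}

#' Multi-tau autocorrelation on a quasi-logarithmic lag grid
#'
#' Standard multiple-tau scheme: `m` linearly spaced lags at the original bin
#' width (level 0), then per level the trace is coarsened by pairwise bin
#' summation and lags `m/2 + 1 .. m` (in coarsened bins) are evaluated, so the
#' physical lag spacing doubles per level. Every level uses the same
#' symmetric normalization as [direct_autocorrelate()]; level-0 values are
#' bit-identical to the direct estimator at the shared lags.
#'
#' Coarsening averages the true correlation over the (triangular) overlap of
#' the widened bins; because evaluated lags are always at least `m/2` coarse
#' bins, the relative triangular-averaging bias is bounded by roughly
#' `(2/m)^2` and is not corrected further.
#'
#' @param trace an [intensity_trace()].
#' @param m lags per level; even, >= 8. Default 16.
#' @param levels number of coarsening levels, or `NULL` (default) to extend
#'   the grid to about one tenth of the trace duration.
#' @param n_segments if > 1, the trace is split into this many contiguous
#'   segments and the per-lag standard error across segment ACFs is returned
#'   in `g_sd` (lags longer than a twentieth of a segment get `NA`).
#' @return An [acf_curve()].
#' @export
multitau_autocorrelate <- function(trace, m = 16L, levels = NULL,
                                   n_segments = 0L) {
  stopifnot(inherits(trace, "intensity_trace"))
  m <- as.integer(m)
  if (m < 8L || m %% 2L != 0L) stop("m must be an even integer >= 8")
  n <- length(trace$counts)
  if (all(trace$counts == 0))
    stop("autocorrelation undefined for an all-zero trace")
  duration <- n * trace$bin_width
  if (is.null(levels)) {
    levels <- 0L
    while (m * 2^(levels + 1) * trace$bin_width < duration / 10 &&
           n / 2^(levels + 1) >= 2L * m) {
      levels <- levels + 1L
    }
  }
  levels <- as.integer(levels)
  if (n / 2^levels < 2L * m)
    stop("trace too short for the requested number of levels")

  x <- as.numeric(trace$counts)
  width <- trace$bin_width
  lags <- (seq_len(m)) * width
  g <- acf_at_lags(x, seq_len(m))
  if (levels > 0L) {
    for (lev in seq_len(levels)) {
      keep <- (length(x) %/% 2L) * 2L
      x <- x[seq(1L, keep, by = 2L)] + x[seq(2L, keep, by = 2L)]
      width <- width * 2
      ks <- seq.int(m %/% 2L + 1L, m)
      lags <- c(lags, ks * width)
      g <- c(g, acf_at_lags(x, ks))
    }
  }

  g_sd <- NULL
  if (n_segments > 1L) {
    seg_len <- n %/% as.integer(n_segments)
    if (seg_len < 4L * m) stop("segments too short for SD estimation")
    seg_g <- vapply(seq_len(n_segments), function(s) {
      seg <- as.numeric(
        trace$counts[seq.int((s - 1L) * seg_len + 1L, s * seg_len)])
      vapply(lags, function(tau) {
        k <- as.integer(round(tau / trace$bin_width))
        if (k > seg_len %/% 20L) return(NA_real_)
        acf_at_lags(seg, k)
      }, numeric(1))
    }, numeric(length(lags)))
    g_sd <- apply(seg_g, 1L, function(v) {
      if (anyNA(v)) NA_real_ else sd(v) / sqrt(length(v))
    })
  }

  acf_curve(lags, g, g_sd,
            source = list(estimator = "multitau", m = m, levels = levels,
                          trace = trace$metadata$id %||% NA))
}
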