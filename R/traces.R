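#' Binned photon-count intensity trace
#'
#' Container for a fluorescence fluctuation record: non-negative photon counts
#' per time bin, the bin width, and free-form metadata (laser power label,
#' position label, background rate, simulation provenance).
#'
#' @param counts integer vector of photon counts per bin (all >= 0, length >= 2).
#' @param bin_width bin width in seconds (> 0).
#' @param metadata named list of free-form metadata.
#' @return An object of class `intensity_trace` with elements `counts`,
#'   `bin_width` and `metadata`.
#' @examples
#' tr <- intensity_trace(c(1L, 2L, 0L, 3L), bin_width = 1e-5)
#' mean_rate(tr)
#' @export
intensity_trace <- function(counts, bin_width, metadata = list()) {
  if (length(counts) < 2L)
    stop("an intensity trace needs at least 2 bins")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number")
  if (!is.list(metadata)) stop("metadata must be a list")
  structure(
    list(counts = as.integer(round(counts)), bin_width = as.numeric(bin_width),
         metadata = metadata),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  dur <- length(x$counts) * x$bin_width
  cat(sprintf(
    "<intensity_trace> %d bins x %.3g s = %.3g s, mean rate %.4g kHz\n",
    length(x$counts), x$bin_width, dur, mean_rate(x) / 1e3))
  invisible(x)
}

#' @export
length.intensity_trace <- function(x) length(x$counts)

#' Mean detected photon rate of a trace
#'
#' @param trace an [intensity_trace()].
#' @return mean count rate in counts per second.
#' @export
mean_rate <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  mean(trace$counts) / trace$bin_width
}

#' Coarsen a trace by summing adjacent bins
#'
#' Counts are summed in consecutive groups of `factor` bins and the bin width
#' multiplied accordingly; total counts are conserved over the retained span.
#' A trailing remainder that does not fill a whole group is dropped (reported
#' via a message and recorded in the metadata).
#'
#' @param trace an [intensity_trace()].
#' @param factor integer >= 2, coarsening factor.
#' @return A new [intensity_trace()] with `length %/% factor` bins.
#' @examples
#' rebin_trace(intensity_trace(c(1L, 2L, 3L, 4L), 1e-5), 2)$counts # 3, 7
#' @export
rebin_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "intensity_trace"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor <= 1L)
    stop("rebin factor must be an integer >= 2")
  n <- length(trace$counts)
  keep <- (n %/% factor) * factor
  if (keep < 2L * factor)
    stop("trace too short to rebin by this factor")
  dropped <- n - keep
  if (dropped > 0L)
    message(sprintf("rebin_trace: dropping %d trailing bin(s)", dropped))
  m <- matrix(trace$counts[seq_len(keep)], nrow = factor)
  meta <- trace$metadata
  meta$rebin_dropped_bins <- dropped
  intensity_trace(colSums(m), trace$bin_width * factor, meta)
}
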