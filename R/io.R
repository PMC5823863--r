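#' Read and write intensity traces, ACF curves and measurement tables
#'
#' All formats are plain CSV with a JSON sidecar (`<path>.json`) carrying the
#' metadata needed to reproduce or reinterpret the file (bin width, duration,
#' configuration echo, seed). Round trips are lossless.
#'
#' @param trace an [intensity_trace()].
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_*` return the path invisibly; `read_*` return the object.
#' @name trace_io
NULL

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  write.csv(data.frame(bin_index = seq_along(trace$counts) - 1L,
                       counts = trace$counts),
            path, row.names = FALSE)
  write_sidecar(path, list(
    type = "intensity_trace",
    bin_width_s = trace$bin_width,
    duration_s = length(trace$counts) * trace$bin_width,
    metadata = trace$metadata))
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "intensity_trace"))
    stop("sidecar does not describe an intensity trace")
  d <- read.csv(path)
  intensity_trace(d$counts, meta$bin_width_s,
                  metadata = as.list(meta$metadata %||% list()))
}

#' @rdname trace_io
#' @param acf an [acf_curve()].
#' @export
write_acf <- function(acf, path) {
  stopifnot(inherits(acf, "acf_curve"))
  write.csv(data.frame(lag_s = acf$lags, g = acf$g,
                       g_sd = acf$g_sd %||% NA_real_),
            path, row.names = FALSE)
  write_sidecar(path, list(type = "acf_curve", source = acf$source,
                           has_sd = !is.null(acf$g_sd)))
  invisible(path)
}

#' @rdname trace_io
#' @export
read_acf <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "acf_curve"))
    stop("sidecar does not describe an ACF curve")
  d <- read.csv(path)
  acf_curve(d$lag_s, d$g,
            g_sd = if (isTRUE(meta$has_sd)) d$g_sd else NULL,
            source = as.list(meta$source %||% list()))
}

#' @rdname trace_io
#' @param measurements a measurement table as returned by
#'   [generate_gradient_dataset()].
#' @export
write_measurements <- function(measurements, path) {
  need <- c("cell_id", "condition", "distance_um", "time_min", "conc_nM",
            "diff_coeff_m2s")
  if (!all(need %in% names(measurements)))
    stop("measurement table must have columns: ", paste(need, collapse = ", "))
  write.csv(measurements[, need], path, row.names = FALSE)
  frame <- attr(measurements, "reference_frame")
  write_sidecar(path, list(
    type = "measurements",
    reference_frame = if (is.null(frame)) NULL else as.list(frame),
    seed = attr(measurements, "seed")))
  invisible(path)
}

#' @rdname trace_io
#' @export
read_measurements <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "measurements"))
    stop("sidecar does not describe a measurement table")
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(meta$reference_frame))
    attr(d, "reference_frame") <- unlist(meta$reference_frame)
  attr(d, "seed") <- meta$seed
  d
}
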