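#' Sampled time series
#'
#' Lightweight container for a regularly sampled 1-D signal. Every signal that
#' moves through the pipeline (network time courses, voxel series, nuisance
#' components) is carried in one of these so that the sampling interval and
#' the signal level (neural vs BOLD) travel with the values. Level transitions
#' are restricted: only [convolve_bold()] turns a neural series into a BOLD
#' series and only [deconvolve_neural()] does the reverse.
#'
#' @param values numeric vector of samples, length >= 2.
#' @param tr sampling interval in seconds (the fMRI repetition time), > 0.
#' @param level signal level, `"bold"` or `"neural"`.
#' @param label free-text label (e.g. a network name such as `"SAL"`).
#' @return an object of class `netppi_ts` with fields `values`, `tr`,
#'   `level`, `label`.
#' @export
time_series <- function(values, tr, level = c("bold", "neural"), label = "") {
  level <- match.arg(level)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("time_series: need at least 2 samples, got ", length(values))
  if (!is.finite(tr) || tr <= 0)
    stop("time_series: tr must be a positive number of seconds")
  if (anyNA(values))
    stop("time_series: values contain NA")
  structure(list(values = values, tr = tr, level = level,
                 label = as.character(label)[1]),
            class = "netppi_ts")
}

is_time_series <- function(x) inherits(x, "netppi_ts")

#' @export
print.netppi_ts <- function(x, ...) {
  cat(sprintf("<netppi_ts '%s': %d samples, tr = %gs, level = %s>\n",
              x$label, length(x$values), x$tr, x$level))
  invisible(x)
}

#' @export
length.netppi_ts <- function(x) length(x$values)

# Accept either a netppi_ts or a bare numeric vector; internal fast path.
ts_values <- function(x) {
  if (is_time_series(x)) x$values else as.numeric(x)
}

# Replace values, keep metadata; optionally switch level.
ts_with_values <- function(x, values, level = NULL, label = NULL) {
  time_series(values, x$tr,
              level = if (is.null(level)) x$level else level,
              label = if (is.null(label)) x$label else label)
}

assert_level <- function(x, level, op) {
  if (!is_time_series(x))
    stop(op, ": expected a netppi_ts object")
  if (!identical(x$level, level))
    stop(op, ": series '", x$label, "' has level '", x$level,
         "' but level '", level, "' is required")
  invisible(x)
}

#' Rescale a time series to unit variance
#'
#' @param x a `netppi_ts`.
#' @return the same series with sample standard deviation 1. Errors on a
#'   constant series.
#' @export
scale_unit_variance <- function(x) {
  v <- ts_values(x)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("scale_unit_variance: series '",
         if (is_time_series(x)) x$label else "", "' has zero variance")
  if (is_time_series(x)) ts_with_values(x, v / s) else v / s
}
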