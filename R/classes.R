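#' Core signal containers
#'
#' Lightweight S3 containers used across the package. All traces are
#' uniformly sampled; times are seconds from session start unless noted.
#'
#' * `raw_trace()` — a raw fluorescence trace in arbitrary units.
#' * `lfp_trace()` — a local field potential trace in microvolts
#'   (digitized at 1 kHz by default).
#' * `spike_train()` — sorted spike timestamps of one unit together with the
#'   session extent they were recorded over.
#' * `track()` — open-field X/Y coordinates in cm.
#' * `binned_series()` — values over consecutive half-open time bins
#'   `[edge_i, edge_{i+1})`.
#'
#' @param samples numeric vector of samples.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample, seconds.
#' @param channel_id,unit_id optional label.
#' @param spike_times numeric vector of spike times, seconds, sorted.
#' @param extent length-2 numeric `(start, end)` of the recording, seconds.
#' @param times,x,y tracking sample times (s) and coordinates (cm).
#' @param edges increasing numeric vector of bin edges, seconds.
#' @param values per-bin values, `length(edges) - 1`.
#' @param units label describing the bin values (e.g. `"events/min"`).
#' @return An object of the corresponding class.
#' @name containers
NULL

#' @rdname containers
#' @export
raw_trace <- function(samples, sampling_rate, start_time = 0) {
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 1L || any(!is.finite(samples)))
    op_stop("trace samples must be non-empty and finite", "optophys_invalid_parameter")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "raw_trace")
}

#' @rdname containers
#' @export
lfp_trace <- function(samples, sampling_rate = 1000, start_time = 0,
                      channel_id = "lfp") {
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 1L || any(!is.finite(samples)))
    op_stop("LFP samples must be non-empty and finite", "optophys_invalid_parameter")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 start_time = start_time, channel_id = channel_id),
            class = "lfp_trace")
}

#' @rdname containers
#' @export
spike_train <- function(spike_times, extent, unit_id = "unit") {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times))
    op_stop("spike_times must be sorted", "optophys_invalid_parameter")
  if (length(extent) != 2L || extent[2] <= extent[1])
    op_stop("extent must be (start, end) with end > start", "optophys_invalid_parameter")
  if (length(spike_times) &&
      (min(spike_times) < extent[1] || max(spike_times) > extent[2]))
    op_stop("spike times outside session extent", "optophys_invalid_parameter")
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 extent = as.numeric(extent)),
            class = "spike_train")
}

#' @rdname containers
#' @export
track <- function(times, x, y, sampling_rate) {
  if (length(times) != length(x) || length(times) != length(y))
    op_stop("times, x, y must have equal length", "optophys_invalid_parameter")
  if (is.unsorted(times, strictly = TRUE))
    op_stop("track times must be strictly increasing", "optophys_invalid_input")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    op_stop("track coordinates must be finite", "optophys_invalid_parameter")
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), sampling_rate = sampling_rate),
            class = "track")
}

#' @rdname containers
#' @export
binned_series <- function(edges, values, units = "") {
  edges <- as.numeric(edges)
  if (is.unsorted(edges, strictly = TRUE))
    op_stop("bin edges must be strictly increasing", "optophys_invalid_parameter")
  if (length(values) != length(edges) - 1L)
    op_stop("need length(values) == length(edges) - 1", "optophys_invalid_parameter")
  structure(list(edges = edges, values = as.numeric(values), units = units),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> %d bins of %.4g s [%s]\n",
              length(x$values), x$edges[2] - x$edges[1], x$units))
  invisible(x)
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> '%s' %d samples @ %g Hz\n",
              x$channel_id, length(x$samples), x$sampling_rate))
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> '%s' %d spikes over [%g, %g] s (%.3f Hz)\n",
              x$unit_id, length(x$spike_times), x$extent[1], x$extent[2],
              length(x$spike_times) / diff(x$extent)))
  invisible(x)
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> %d samples @ %g Hz, %.1f s\n",
              length(x$times), x$sampling_rate, diff(range(x$times))))
  invisible(x)
}

# internal: duration in seconds of any trace-like object
trace_duration <- function(tr) length(tr$samples) / tr$sampling_rate

# internal: sample times of a trace
trace_times <- function(tr)
  tr$start_time + (seq_along(tr$samples) - 1) / tr$sampling_rate
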