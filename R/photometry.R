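#' Normalize a fluorescence trace to dF/F with a sliding baseline
#'
#' The baseline F at each sample is the mean of the raw trace over a centered
#' window of `window` seconds (default 2 min), clipped to the trace extent,
#' so bleaching correction and normalization happen in one step:
#' `dF/F = (x - F) / F`. The output is scale invariant
#' (`normalize_dff(k * x) == normalize_dff(x)` for k > 0) and identically
#' zero for a constant trace.
#'
#' @param trace a [raw_trace()].
#' @param window baseline window length, seconds (> 0).
#' @return A `normalized_trace`: same length and rate as the input, samples
#'   in dF/F fractions, with the window length recorded.
#' @export
normalize_dff <- function(trace, window = 120) {
  stopifnot(inherits(trace, "raw_trace"))
  check_scalar(window, "window", positive = TRUE)
  x <- trace$samples
  n <- length(x)
  h <- round(window / 2 * trace$sampling_rate)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  baseline <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  bad <- which(baseline <= 0)
  if (length(bad))
    op_stop(sprintf("baseline F <= 0 over samples %d..%d; dF/F undefined",
                    min(bad), max(bad)),
            "optophys_degenerate_baseline")
  structure(list(samples = (x - baseline) / baseline,
                 sampling_rate = trace$sampling_rate,
                 start_time = trace$start_time, window_length = window),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> %d samples @ %g Hz, baseline window %g s\n",
              length(x$samples), x$sampling_rate, x$window_length))
  invisible(x)
}

# internal: indices of strict local maxima of a numeric vector
local_maxima <- function(d) {
  n <- length(d)
  if (n < 3L) return(integer(0))
  which(c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] > d[3:n], FALSE))
}

# internal: centered boxcar smoothing, edges keep the raw value
smooth_boxcar <- function(d, w) {
  if (w <= 1L) return(d)
  ds <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
  na <- is.na(ds)
  ds[na] <- d[na]
  ds
}

#' Detect calcium transients in a dF/F trace
#'
#' Events are local maxima of the (lightly smoothed) dF/F trace exceeding
#' `threshold` (strict `>`), thinned so that surviving events are at least
#' `min_interval` apart. Thinning is greedy in descending amplitude order
#' (ties resolved toward the earlier peak). To reject noise wiggles riding
#' on the slow decay tail of a previous transient, a candidate must also
#' rise more than `min_rise` above the minimum of the smoothed trace over
#' the preceding `min_interval` seconds — a real transient has a sharp
#' onset, a tail wiggle does not. Set `min_rise = 0` and
#' `smooth_window = 0` for bare local-maxima detection.
#'
#' @param norm a `normalized_trace` from [normalize_dff()].
#' @param threshold event threshold, dF/F fraction (default 0.05 = 5%).
#' @param min_interval minimum inter-event interval, seconds.
#' @param min_rise minimum onset rise above the preceding-window minimum,
#'   dF/F fraction; default half the threshold.
#' @param smooth_window boxcar width for candidate detection, seconds.
#' @return A `transient_set` with `event_times` (s, absolute),
#'   `event_amplitudes` (dF/F at the peak), and the detection parameters.
#' @export
detect_transients <- function(norm, threshold = 0.05, min_interval = 1.0,
                              min_rise = threshold / 2, smooth_window = 0.1) {
  stopifnot(inherits(norm, "normalized_trace"))
  check_scalar(threshold, "threshold", positive = TRUE)
  check_scalar(min_interval, "min_interval", nonneg = TRUE)
  fs <- norm$sampling_rate
  d <- smooth_boxcar(norm$samples, max(1L, round(smooth_window * fs)))
  idx <- local_maxima(d)
  idx <- idx[d[idx] > threshold]
  if (min_rise > 0 && length(idx)) {
    hb <- max(1L, round(min_interval * fs))
    rise <- vapply(idx, function(i) d[i] - min(d[max(1L, i - hb):i]), 0)
    idx <- idx[rise > min_rise]
  }
  kept_t <- numeric(0); kept_a <- numeric(0)
  if (length(idx)) {
    ord <- idx[order(-d[idx], idx)]
    tcand <- (ord - 1L) / fs
    for (k in seq_along(ord)) {
      if (!length(kept_t) || all(abs(tcand[k] - kept_t) >= min_interval)) {
        kept_t <- c(kept_t, tcand[k])
        kept_a <- c(kept_a, d[ord[k]])
      }
    }
    o <- order(kept_t)
    kept_t <- kept_t[o]; kept_a <- kept_a[o]
  }
  structure(list(event_times = kept_t + norm$start_time,
                 event_amplitudes = kept_a, threshold = threshold,
                 min_interval = min_interval),
            class = "transient_set")
}

#' @export
print.transient_set <- function(x, ...) {
  cat(sprintf("<transient_set> %d events (> %g dF/F, >= %g s apart)\n",
              length(x$event_times), x$threshold, x$min_interval))
  invisible(x)
}

#' Screen control traces for movement artifacts
#'
#' A fluorophore-only (eYFP) control trace fails the screen if any strict
#' local maximum of its raw dF/F exceeds the cutoff. Recordings whose
#' controls pass support using the cutoff to separate calcium transients
#' from motion artifacts.
#'
#' @param norm_traces a `normalized_trace` or list of them.
#' @param threshold dF/F cutoff (default 0.05).
#' @return Logical vector: `TRUE` if the trace exceeds the cutoff.
#' @export
artifact_screen <- function(norm_traces, threshold = 0.05) {
  if (inherits(norm_traces, "normalized_trace"))
    norm_traces <- list(norm_traces)
  if (!length(norm_traces))
    op_stop("need at least one trace", "optophys_invalid_parameter")
  vapply(norm_traces, function(tr) {
    idx <- local_maxima(tr$samples)
    length(idx) > 0 && any(tr$samples[idx] > threshold)
  }, logical(1))
}

# internal: shared binning of event times into half-open [l, r) bins
bin_edges_for <- function(extent, bin) {
  nb <- floor((extent[2] - extent[1]) / bin + 1e-9)
  if (nb < 1L)
    op_stop("extent shorter than one bin", "optophys_invalid_parameter")
  extent[1] + bin * (0:nb)
}

#' Bin event times into a rate time-course
#'
#' Counts events in consecutive half-open bins `[left, right)` (an event on
#' an edge goes to the later bin) and converts counts to events/min.
#'
#' @param events a `transient_set` (or numeric vector of event times, s).
#' @param bin bin width, seconds (> 0; default 60).
#' @param extent `c(start, end)` of the session, s; must cover all events.
#'   Only complete bins are formed.
#' @return A [binned_series()] in events/min.
#' @export
bin_event_rate <- function(events, bin = 60, extent) {
  times <- if (inherits(events, "transient_set")) events$event_times
           else as.numeric(events)
  check_scalar(bin, "bin", positive = TRUE)
  if (length(times) && (min(times) < extent[1] || max(times) > extent[2]))
    op_stop("events outside the session extent", "optophys_invalid_parameter")
  edges <- bin_edges_for(extent, bin)
  counts <- tabulate(findInterval(times, edges, left.open = FALSE),
                     nbins = length(edges))[seq_len(length(edges) - 1L)]
  binned_series(edges, counts * 60 / bin, units = "events/min")
}

#' Normalize a binned series to its pre-manipulation mean
#'
#' Expresses every bin as a percentage of the mean over the first
#' `n_pre_bins` bins (the pre-injection baseline).
#'
#' @param binned a [binned_series()].
#' @param n_pre_bins number of leading baseline bins (default 30).
#' @return A [binned_series()] in percent of the pre mean.
#' @export
percent_of_pre <- function(binned, n_pre_bins = 30) {
  stopifnot(inherits(binned, "binned_series"))
  if (n_pre_bins < 1L || n_pre_bins > length(binned$values))
    op_stop("n_pre_bins outside the series", "optophys_range_error")
  pre_mean <- mean(binned$values[seq_len(n_pre_bins)])
  if (!is.finite(pre_mean) || pre_mean == 0)
    op_stop("pre-period mean is zero; percent-of-pre undefined",
            "optophys_normalization_undefined")
  binned_series(binned$edges, 100 * binned$values / pre_mean,
                units = "% of pre")
}

#' Average a binned series over pre and post analysis windows
#'
#' Windows are given as bin-index ranges (1-based, inclusive). For a 60-min
#' session in 1-min bins with injection at 30 min, the defaults average
#' minutes 11-30 (pre) and 41-60 (post).
#'
#' @param binned a [binned_series()].
#' @param pre_window,post_window integer bin indices to average.
#' @return Named numeric `c(pre_mean, post_mean)`.
#' @export
summarize_windows <- function(binned, pre_window = 11:30,
                              post_window = 41:60) {
  stopifnot(inherits(binned, "binned_series"))
  nb <- length(binned$values)
  if (min(pre_window) < 1L || max(post_window) > nb ||
      min(post_window) < 1L || max(pre_window) > nb)
    op_stop("analysis window outside the session", "optophys_range_error")
  c(pre_mean = mean(binned$values[pre_window]),
    post_mean = mean(binned$values[post_window]))
}

#' Dead-time-corrected transient rate
#'
#' The enforced minimum inter-event interval censors events: two transients
#' closer than `min_interval` can never both be counted, so the raw count
#' rate under-estimates the true Poisson rate at high rates. For a Poisson
#' process thinned by a hard-core rule of radius `min_interval` the expected
#' observed rate is `r = (1 - exp(-2 * delta * lambda)) / (2 * delta)`
#' (a point survives if no competitor falls within `min_interval` on either
#' side); inverting gives the corrected estimate
#' `lambda_hat = -log(1 - 2 * delta * r) / (2 * delta)`.
#'
#' @param events a `transient_set`.
#' @param extent `c(start, end)` of the recording, s.
#' @param correct logical; apply the dead-time correction (default `TRUE`).
#' @return Estimated event rate, events/min.
#' @export
transient_rate <- function(events, extent, correct = TRUE) {
  stopifnot(inherits(events, "transient_set"))
  dur <- extent[2] - extent[1]
  check_scalar(dur, "extent length", positive = TRUE)
  r <- length(events$event_times) / dur          # events per second
  if (!correct || events$min_interval <= 0) return(r * 60)
  delta <- events$min_interval
  if (2 * delta * r >= 1)
    op_stop("observed rate at the dead-time saturation limit",
            "optophys_invalid_input")
  60 * (-log(1 - 2 * delta * r) / (2 * delta))
}
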