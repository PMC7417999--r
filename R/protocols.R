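#' Stimulation schedule container
#'
#' A `stim_schedule` is an explicit list of light-pulse onsets (seconds from
#' the start of the protocol epoch; the first onset of every builder is at
#' t = 0) plus the pulse width. Multi-block protocols carry their block
#' boundaries so downstream trial extraction can exclude pulses delivered
#' inside plasticity-induction blocks.
#'
#' @param onsets strictly increasing pulse-onset times, seconds.
#' @param pulse_width pulse duration, seconds.
#' @param protocol_name label, e.g. `"test"`, `"lfs"`, `"tbs"`, `"hfs"`.
#' @param block_boundaries optional list of `c(start, end)` windows (s) for
#'   multi-block protocols; must be non-overlapping.
#' @return A `stim_schedule` object.
#' @export
stim_schedule <- function(onsets, pulse_width, protocol_name = "custom",
                          block_boundaries = NULL) {
  onsets <- as.numeric(onsets)
  check_scalar(pulse_width, "pulse_width", positive = TRUE)
  if (length(onsets) == 0L)
    op_stop("schedule needs at least one onset", "optophys_invalid_parameter")
  if (is.unsorted(onsets, strictly = TRUE))
    op_stop("onsets must be strictly increasing", "optophys_invalid_parameter")
  if (length(onsets) > 1L && min(diff(onsets)) < pulse_width)
    op_stop("consecutive onsets closer than pulse_width", "optophys_invalid_parameter")
  if (!is.null(block_boundaries)) {
    bb <- do.call(rbind, lapply(block_boundaries, as.numeric))
    if (ncol(bb) != 2L || any(bb[, 2] <= bb[, 1]))
      op_stop("block boundaries must be (start, end), end > start",
              "optophys_invalid_parameter")
    o <- order(bb[, 1])
    if (nrow(bb) > 1L && any(bb[o, 1][-1] < bb[o, 2][-nrow(bb)]))
      op_stop("block boundaries overlap", "optophys_invalid_parameter")
  }
  structure(list(onsets = onsets, pulse_width = pulse_width,
                 protocol_name = protocol_name,
                 block_boundaries = block_boundaries),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> '%s': %d pulses of %g ms, span %.1f s\n",
              x$protocol_name, length(x$onsets), 1000 * x$pulse_width,
              max(x$onsets) + x$pulse_width))
  invisible(x)
}

# internal: regular pulse train, first onset 0, pulses fully inside duration
regular_onsets <- function(rate_hz, duration) {
  seq(0, duration, by = 1 / rate_hz)
}

#' Stimulation protocol builders
#'
#' Construct the study's four light-delivery protocols as explicit pulse
#' schedules:
#'
#' * `build_test_pulses(duration)` — sparse probe pulses: 15 ms pulses at
#'   0.2 Hz (one every 5 s), used to monitor evoked-response strength without
#'   inducing plasticity. 1800 s gives 360 pulses.
#' * `build_lfs()` — low-frequency stimulation: 15 ms pulses at 5 Hz for
#'   15 min (4500 pulses).
#' * `build_tbs()` — theta-burst stimulation: 10 repetitions of 10 bursts at
#'   theta frequency (10.5 Hz), each burst 4 pulses at 50 Hz (400 pulses).
#'   Each repetition is recorded as one block.
#' * `build_hfs()` — high-frequency stimulation: two 5-min blocks of 60 Hz
#'   pulses separated by a 14-min interval (36,000 pulses; second block ends
#'   1440 s after protocol start).
#'
#' All onsets are relative to the protocol epoch (first pulse at t = 0);
#' place a protocol in absolute session time by adding its start time
#' (e.g. via [shift_schedule()]).
#'
#' @param duration epoch length for test pulses, seconds (> 0). Pulses are
#'   kept only if they fit entirely (`onset + width <= duration`).
#' @param pulse_width pulse duration in seconds; 0.015 for all protocols.
#' @param rep_interval_s TBS only: interval between repetition onsets,
#'   seconds. Not stated by the source protocol; default 10 s keeps the ten
#'   repetitions non-overlapping (one repetition spans < 1 s).
#' @return A [stim_schedule()].
#' @name protocol_builders
NULL

#' @rdname protocol_builders
#' @export
build_test_pulses <- function(duration, pulse_width = 0.015) {
  check_scalar(duration, "duration", positive = TRUE)
  on <- regular_onsets(0.2, duration)
  on <- on[on + pulse_width <= duration]
  if (!length(on)) on <- 0
  stim_schedule(on, pulse_width, "test")
}

#' @rdname protocol_builders
#' @export
build_lfs <- function(pulse_width = 0.015) {
  on <- seq(0, by = 1 / 5, length.out = 5 * 900)
  stim_schedule(on, pulse_width, "lfs")
}

#' @rdname protocol_builders
#' @export
build_tbs <- function(pulse_width = 0.015, rep_interval_s = 10) {
  check_scalar(rep_interval_s, "rep_interval_s", positive = TRUE)
  burst <- (0:3) * (1 / 50)                 # 4 pulses at 50 Hz
  rep_pattern <- as.vector(outer(burst, (0:9) / 10.5, `+`))  # 10 bursts at 10.5 Hz
  on <- as.vector(outer(sort(rep_pattern), (0:9) * rep_interval_s, `+`))
  blocks <- lapply(0:9, function(r)
    c(r * rep_interval_s, r * rep_interval_s + max(rep_pattern) + pulse_width))
  stim_schedule(sort(on), pulse_width, "tbs", block_boundaries = blocks)
}

#' @rdname protocol_builders
#' @export
build_hfs <- function(pulse_width = 0.015) {
  block <- seq(0, by = 1 / 60, length.out = 60 * 300)  # 18,000 pulses / block
  gap <- 14 * 60
  on <- c(block, 300 + gap + block)
  blocks <- list(c(0, 300), c(300 + gap, 300 + gap + 300))
  stim_schedule(on, pulse_width, "hfs", block_boundaries = blocks)
}

#' Shift a schedule in absolute session time
#'
#' @param schedule a [stim_schedule()].
#' @param start absolute start time of the protocol epoch, seconds.
#' @return The shifted schedule.
#' @export
shift_schedule <- function(schedule, start) {
  check_scalar(start, "start")
  schedule$onsets <- schedule$onsets + start
  if (!is.null(schedule$block_boundaries))
    schedule$block_boundaries <- lapply(schedule$block_boundaries,
                                        function(b) b + start)
  schedule
}
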