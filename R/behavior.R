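# internal: per-segment Euclidean path lengths and segment start times
path_segments <- function(track) {
  n <- length(track$times)
  if (n < 2L)
    op_stop("need at least 2 tracking samples", "optophys_invalid_input")
  list(t0 = track$times[-n],
       len = sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' Instant velocity from tracking coordinates
#'
#' Accumulates the Euclidean path length over consecutive windows of
#' `window` seconds (default 1 s) and divides by the window: a within-window
#' direction change still counts as distance travelled. Only complete
#' windows are returned. Invariant under rigid translation/rotation of the
#' coordinate frame.
#'
#' @param track a [track()].
#' @param window velocity window, s (> 0).
#' @return A [binned_series()] in cm/s with `window`-second bins.
#' @export
instant_velocity <- function(track, window = 1) {
  stopifnot(inherits(track, "track"))
  check_scalar(window, "window", positive = TRUE)
  seg <- path_segments(track)
  extent <- c(track$times[1], max(track$times))
  edges <- bin_edges_for(extent, window)
  idx <- findInterval(seg$t0, edges, left.open = FALSE)
  nb <- length(edges) - 1L
  keep <- idx >= 1L & idx <= nb
  sums <- rowsum(seg$len[keep], idx[keep])
  v <- numeric(nb)
  v[as.integer(rownames(sums))] <- sums[, 1]
  binned_series(edges, v / window, units = "cm/s")
}

#' Binned, pre-normalized velocity time-course
#'
#' Averages the instant-velocity series into `bin`-second bins and expresses
#' each bin as percent of the mean over the first `n_pre_bins` bins.
#'
#' @param track a [track()].
#' @param bin bin width, s (default 60).
#' @param n_pre_bins number of pre-manipulation baseline bins (default 30).
#' @param window instant-velocity window, s.
#' @return A [binned_series()] in percent of the pre mean.
#' @export
velocity_timecourse <- function(track, bin = 60, n_pre_bins = 30, window = 1) {
  iv <- instant_velocity(track, window)
  centers <- iv$edges[-length(iv$edges)]
  extent <- c(iv$edges[1], max(iv$edges))
  edges <- bin_edges_for(extent, bin)
  idx <- findInterval(centers, edges, left.open = FALSE)
  keep <- idx >= 1L & idx <= length(edges) - 1L
  m <- vapply(seq_len(length(edges) - 1L), function(k)
    mean(iv$values[keep][idx[keep] == k]), numeric(1))
  percent_of_pre(binned_series(edges, m, "cm/s"), n_pre_bins)
}

#' Distance moved over analysis windows
#'
#' Sums the Euclidean path length over one or more time windows (e.g. the
#' 14-min inter-HFS interval plus the 16 min after the second HFS block in
#' the sensitization assay).
#'
#' @param track a [track()].
#' @param windows list of `c(start, end)` windows, s, within the track
#'   extent. A segment contributes to the window containing its start time.
#' @return Total distance, cm.
#' @export
distance_moved <- function(track, windows) {
  stopifnot(inherits(track, "track"))
  if (inherits(windows, "numeric") && length(windows) == 2L)
    windows <- list(windows)
  seg <- path_segments(track)
  extent <- range(track$times)
  total <- 0
  for (w in windows) {
    if (w[1] < extent[1] - 1e-9 || w[2] > extent[2] + 1e-9 || w[2] <= w[1])
      op_stop("window outside the track extent", "optophys_range_error")
    total <- total + sum(seg$len[seg$t0 >= w[1] & seg$t0 < w[2]])
  }
  total
}

#' One-sided 3-SD subject exclusion
#'
#' A subject is excluded when its metric exceeds the mean of the *other*
#' subjects by more than `n_sd` of their standard deviation (leave-one-out,
#' Grubbs-style; only high outliers are excluded). Zero residual variance
#' excludes nobody.
#'
#' @param values per-subject metric (length >= 3).
#' @param n_sd exclusion threshold in standard deviations (default 3).
#' @return Logical inclusion mask (`TRUE` = keep).
#' @export
exclude_outliers <- function(values, n_sd = 3) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    op_stop("need at least 3 subjects", "optophys_invalid_parameter")
  keep <- vapply(seq_along(values), function(i) {
    rest <- values[-i]
    s <- sd(rest)
    if (!is.finite(s) || s == 0) return(TRUE)
    values[i] <= mean(rest) + n_sd * s
  }, logical(1))
  keep
}
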