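#' Bin a spike train into a firing-rate time-course
#'
#' Counts spikes in consecutive half-open `[left, right)` bins over the
#' train's session extent and converts counts to Hz.
#'
#' @param train a [spike_train()].
#' @param bin bin width, seconds (> 0; default 60).
#' @return A [binned_series()] in Hz.
#' @export
bin_firing <- function(train, bin = 60) {
  stopifnot(inherits(train, "spike_train"))
  check_scalar(bin, "bin", positive = TRUE)
  edges <- bin_edges_for(train$extent, bin)
  counts <- tabulate(findInterval(train$spike_times, edges, left.open = FALSE),
                     nbins = length(edges))[seq_len(length(edges) - 1L)]
  binned_series(edges, counts / bin, units = "Hz")
}

#' Pre/post window means of a binned firing-rate series
#'
#' Thin wrapper over [summarize_windows()] with the unit-analysis defaults:
#' bins 11-30 of the pre period and bins 11-30 of the post period (session
#' bins 41-60 for a 60-min session with the manipulation at 30 min).
#'
#' @inheritParams summarize_windows
#' @return Named numeric `c(pre_mean, post_mean)`.
#' @export
window_means <- function(binned, pre_window = 11:30, post_window = 41:60) {
  summarize_windows(binned, pre_window, post_window)
}

#' Modulation call container
#'
#' Produced by [classify_unit()] and [classify_lfp()]. The label is
#' `"non-modulated"` exactly when `p_value >= alpha_corrected`; a
#' significant signal is `"potentiated"` if the post window is above 100% of
#' the pre window and `"depressed"` if below.
#'
#' @param unit_id label of the classified signal.
#' @param p_value paired-test p-value.
#' @param alpha_corrected Bonferroni-corrected significance threshold.
#' @param percent_change post mean as percent of pre mean.
#' @param flag optional character note (e.g. `"zero-variance"`).
#' @return A `modulation_call`.
#' @export
modulation_call <- function(unit_id, p_value, alpha_corrected,
                            percent_change, flag = NA_character_) {
  label <- if (!is.finite(p_value) || p_value >= alpha_corrected)
    "non-modulated"
  else if (percent_change > 100) "potentiated" else "depressed"
  structure(list(unit_id = unit_id, p_value = p_value,
                 alpha_corrected = alpha_corrected,
                 percent_change = percent_change, label = label,
                 flag = flag),
            class = "modulation_call")
}

#' @export
print.modulation_call <- function(x, ...) {
  cat(sprintf("<modulation_call> '%s': %s (p = %.3g, alpha = %.3g, %.1f%% of pre)%s\n",
              x$unit_id, x$label, x$p_value, x$alpha_corrected,
              x$percent_change,
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

# internal: paired t-test on two equal-length bin windows of a series,
# with the degenerate zero-variance case mapped to p = 1 and flagged
classify_series <- function(binned, pre_window, post_window, alpha,
                            n_comparisons, id) {
  stopifnot(inherits(binned, "binned_series"))
  if (length(pre_window) != length(post_window))
    op_stop("pre and post test windows must pair equal numbers of bins",
            "optophys_invalid_parameter")
  nb <- length(binned$values)
  if (min(c(pre_window, post_window)) < 1L ||
      max(c(pre_window, post_window)) > nb)
    op_stop("test window outside the series", "optophys_range_error")
  if (n_comparisons < 1)
    op_stop("n_comparisons must be >= 1", "optophys_invalid_parameter")
  pre <- binned$values[pre_window]
  post <- binned$values[post_window]
  diffs <- post - pre
  flag <- NA_character_
  if (sd(diffs) == 0) {
    p <- 1
    flag <- "zero-variance"
  } else {
    p <- t.test(post, pre, paired = TRUE)$p.value
  }
  pre_mean <- mean(pre)
  pct <- if (pre_mean == 0) NA_real_ else 100 * mean(post) / pre_mean
  if (is.na(pct)) flag <- paste(stats::na.omit(c(flag, "zero-pre-mean")),
                                collapse = ";")
  modulation_call(id, p, alpha / n_comparisons, pct, flag)
}

#' Classify a unit as potentiated, depressed or non-modulated
#'
#' Two-sided paired t-test between pre- and post-manipulation firing-rate
#' bins (paired by index within the window — the only order-preserving
#' pairing), significant if `p < alpha / n_comparisons` (Bonferroni).
#' Direction from the percent-of-pre rule: a significant change above 100%
#' is a potentiation, below 100% a depression. Identical windows (zero
#' difference variance) are treated as p = 1 and flagged.
#'
#' @param binned a [binned_series()] from [bin_firing()].
#' @param test_window_pre,test_window_post equal-length bin-index windows
#'   (defaults: bins 11-30 of each 30-bin period of a 60-min session).
#' @param alpha uncorrected significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor: the number of signals tested
#'   simultaneously in the cohort (default 1).
#' @param unit_id label carried into the call.
#' @return A [modulation_call()].
#' @export
classify_unit <- function(binned, test_window_pre = 11:30,
                          test_window_post = 41:60, alpha = 0.05,
                          n_comparisons = 1, unit_id = "unit") {
  classify_series(binned, test_window_pre, test_window_post, alpha,
                  n_comparisons, unit_id)
}

#' Firing-rate time-course as percent of the pre-manipulation mean
#'
#' Identical contract to [percent_of_pre()]; provided under the
#' unit-analysis name.
#'
#' @inheritParams percent_of_pre
#' @export
timecourse_percent_of_pre <- function(binned, n_pre_bins = 30) {
  percent_of_pre(binned, n_pre_bins)
}

#' Tally modulation calls for a cohort pie chart
#'
#' @param calls list of [modulation_call()] objects.
#' @return Named integer vector
#'   `c(potentiated, depressed, `non-modulated`)`; sums to `length(calls)`.
#' @export
cohort_pie <- function(calls) {
  labels <- vapply(calls, function(cl) cl$label, character(1))
  out <- c(potentiated = sum(labels == "potentiated"),
           depressed = sum(labels == "depressed"),
           "non-modulated" = sum(labels == "non-modulated"))
  storage.mode(out) <- "integer"
  out
}

#' Classify a cohort of spike trains
#'
#' Bins each train, classifies it with [classify_unit()], and applies the
#' cohort-level Bonferroni divisor (`n_comparisons` defaults to the number
#' of units classified together).
#'
#' @param trains list of [spike_train()] objects.
#' @param bin bin width, s.
#' @param ... passed to [classify_unit()].
#' @param n_comparisons Bonferroni divisor; default `length(trains)`.
#' @return List of [modulation_call()] objects.
#' @export
classify_cohort <- function(trains, bin = 60, ...,
                            n_comparisons = length(trains)) {
  lapply(trains, function(tr)
    classify_unit(bin_firing(tr, bin), ...,
                  n_comparisons = n_comparisons, unit_id = tr$unit_id))
}
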