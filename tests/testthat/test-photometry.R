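test_that("dF/F of constant traces is zero and scaling is invariant", {
  tr <- raw_trace(rep(42, 1000), 10)
  expect_equal(normalize_dff(tr)$samples, rep(0, 1000))

  gt <- random_photometry_gt(3, seed = 2, duration = 300)
  x <- generate_photometry(gt, seed = 2)$trace
  xk <- raw_trace(7.3 * x$samples, x$sampling_rate)
  expect_equal(normalize_dff(xk)$samples, normalize_dff(x)$samples,
               tolerance = 1e-12)
})

test_that("windowed-mean baseline matches the brute-force oracle", {
  tr <- bump_trace()
  got <- normalize_dff(tr)$samples
  expect_equal(got, oracle_dff(tr$samples, tr$sampling_rate),
               tolerance = 1e-12)
  # 2 s rectangular bump 100 -> 110 inflates its own 120 s window mean:
  # F = (1181*100 + 20*110)/1201 (2h+1 samples), peak dF/F ~ 0.0982
  f_peak <- 120300 / 1201
  expect_equal(max(got), (110 - f_peak) / f_peak, tolerance = 1e-9)
})

test_that("non-positive baselines raise a degenerate-baseline error", {
  tr <- raw_trace(c(rep(1, 50), rep(-2, 500), rep(1, 50)), 10)
  expect_error(normalize_dff(tr), class = "optophys_degenerate_baseline")
})

test_that("transient detection applies threshold, greedy interval and ties", {
  empty <- detect_transients(as_norm(numeric(6000)))
  expect_length(empty$event_times, 0)

  # two peaks 0.5 s apart: only the taller survives the 1 s interval
  two <- peak_trace(c(30, 30.5), c(0.10, 0.08))
  ev <- detect_transients(two, smooth_window = 0, min_rise = 0)
  expect_equal(ev$event_times, 30)
  expect_equal(ev$event_amplitudes, 0.10)

  # amplitude exactly at the threshold is excluded (strict >)
  at_thr <- peak_trace(30, 0.05)
  expect_length(detect_transients(at_thr, smooth_window = 0,
                                  min_rise = 0)$event_times, 0)

  # equal amplitudes: the earlier peak wins the tie
  tie <- peak_trace(c(30, 30.6), c(0.10, 0.10))
  ev2 <- detect_transients(tie, smooth_window = 0, min_rise = 0)
  expect_equal(ev2$event_times, 30)
})

test_that("detected events respect the transient-set invariants", {
  for (seed in 1:4) {
    gt <- random_photometry_gt(6, seed = seed, duration = 600)
    norm <- normalize_dff(generate_photometry(gt, seed = seed)$trace)
    ev <- detect_transients(norm)
    if (length(ev$event_times) > 1) {
      expect_true(all(diff(ev$event_times) >= ev$min_interval))
      expect_true(all(diff(ev$event_times) > 0))
    }
    expect_true(all(ev$event_amplitudes > ev$threshold))
  }
})

test_that("event count is monotone in threshold and min_interval", {
  gt <- random_photometry_gt(6, seed = 3, duration = 900)
  norm <- normalize_dff(generate_photometry(gt, seed = 3)$trace)
  n_thr <- vapply(c(0.05, 0.07, 0.09), function(th)
    length(detect_transients(norm, threshold = th)$event_times), numeric(1))
  expect_true(all(diff(n_thr) <= 0))
  n_int <- vapply(c(0.5, 1, 2, 4), function(mi)
    length(detect_transients(norm, min_interval = mi)$event_times), numeric(1))
  expect_true(all(diff(n_int) <= 0))
})

test_that("artifact screen flags any local maximum above the cutoff", {
  expect_false(artifact_screen(as_norm(numeric(1000))))
  expect_true(artifact_screen(peak_trace(30, 0.06)))
  expect_false(artifact_screen(peak_trace(30, 0.04)))
  both <- artifact_screen(list(peak_trace(30, 0.06), peak_trace(30, 0.02)))
  expect_identical(as.vector(both), c(TRUE, FALSE))
})

test_that("event binning uses half-open bins and events/min units", {
  zero <- bin_event_rate(numeric(0), extent = c(0, 600))
  expect_equal(zero$values, rep(0, 10))

  # event exactly on an edge goes to the later bin
  ev <- bin_event_rate(c(59.999, 60), extent = c(0, 180))
  expect_equal(ev$values, c(1, 1, 0))

  # 30 s bins: counts scale to events/min
  halfbin <- bin_event_rate(c(10, 20), bin = 30, extent = c(0, 60))
  expect_equal(halfbin$values, c(4, 0))

  expect_error(bin_event_rate(c(1, 2), bin = -60, extent = c(0, 600)),
               class = "optophys_invalid_parameter")
})

test_that("percent-of-pre normalization and window summaries", {
  flat <- bs_of(rep(4, 60))
  expect_equal(percent_of_pre(flat)$values, rep(100, 60))

  stepped <- bs_of(c(rep(2, 30), rep(4, 30)))
  expect_equal(percent_of_pre(stepped)$values,
               c(rep(100, 30), rep(200, 30)))
  expect_equal(unname(summarize_windows(stepped)), c(2, 4))
  expect_equal(unname(summarize_windows(bs_of(rep(7, 60)))), c(7, 7))
  # unequal window lengths are means, not sums
  expect_equal(unname(summarize_windows(stepped, pre_window = 1:10,
                                        post_window = 31:60)),
               c(2, 4))

  expect_error(percent_of_pre(bs_of(c(rep(0, 30), rep(1, 30)))),
               class = "optophys_normalization_undefined")
  expect_error(summarize_windows(bs_of(rep(1, 10))),
               class = "optophys_range_error")
})

test_that("transient_rate inverts the dead-time thinning", {
  ev <- structure(list(event_times = seq(2.5, 597.5, by = 5),
                       event_amplitudes = rep(0.1, 120),
                       threshold = 0.05, min_interval = 0),
                  class = "transient_set")
  expect_equal(transient_rate(ev, c(0, 600)), 12)
  ev$min_interval <- 1
  # corrected rate inverts r = (1 - exp(-2*d*lambda)) / (2*d) exactly
  r <- 0.2
  expect_equal(transient_rate(ev, c(0, 600)), 60 * -log(1 - 2 * r) / 2)
  expect_gt(transient_rate(ev, c(0, 600)), 12)
  expect_equal(transient_rate(ev, c(0, 600), correct = FALSE), 12)
})
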