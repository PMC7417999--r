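make_trials <- function(amp_pre = 100, amp_post = 100, sd = 0,
                        duration = 3600, manip = 1800, seed = 1,
                        alpha = 1) {
  sched <- build_test_pulses(duration)
  gt <- evoked_gt(amp_pre = amp_pre, amp_post = amp_post,
                  background = c(alpha = alpha, sd = sd),
                  manipulation_time = manip)
  lfp <- generate_evoked_lfp(gt, sched, duration, seed = seed)
  suppressWarnings(extract_trials(lfp, sched, manip))
}

test_that("trial extraction covers pulses, drops edges, excludes blocks", {
  sched <- build_test_pulses(1800)
  lfp <- lfp_trace(rnorm(1800 * 1000), 1000)
  expect_warning(trials <- extract_trials(lfp, sched, 900),
                 "incomplete")                      # pulse at t = 0
  expect_equal(nrow(trials$trials), 359)
  expect_equal(ncol(trials$trials), 201)
  expect_equal(sum(trials$phase == "Pre"), 179)

  # pulses inside a protocol block are excluded
  sched_blk <- stim_schedule(sched$onsets, sched$pulse_width, "mixed",
                             block_boundaries = list(c(600, 900)))
  tr2 <- suppressWarnings(extract_trials(lfp, sched_blk, 900))
  expect_false(any(tr2$onset_times >= 600 & tr2$onset_times < 900))
  expect_equal(nrow(tr2$trials), 359 - 60)

  # extra exclusion windows behave the same
  tr3 <- suppressWarnings(extract_trials(lfp, sched, 900,
                                         exclude = list(c(600, 900))))
  expect_equal(tr3$onset_times, tr2$onset_times)
})

test_that("peak_to_peak basics and invariances", {
  t <- seq(0, 1, length.out = 1000)
  expect_equal(peak_to_peak(3 * sin(2 * pi * t)), 6, tolerance = 1e-4)
  expect_equal(peak_to_peak(rep(2.5, 10)), 0)
  expect_equal(peak_to_peak(seq(-3, 7, length.out = 50)), 10)
  x <- rnorm(200)
  expect_equal(peak_to_peak(x + 100), peak_to_peak(x))
  expect_equal(peak_to_peak(2.5 * x), 2.5 * peak_to_peak(x))
  expect_error(peak_to_peak(numeric(0)), class = "optophys_invalid_input")
})

test_that("wire responsiveness detects evoked deflections", {
  clean <- make_trials(amp_pre = 50, amp_post = 50, sd = 0, duration = 600,
                       manip = 300)
  expect_true(wire_is_responsive(clean))

  # pure noise: no systematic post > pre difference
  sched <- build_test_pulses(600)
  null_lfp <- generate_evoked_lfp(
    evoked_gt(amp_pre = 0, amp_post = 0, background = c(alpha = 1, sd = 10),
              manipulation_time = 300), sched, 600, seed = 3)
  null_tr <- suppressWarnings(extract_trials(null_lfp, sched, 300))
  expect_type(wire_is_responsive(null_tr), "logical")

  one_trial <- suppressWarnings(
    extract_trials(lfp_trace(rnorm(12000), 1000),
                   stim_schedule(c(5), 0.015), 10))
  expect_error(wire_is_responsive(one_trial),
               class = "optophys_insufficient_data")
})

test_that("null wires are flagged responsive at about the one-sided rate", {
  sched <- build_test_pulses(300)
  hits <- vapply(1:120, function(k) {
    lfp <- generate_evoked_lfp(
      evoked_gt(amp_pre = 0, amp_post = 0,
                background = c(alpha = 0, sd = 10),
                manipulation_time = 150), sched, 300, seed = 5000 + k)
    wire_is_responsive(suppressWarnings(extract_trials(lfp, sched, 150)))
  }, logical(1))
  # expected 2.5% (two-sided alpha, one-sided direction requirement)
  expect_lt(mean(hits), 0.025 + 3 * sqrt(0.025 * 0.975 / 120))
})

test_that("amplitude time-course normalizes to the Pre mean", {
  clean <- make_trials(amp_pre = 60, amp_post = 60, sd = 0, duration = 1200,
                       manip = 600)
  tc <- amplitude_timecourse(clean)
  expect_equal(tc$values[!is.na(tc$values)],
               rep(100, sum(!is.na(tc$values))), tolerance = 1e-9)

  up <- make_trials(amp_pre = 100, amp_post = 140, sd = 10, seed = 11)
  tc2 <- amplitude_timecourse(up, average_within_bin = TRUE)
  post <- mean(tc2$values[41:60])
  expect_equal(post, 140, tolerance = 14)

  down <- make_trials(amp_pre = 100, amp_post = 50, sd = 10, seed = 12)
  tc3 <- amplitude_timecourse(down, average_within_bin = TRUE)
  expect_equal(mean(tc3$values[41:60]), 50, tolerance = 5)
})

test_that("classify_lfp applies the shared classification contract", {
  flat <- make_trials(amp_pre = 100, amp_post = 100, sd = 0)
  expect_identical(classify_lfp(flat)$label, "non-modulated")

  up <- make_trials(amp_pre = 100, amp_post = 150, sd = 10, seed = 13)
  cl <- classify_lfp(up, n_comparisons = 8)
  expect_identical(cl$label, "potentiated")

  down <- make_trials(amp_pre = 100, amp_post = 50, sd = 10, seed = 14)
  expect_identical(classify_lfp(down, n_comparisons = 8)$label, "depressed")
})

test_that("evoked firing ON/OFF analysis and classification", {
  sched <- build_test_pulses(600)
  silent <- spike_train(numeric(0), c(0, 600))
  expect_identical(evoked_firing(silent, sched)$call, "not-modulated")

  gt <- unit_gt(4, 1, injection_time = 600,
                evoked_bump = list(latency = 0, width = 0.015,
                                   added_rate = 40))
  trn <- generate_spike_train(gt, 600, seed = 15, schedule = sched)
  ef <- evoked_firing(trn, sched)
  expect_identical(ef$call, "activated")
  expect_equal(nrow(ef$rates), length(sched$onsets))
})

test_that("evoked firing time-course recovers a post gain", {
  sched <- build_test_pulses(3600)
  gt <- unit_gt(4, 1, injection_time = 1800,
                evoked_bump = list(latency = 0, width = 0.015,
                                   added_rate = 60, post_gain = 2))
  trn <- generate_spike_train(gt, 3600, seed = 16, schedule = sched)
  res <- evoked_firing_timecourse(trn, sched, 1800, n_comparisons = 5)
  expect_identical(res$call$label, "potentiated")
  # ON-rate: baseline 4 Hz + 60 Hz * 15/25 = 40 pre, 76 post => ~190%
  expect_equal(res$call$percent_change, 190, tolerance = 20)

  gt0 <- unit_gt(4, 1, injection_time = 1800,
                 evoked_bump = list(latency = 0, width = 0.015,
                                    added_rate = 60))
  trn0 <- generate_spike_train(gt0, 3600, seed = 17, schedule = sched)
  res0 <- evoked_firing_timecourse(trn0, sched, 1800, n_comparisons = 5)
  expect_identical(res0$call$label, "non-modulated")
  expect_equal(mean(res0$timecourse$values, na.rm = TRUE), 100,
               tolerance = 10)
})
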