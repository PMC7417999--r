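test_that("photometry generator: identity case, determinism, errors", {
  flat <- photometry_gt(bleach = c(level = 50, frac_fast = 0, tau_fast = 1,
                                   tau_slow = 1e12),
                        noise_sd = 0, duration = 30)
  tr <- generate_photometry(flat, seed = 7)$trace
  expect_equal(tr$samples, rep(50, 3000), tolerance = 1e-9)

  gt <- random_photometry_gt(3, seed = 11, duration = 120)
  a <- generate_photometry(gt, seed = 5)$trace
  b <- generate_photometry(gt, seed = 5)$trace
  expect_identical(a$samples, b$samples)

  expect_error(photometry_gt(sampling_rate = -1),
               class = "optophys_invalid_parameter")
  expect_error(photometry_gt(duration = 0),
               class = "optophys_invalid_parameter")
  expect_error(photometry_gt(transient_times = c(5, 1),
                             transient_amplitudes = c(0.1, 0.1)),
               class = "optophys_invalid_parameter")
})

test_that("a 10% transient on a constant baseline yields ~10% dF/F", {
  gt <- photometry_gt(transient_times = 300, transient_amplitudes = 0.10,
                      bleach = c(level = 100, frac_fast = 0, tau_fast = 1,
                                 tau_slow = 1e12),
                      noise_sd = 0, duration = 600)
  tr <- generate_photometry(gt, seed = 1)$trace
  got <- max(normalize_dff(tr)$samples)
  # oracle: brute-force windowed mean on the same generated array
  expected <- max(oracle_dff(tr$samples, tr$sampling_rate))
  expect_equal(got, expected, tolerance = 1e-10)
  # the transient inflates its own baseline window slightly, so the peak
  # sits just below the nominal 10%
  expect_gt(got, 0.09)
  expect_lt(got, 0.101)
})

test_that("spike generator matches Poisson counting statistics", {
  expect_length(generate_spike_train(unit_gt(0), 100, seed = 1)$spike_times, 0)

  trn <- generate_spike_train(unit_gt(5, 1), 3600, seed = 2)
  rate <- length(trn$spike_times) / 3600
  expect_lt(abs(rate - 5), 3 * sqrt(5 / 3600))

  trn2 <- generate_spike_train(unit_gt(5, 2, injection_time = 1800), 3600,
                               seed = 3)
  pre <- sum(trn2$spike_times < 1800) / 1800
  post <- sum(trn2$spike_times >= 1800) / 1800
  expect_lt(abs(post / pre - 2), 3 * sqrt(5 / 1800 + 10 / 1800) / 5 * 2)

  expect_error(unit_gt(-1), class = "optophys_invalid_parameter")
  expect_error(generate_spike_train(unit_gt(5), 0),
               class = "optophys_invalid_parameter")
  expect_identical(generate_spike_train(unit_gt(5), 600, seed = 9)$spike_times,
                   generate_spike_train(unit_gt(5), 600, seed = 9)$spike_times)
})

test_that("spike generator adds the evoked bump after pulse onsets", {
  sched <- build_test_pulses(600)
  gt <- unit_gt(2, 1, injection_time = 600,
                evoked_bump = list(latency = 0.005, width = 0.015,
                                   added_rate = 60))
  trn <- generate_spike_train(gt, 600, seed = 4, schedule = sched)
  ef <- evoked_firing(trn, sched)
  # expected on-window extra: 60 Hz * 15 ms over a 25 ms window = 36 Hz
  expect_gt(mean(ef$rates$on_rate) - mean(ef$rates$off_rate), 20)
  expect_identical(ef$call, "activated")
})

test_that("evoked LFP generator is exact in the noise-free case", {
  sched <- build_test_pulses(120)
  gt <- evoked_gt(amp_pre = 80, amp_post = 80,
                  background = c(alpha = 1, sd = 0), manipulation_time = 60)
  lfp <- generate_evoked_lfp(gt, sched, 120, seed = 1)
  trials <- suppressWarnings(extract_trials(lfp, sched, 60))
  amps <- amplitude_series(trials)$amplitude
  expect_equal(amps, rep(80, length(amps)), tolerance = 1e-9)

  gt2 <- evoked_gt(amp_pre = 80, amp_post = 120,
                   background = c(alpha = 1, sd = 0), manipulation_time = 60)
  lfp2 <- generate_evoked_lfp(gt2, sched, 120, seed = 1)
  t2 <- suppressWarnings(extract_trials(lfp2, sched, 60))
  expect_equal(evoked_amplitude_ratio(t2), 1.5, tolerance = 1e-9)

  long_kernel <- rep(0.5, 90)  # 90 ms at 1 kHz
  hfs_like <- stim_schedule(seq(0, 1, by = 1 / 60), 0.015)
  expect_error(generate_evoked_lfp(evoked_gt(kernel = long_kernel),
                                   hfs_like, 10),
               class = "optophys_invalid_parameter")
  expect_error(evoked_gt(kernel = numeric(150)),
               class = "optophys_invalid_parameter")
})

test_that("noisy evoked ratio is recovered by trial averaging", {
  sched <- build_test_pulses(720)
  gt <- evoked_gt(amp_pre = 100, amp_post = 150,
                  background = c(alpha = 1, sd = 10),
                  manipulation_time = 360)
  lfp <- generate_evoked_lfp(gt, sched, 720, seed = 6)
  trials <- suppressWarnings(extract_trials(lfp, sched, 360))
  expect_equal(evoked_amplitude_ratio(trials), 1.5, tolerance = 0.1)
})

test_that("default eYFP-mode traces stay below the 5% artifact cutoff", {
  exceeds <- vapply(1:8, function(k) {
    gt <- random_photometry_gt(0, seed = 2000 + k, duration = 3600,
                               eyfp = TRUE)
    norm <- normalize_dff(generate_photometry(gt, seed = 2000 + k)$trace)
    artifact_screen(norm)
  }, logical(1))
  expect_gte(sum(!exceeds), 7)
})

test_that("track generator: stationary, straight, arena and determinism", {
  still <- generate_track(track_gt(0, 0), 60, seed = 1)
  expect_true(all(instant_velocity(still)$values == 0))

  st <- straight_track(2, 10)
  expect_equal(instant_velocity(st)$values, rep(2, 10), tolerance = 1e-9)

  gt <- track_gt(3, 9, arena = c(30, 30), change_time = 150)
  trk <- generate_track(gt, 300, seed = 8)
  expect_true(all(trk$x >= 0 & trk$x <= 30 & trk$y >= 0 & trk$y <= 30))
  trk2 <- generate_track(gt, 300, seed = 8)
  expect_identical(trk$x, trk2$x)

  expect_error(track_gt(1, arena = c(-5, 10)),
               class = "optophys_invalid_parameter")
})

test_that("track speed ratio is recovered from binned velocity", {
  gt <- track_gt(2, 6, arena = c(100, 100), change_time = 600)
  trk <- generate_track(gt, 1200, seed = 10)
  tc <- velocity_timecourse(trk, bin = 60, n_pre_bins = 10)
  post <- mean(tc$values[11:20])
  expect_equal(post, 300, tolerance = 0.1 * 300)
})
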