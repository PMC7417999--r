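#' Ground-truth descriptions for synthetic sessions
#'
#' Each `*_gt()` constructor describes one synthetic signal with the
#' parameters a downstream recovery test needs to verify: transient times and
#' amplitudes for photometry, the firing-rate step for units, pre/post evoked
#' amplitudes for LFP, and pre/post running speed for tracking. Generators
#' (`generate_*`) consume a ground truth plus a seed and are bit-reproducible
#' for identical inputs.
#'
#' The photometry signal model is multiplicative:
#' `trace(t) = bleach(t) * (1 + transients(t) + artifacts(t) + noise(t))`,
#' where `bleach` is a double-exponential photobleaching decay, each
#' transient is an instantaneous rise followed by a single-exponential decay
#' (tau 1.5 s, slow-indicator-like), artifacts are brief sharp spikes used in
#' fluorophore-only (eYFP) control mode, and `noise` is white with standard
#' deviation `noise_sd` expressed as a fraction of the instantaneous bleach
#' level (photon noise scales with collected light, so the dF/F noise floor
#' stays constant as the session bleaches).
#'
#' @param transient_times transient onset times, seconds, strictly increasing.
#' @param transient_amplitudes per-transient peak amplitude as a dF/F
#'   fraction (0.10 = 10%).
#' @param bleach named vector `c(level, frac_fast, tau_fast, tau_slow)`:
#'   initial level (a.u.), fraction of the level that decays with the fast
#'   time constant, and the two decay constants (s). The level stays strictly
#'   positive for all t.
#' @param noise_sd white-noise SD as a fraction of the bleach level.
#' @param artifact_times,artifact_amplitudes motion-artifact spike onsets (s)
#'   and amplitudes (dF/F fraction); empty by default.
#' @param sampling_rate photometry digitization rate, Hz (default 100).
#' @param duration session length, seconds.
#' @param transient_tau,artifact_tau exponential decay constants, seconds.
#' @return A `photometry_gt` object.
#' @export
photometry_gt <- function(transient_times = numeric(0),
                          transient_amplitudes = numeric(0),
                          bleach = c(level = 100, frac_fast = 0.15,
                                     tau_fast = 180, tau_slow = 10000),
                          noise_sd = 0.01,
                          artifact_times = numeric(0),
                          artifact_amplitudes = numeric(0),
                          sampling_rate = 100, duration = 3600,
                          transient_tau = 1.5, artifact_tau = 0.3) {
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(transient_tau, "transient_tau", positive = TRUE)
  if (length(transient_times) != length(transient_amplitudes))
    op_stop("transient times/amplitudes length mismatch", "optophys_invalid_parameter")
  if (length(artifact_times) != length(artifact_amplitudes))
    op_stop("artifact times/amplitudes length mismatch", "optophys_invalid_parameter")
  if (length(transient_times) &&
      (is.unsorted(transient_times, strictly = TRUE) ||
       min(transient_times) < 0 || max(transient_times) > duration))
    op_stop("transient_times must be strictly increasing within [0, duration]",
            "optophys_invalid_parameter")
  b <- as.list(bleach)
  if (b$level <= 0 || b$frac_fast < 0 || b$frac_fast > 1 ||
      b$tau_fast <= 0 || b$tau_slow <= 0)
    op_stop("invalid bleach parameters", "optophys_invalid_parameter")
  structure(list(transient_times = as.numeric(transient_times),
                 transient_amplitudes = as.numeric(transient_amplitudes),
                 bleach = bleach, noise_sd = noise_sd,
                 artifact_times = as.numeric(artifact_times),
                 artifact_amplitudes = as.numeric(artifact_amplitudes),
                 sampling_rate = sampling_rate, duration = duration,
                 transient_tau = transient_tau, artifact_tau = artifact_tau),
            class = "photometry_gt")
}

#' Draw a random photometry ground truth
#'
#' Convenience factory for recovery tests: transient onsets are homogeneous
#' Poisson at `rate_per_min`, all with the same amplitude. In eYFP control
#' mode no transients are generated; instead a small number of brief motion
#' artifacts (Poisson, `artifact_rate_per_hr`) with log-normal amplitudes
#' around 2% dF/F emulate a fluorophore-only recording.
#'
#' @param rate_per_min mean transient rate, events/min.
#' @param amplitude transient amplitude, dF/F fraction.
#' @param duration session length, s.
#' @param seed integer seed for the onset draw.
#' @param eyfp logical; fluorophore-only control mode.
#' @param artifact_rate_per_hr mean artifact count per hour in eYFP mode.
#' @param ... further arguments passed to [photometry_gt()].
#' @return A `photometry_gt`.
#' @export
random_photometry_gt <- function(rate_per_min, amplitude = 0.10,
                                 duration = 3600, seed = 1, eyfp = FALSE,
                                 artifact_rate_per_hr = 10, ...) {
  check_scalar(rate_per_min, "rate_per_min", nonneg = TRUE)
  set.seed(seed)
  if (eyfp) {
    n_art <- rpois(1, artifact_rate_per_hr * duration / 3600)
    at <- sort(runif(n_art, 0, duration))
    # small artifacts (~1.5% dF/F median): near the trace start the clipped
    # baseline window over the fast bleach phase biases dF/F upward by up
    # to ~2.5%, and artifacts riding that edge must still stay below the 5%
    # screen for default parameters
    aa <- rlnorm(n_art, log(0.015), 0.25)
    photometry_gt(artifact_times = at, artifact_amplitudes = aa,
                  noise_sd = 0.005, duration = duration, ...)
  } else {
    n_tr <- rpois(1, rate_per_min / 60 * duration)
    tt <- sort(runif(n_tr, 0, duration))
    tt <- tt[c(TRUE, diff(tt) > 0)]          # degenerate ties are measure-zero
    photometry_gt(transient_times = tt,
                  transient_amplitudes = rep(amplitude, length(tt)),
                  duration = duration, ...)
  }
}

# internal: sum of exponential-decay kernels at given onsets/amplitudes
decay_kernel_sum <- function(n, fs, onsets, amplitudes, tau) {
  s <- numeric(n)
  if (!length(onsets)) return(s)
  klen <- ceiling(10 * tau * fs)
  tgrid <- (0:(n - 1)) / fs
  for (j in seq_along(onsets)) {
    i0 <- floor(onsets[j] * fs) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + klen)
    s[idx] <- s[idx] + amplitudes[j] * exp(-(tgrid[idx] - onsets[j]) / tau)
  }
  s
}

#' Generate a synthetic photometry trace
#'
#' @param gt a [photometry_gt()].
#' @param seed integer seed; identical `(gt, seed)` give identical traces.
#' @return A list with elements `trace` (a [raw_trace()]) and `gt`.
#' @export
generate_photometry <- function(gt, seed = 1) {
  stopifnot(inherits(gt, "photometry_gt"))
  set.seed(seed)
  fs <- gt$sampling_rate
  n <- round(gt$duration * fs)
  t <- (0:(n - 1)) / fs
  b <- as.list(gt$bleach)
  bleach <- b$level * (b$frac_fast * exp(-t / b$tau_fast) +
                       (1 - b$frac_fast) * exp(-t / b$tau_slow))
  s <- decay_kernel_sum(n, fs, gt$transient_times, gt$transient_amplitudes,
                        gt$transient_tau) +
       decay_kernel_sum(n, fs, gt$artifact_times, gt$artifact_amplitudes,
                        gt$artifact_tau)
  noise <- if (gt$noise_sd > 0) rnorm(n, 0, gt$noise_sd) else numeric(n)
  list(trace = raw_trace(bleach * (1 + s + noise), fs), gt = gt)
}

#' Unit firing-rate ground truth
#'
#' Describes a rate-stepped Poisson unit: `base_rate` Hz before
#' `injection_time`, `base_rate * post_multiplier` after. An optional evoked
#' bump adds `added_rate` Hz during `[latency, latency + width)` after each
#' pulse of a supplied schedule; `post_gain` scales the bump's added rate
#' after the injection (evoked-response plasticity).
#'
#' @param base_rate baseline firing rate, Hz (>= 0).
#' @param post_multiplier rate multiplier after injection (> 0).
#' @param injection_time manipulation time, s.
#' @param evoked_bump `NULL` or named vector/list
#'   `c(latency, width, added_rate)` (s, s, Hz), optionally with `post_gain`.
#' @return A `unit_gt` object.
#' @export
unit_gt <- function(base_rate, post_multiplier = 1, injection_time = 1800,
                    evoked_bump = NULL) {
  check_scalar(base_rate, "base_rate", nonneg = TRUE)
  check_scalar(post_multiplier, "post_multiplier", positive = TRUE)
  check_scalar(injection_time, "injection_time", nonneg = TRUE)
  if (!is.null(evoked_bump)) {
    eb <- as.list(evoked_bump)
    if (is.null(eb$post_gain)) eb$post_gain <- 1
    if (eb$latency < 0 || eb$width <= 0 || eb$added_rate < 0 || eb$post_gain < 0)
      op_stop("invalid evoked_bump parameters", "optophys_invalid_parameter")
    evoked_bump <- eb
  }
  structure(list(base_rate = base_rate, post_multiplier = post_multiplier,
                 injection_time = injection_time, evoked_bump = evoked_bump),
            class = "unit_gt")
}

#' Generate a rate-modulated Poisson spike train
#'
#' Inhomogeneous Poisson sampling of the [unit_gt()] rate profile. Baseline
#' spikes are drawn per rate segment; evoked-bump spikes (if a schedule is
#' supplied) are superposed as an independent Poisson component after each
#' pulse onset.
#'
#' @param gt a [unit_gt()].
#' @param duration session length, s (> 0).
#' @param seed integer seed.
#' @param schedule optional [stim_schedule()] driving the evoked bump.
#' @return A [spike_train()].
#' @export
generate_spike_train <- function(gt, duration, seed = 1, schedule = NULL) {
  stopifnot(inherits(gt, "unit_gt"))
  check_scalar(duration, "duration", positive = TRUE)
  set.seed(seed)
  segs <- rbind(c(0, min(gt$injection_time, duration), gt$base_rate),
                c(min(gt$injection_time, duration), duration,
                  gt$base_rate * gt$post_multiplier))
  spikes <- numeric(0)
  for (k in seq_len(nrow(segs))) {
    len <- segs[k, 2] - segs[k, 1]
    if (len <= 0 || segs[k, 3] <= 0) next
    m <- rpois(1, segs[k, 3] * len)
    spikes <- c(spikes, runif(m, segs[k, 1], segs[k, 2]))
  }
  if (!is.null(gt$evoked_bump) && !is.null(schedule)) {
    eb <- gt$evoked_bump
    for (on in schedule$onsets) {
      lo <- on + eb$latency
      if (lo >= duration) next
      gain <- if (on >= gt$injection_time) eb$post_gain else 1
      m <- rpois(1, eb$added_rate * gain * eb$width)
      if (m) spikes <- c(spikes, runif(m, lo, min(lo + eb$width, duration)))
    }
  }
  spike_train(sort(spikes), extent = c(0, duration))
}

#' Evoked-LFP ground truth and default response kernel
#'
#' `evoked_gt()` describes a stimulus-locked LFP deflection whose amplitude
#' changes at a manipulation time: each pulse adds `kernel` scaled so its
#' peak-to-peak amplitude equals `amp_pre` (pulses before
#' `manipulation_time`) or `amp_post` (after), on top of 1/f^alpha-shaped
#' Gaussian background noise.
#'
#' `default_evoked_kernel()` returns a biphasic damped-sine waveform
#' (negative-then-positive deflection, support `duration` seconds, <= 100 ms)
#' normalized to unit peak-to-peak amplitude.
#'
#' @param kernel numeric waveform sampled at `sampling_rate`; support must be
#'   at most 100 ms.
#' @param amp_pre,amp_post peak-to-peak response amplitude (µV) before/after
#'   the manipulation (>= 0).
#' @param background `c(alpha, sd)`: spectral exponent of the 1/f^alpha
#'   background and its SD in µV.
#' @param manipulation_time s.
#' @param sampling_rate Hz (default 1000).
#' @param duration kernel support, s.
#' @param f0 oscillation frequency of the damped sine, Hz.
#' @param tau damping constant, s.
#' @return `evoked_gt()`: an `evoked_gt` object; `default_evoked_kernel()`:
#'   a numeric vector.
#' @export
evoked_gt <- function(kernel = default_evoked_kernel(),
                      amp_pre = 100, amp_post = 100,
                      background = c(alpha = 1, sd = 10),
                      manipulation_time = 1800, sampling_rate = 1000) {
  check_scalar(amp_pre, "amp_pre", nonneg = TRUE)
  check_scalar(amp_post, "amp_post", nonneg = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (length(kernel) / sampling_rate > 0.1 + 1e-9)
    op_stop("kernel support exceeds 100 ms", "optophys_invalid_parameter")
  bg <- as.list(background)
  if (bg$sd < 0) op_stop("background sd must be >= 0", "optophys_invalid_parameter")
  structure(list(kernel = as.numeric(kernel), amp_pre = amp_pre,
                 amp_post = amp_post, background = background,
                 manipulation_time = manipulation_time,
                 sampling_rate = sampling_rate),
            class = "evoked_gt")
}

#' @rdname evoked_gt
#' @export
default_evoked_kernel <- function(sampling_rate = 1000, duration = 0.08,
                                  f0 = 25, tau = 0.03) {
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  k <- -sin(2 * pi * f0 * t) * exp(-t / tau)
  k / (max(k) - min(k))
}

# internal: Gaussian noise with 1/f^alpha spectral shaping, sd rescaled
pink_noise <- function(n, sd, alpha) {
  if (sd <= 0) return(numeric(n))
  w <- rnorm(n)
  if (alpha == 0) return(sd * w)
  f <- c(1, seq_len(n - 1))                    # avoid DC blow-up
  f <- pmin(f, n - f + 1)                      # symmetric (two-sided) grid
  shape <- 1 / f^(alpha / 2)
  shape[1] <- 0                                # zero-mean background
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  sd * x / sd(x)
}

#' Generate a synthetic evoked-LFP trace
#'
#' @param gt an [evoked_gt()].
#' @param schedule a [stim_schedule()] of pulse onsets (absolute seconds).
#' @param duration trace length, s; must cover the schedule.
#' @param seed integer seed.
#' @return An [lfp_trace()] (µV, `gt$sampling_rate`).
#' @export
generate_evoked_lfp <- function(gt, schedule, duration, seed = 1) {
  stopifnot(inherits(gt, "evoked_gt"), inherits(schedule, "stim_schedule"))
  check_scalar(duration, "duration", positive = TRUE)
  fs <- gt$sampling_rate
  klen <- length(gt$kernel)
  if (length(schedule$onsets) > 1L &&
      klen / fs > min(diff(schedule$onsets)) + 1e-12)
    op_stop("kernel longer than the inter-pulse interval",
            "optophys_invalid_parameter")
  if (max(schedule$onsets) + klen / fs > duration)
    op_stop("schedule extends beyond the trace duration",
            "optophys_invalid_parameter")
  set.seed(seed)
  n <- round(duration * fs)
  bg <- as.list(gt$background)
  x <- pink_noise(n, bg$sd, bg$alpha)
  ptp_k <- max(gt$kernel) - min(gt$kernel)
  for (on in schedule$onsets) {
    amp <- if (on < gt$manipulation_time) gt$amp_pre else gt$amp_post
    if (amp == 0 || ptp_k == 0) next
    i0 <- round(on * fs) + 1L
    idx <- i0:min(n, i0 + klen - 1L)
    x[idx] <- x[idx] + (amp / ptp_k) * gt$kernel[seq_along(idx)]
  }
  lfp_trace(x, fs)
}

#' Locomotion ground truth and track generator
#'
#' `track_gt()` describes a reflected random walk in a rectangular arena:
#' heading diffuses (Gaussian increments), per-step speed is Gamma-
#' distributed with mean `speed_pre` before `change_time` and `speed_post`
#' after (coefficient of variation `speed_cv`), and positions reflect off the
#' arena walls. `generate_track()` samples it; `mode = "straight"` produces a
#' deterministic constant-heading, constant-speed track for exact checks.
#'
#' @param speed_pre,speed_post mean running speed, cm/s (>= 0).
#' @param arena `c(width, height)` in cm (> 0); default 30 x 30 cm open field.
#' @param sampling_rate tracking rate, Hz (default 25).
#' @param change_time time of the speed change, s.
#' @param speed_cv per-step speed coefficient of variation.
#' @return A `track_gt` object.
#' @export
track_gt <- function(speed_pre, speed_post = speed_pre,
                     arena = c(width = 30, height = 30),
                     sampling_rate = 25, change_time = 1800,
                     speed_cv = 0.2) {
  check_scalar(speed_pre, "speed_pre", nonneg = TRUE)
  check_scalar(speed_post, "speed_post", nonneg = TRUE)
  if (any(arena <= 0))
    op_stop("arena dimensions must be > 0", "optophys_invalid_parameter")
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  structure(list(speed_pre = speed_pre, speed_post = speed_post,
                 arena = arena, sampling_rate = sampling_rate,
                 change_time = change_time, speed_cv = speed_cv),
            class = "track_gt")
}

# internal: fold a coordinate into [0, w] by specular reflection
reflect_into <- function(p, w) {
  p <- p %% (2 * w)
  ifelse(p > w, 2 * w - p, p)
}

#' @rdname track_gt
#' @param gt a `track_gt`.
#' @param duration track length, s (> 0).
#' @param seed integer seed.
#' @param mode `"random"` (reflected random walk) or `"straight"`.
#' @param start optional `c(x, y)` start position, cm; default arena center.
#' @param heading initial heading, radians.
#' @export
generate_track <- function(gt, duration, seed = 1,
                           mode = c("random", "straight"),
                           start = NULL, heading = 0) {
  stopifnot(inherits(gt, "track_gt"))
  check_scalar(duration, "duration", positive = TRUE)
  mode <- match.arg(mode)
  set.seed(seed)
  fs <- gt$sampling_rate
  n <- round(duration * fs) + 1L
  times <- (0:(n - 1)) / fs
  w <- as.numeric(gt$arena[1]); h <- as.numeric(gt$arena[2])
  if (is.null(start)) start <- c(w / 2, h / 2)
  target <- ifelse(times[-n] < gt$change_time, gt$speed_pre, gt$speed_post)
  if (mode == "straight") {
    speeds <- target
    headings <- rep(heading, n - 1L)
  } else {
    shape <- 1 / gt$speed_cv^2
    speeds <- ifelse(target > 0,
                     target * rgamma(n - 1L, shape = shape, rate = shape), 0)
    headings <- heading + cumsum(rnorm(n - 1L, 0, 0.5))
  }
  dx <- speeds / fs * cos(headings)
  dy <- speeds / fs * sin(headings)
  x <- reflect_into(start[1] + cumsum(c(0, dx)), w)
  y <- reflect_into(start[2] + cumsum(c(0, dy)), h)
  track(times, x, y, fs)
}
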