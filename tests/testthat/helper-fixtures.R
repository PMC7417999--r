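# Fixture builders shared across test files. All fixtures are built in code;
# oracles are deliberately naive re-implementations (loops, direct sums) kept
# independent of the package internals they check.

# brute-force dF/F oracle: windowed mean by explicit loop
oracle_dff <- function(x, fs, window = 120) {
  n <- length(x)
  h <- round(window / 2 * fs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - h):min(n, i + h)]
    out[i] <- (x[i] - mean(w)) / mean(w)
  }
  out
}

# a constant-baseline raw trace with one rectangular bump
bump_trace <- function(baseline = 100, bump = 110, duration = 600,
                       bump_at = 300, bump_len = 2, fs = 10) {
  x <- rep(baseline, duration * fs)
  i0 <- bump_at * fs + 1
  x[i0:(i0 + bump_len * fs - 1)] <- bump
  raw_trace(x, fs)
}

# dF/F-like normalized trace straight from samples (bypasses normalization)
as_norm <- function(samples, fs = 100) {
  structure(list(samples = samples, sampling_rate = fs, start_time = 0,
                 window_length = 120),
            class = c("normalized_trace"))
}

# a trace of isolated triangular peaks at given times/heights (dF/F units)
peak_trace <- function(times, heights, duration = 60, fs = 100) {
  x <- numeric(duration * fs)
  for (k in seq_along(times)) {
    i <- round(times[k] * fs) + 1
    x[i] <- heights[k]
    x[i - 1] <- heights[k] / 2
    x[i + 1] <- heights[k] / 2
  }
  as_norm(x, fs)
}

# spike train with exactly regular firing
regular_train <- function(rate_hz, duration, extent = c(0, duration)) {
  spike_train(seq(1 / (2 * rate_hz), duration, by = 1 / rate_hz), extent)
}

# binned series from values with unit-width bins
bs_of <- function(values, bin = 60) {
  binned_series(seq(0, by = bin, length.out = length(values) + 1), values)
}

# deterministic straight track: constant speed v along +x, start near wall
straight_track <- function(v, duration, fs = 25, arena = 1e6) {
  gt <- track_gt(v, v, arena = c(arena, arena), sampling_rate = fs,
                 change_time = duration)
  generate_track(gt, duration, seed = 1, mode = "straight",
                 start = c(1, arena / 2), heading = 0)
}
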