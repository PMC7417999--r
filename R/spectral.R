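#' Bartlett-tapered power spectrum of an LFP trace
#'
#' Welch-style averaged periodogram with a Bartlett (triangular) taper per
#' segment and 50% segment overlap. The segment length is derived from the
#' required frequency grid: `n_freq` values spanning 0 to `f_max` Hz imply a
#' spacing of `f_max / (n_freq - 1)` (~0.1956 Hz for the default 512 values
#' over 0-100 Hz), i.e. 5110-sample segments at 1 kHz. Power is restricted
#' to the 0-`f_max` range and renormalized to percent of total within it.
#'
#' @param lfp an [lfp_trace()].
#' @param n_freq number of frequency values on the reported grid (512).
#' @param f_max upper frequency bound, Hz (100).
#' @param overlap segment overlap: a fraction if < 1 (default 0.5), a sample
#'   count if >= 1.
#' @return A `power_spectrum`: `frequencies` (Hz), `power` (percent of total
#'   over 0-`f_max`; sums to 100). Attributes `psd` and `df` hold the
#'   unnormalized one-sided spectral density (µV²/Hz over 0-Nyquist) and
#'   grid spacing for absolute-power checks.
#' @export
power_spectrum <- function(lfp, n_freq = 512, f_max = 100, overlap = 0.5) {
  stopifnot(inherits(lfp, "lfp_trace"))
  fs <- lfp$sampling_rate
  if (f_max > fs / 2)
    op_stop("f_max exceeds the Nyquist frequency", "optophys_invalid_parameter")
  nseg <- round((n_freq - 1) * fs / f_max)
  x <- lfp$samples
  if (length(x) < nseg)
    op_stop(sprintf("trace shorter than one %d-sample segment", nseg),
            "optophys_insufficient_data")
  step <- if (overlap < 1) max(1L, round(nseg * (1 - overlap)))
          else max(1L, nseg - round(overlap))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 1 - abs((seq_len(nseg) - 1) - (nseg - 1) / 2) / ((nseg - 1) / 2)
  norm <- fs * sum(w^2)
  nhalf <- floor(nseg / 2) + 1L
  acc <- numeric(nhalf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    X <- fft((seg - mean(seg)) * w)
    acc <- acc + (Mod(X[seq_len(nhalf)])^2) / norm
  }
  psd <- acc / length(starts)
  psd[-c(1L, if (nseg %% 2 == 0) nhalf)] <-
    2 * psd[-c(1L, if (nseg %% 2 == 0) nhalf)]   # one-sided
  df <- fs / nseg
  freqs <- (seq_len(nhalf) - 1) * df
  sel <- seq_len(n_freq)
  pct <- 100 * psd[sel] / sum(psd[sel])
  structure(list(frequencies = freqs[sel], power = pct),
            class = "power_spectrum",
            psd = psd, df = df, freq_full = freqs)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d values, %.4g-%.4g Hz (spacing %.4g Hz)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Frequency-band shares of a percent spectrum
#'
#' Aggregates a [power_spectrum()] into the five canonical bands: delta
#' (0-4 Hz), theta (4-10), beta (10-30), low-gamma (30-80) and high-gamma
#' (80-100). Bands are half-open `[lo, hi)` except high-gamma, which is
#' closed at 100 Hz, so the shares always sum to 100.
#'
#' @param spec a `power_spectrum`.
#' @return Named numeric vector of per-band percent of total.
#' @export
band_powers <- function(spec) {
  stopifnot(inherits(spec, "power_spectrum"))
  bands <- list(delta = c(0, 4), theta = c(4, 10), beta = c(10, 30),
                low_gamma = c(30, 80), high_gamma = c(80, 100))
  f <- spec$frequencies
  vapply(names(bands), function(b) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- if (b == "high_gamma") f >= lo & f <= hi else f >= lo & f < hi
    sum(spec$power[sel])
  }, numeric(1))
}

#' Average spectra within subjects, then across subjects
#'
#' Electrode-level spectra are first averaged within each subject, and the
#' per-subject means are then averaged within each group, so every subject
#' carries equal weight regardless of its electrode count.
#'
#' @param spectra list of [power_spectrum()] objects on identical grids.
#' @param subject character/factor of the same length: subject of each
#'   spectrum.
#' @param group optional grouping of the same length (e.g. treatment);
#'   a single group is assumed if omitted.
#' @return Named list of `power_spectrum` objects, one per group.
#' @export
average_by_group <- function(spectra, subject, group = NULL) {
  if (!length(spectra))
    op_stop("need at least one spectrum", "optophys_invalid_input")
  f0 <- spectra[[1]]$frequencies
  same <- vapply(spectra, function(s)
    length(s$frequencies) == length(f0) &&
      max(abs(s$frequencies - f0)) < 1e-9, logical(1))
  if (!all(same))
    op_stop("spectra are on mismatched frequency grids", "optophys_invalid_input")
  if (length(subject) != length(spectra))
    op_stop("one subject label per spectrum required", "optophys_invalid_input")
  if (is.null(group)) group <- rep("all", length(spectra))
  mat <- do.call(rbind, lapply(spectra, function(s) s$power))
  subj_means <- rowsum(mat, subject) / as.vector(table(subject)[sort(unique(subject))])
  subj_group <- vapply(sort(unique(subject)), function(s)
    as.character(group[match(s, subject)]), character(1))
  out <- lapply(unique(subj_group), function(g) {
    m <- colMeans(subj_means[subj_group == g, , drop = FALSE])
    structure(list(frequencies = f0, power = m), class = "power_spectrum")
  })
  names(out) <- unique(subj_group)
  out
}
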