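#' Read and write session signals as plain columnar text
#'
#' All signals serialize to simple CSV: traces as `time_s,value`, spike
#' trains and pulse onsets as one timestamp per row, tracks as
#' `time_s,x_cm,y_cm`. Schedules carry a JSON sidecar with the protocol name,
#' pulse width and block boundaries. Reading back a written object restores
#' it (within float formatting).
#'
#' @param trace,train,tr,schedule object to write.
#' @param path file path.
#' @param sampling_rate,start_time,extent,unit_id metadata needed to rebuild
#'   objects whose CSV does not embed them.
#' @return Readers return the rebuilt object; writers return `path`
#'   invisibly.
#' @name session_io
NULL

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' @rdname session_io
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = fmt_num(trace_times(trace)),
                   value = fmt_num(trace$samples))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_trace_csv <- function(path, sampling_rate = NULL, kind = c("raw", "lfp")) {
  kind <- match.arg(kind)
  df <- read.csv(path)
  if (is.null(sampling_rate)) {
    dt <- diff(df$time_s)
    sampling_rate <- 1 / stats::median(dt)
  }
  if (kind == "raw") raw_trace(df$value, sampling_rate, df$time_s[1])
  else lfp_trace(df$value, sampling_rate, df$time_s[1])
}

#' @rdname session_io
#' @export
write_spikes_csv <- function(train, path) {
  write.csv(data.frame(spike_time_s = fmt_num(train$spike_times)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_spikes_csv <- function(path, extent, unit_id = "unit") {
  df <- read.csv(path)
  spike_train(df$spike_time_s, extent, unit_id)
}

#' @rdname session_io
#' @export
write_track_csv <- function(tr, path) {
  write.csv(data.frame(time_s = fmt_num(tr$times), x_cm = fmt_num(tr$x),
                       y_cm = fmt_num(tr$y)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_track_csv <- function(path, sampling_rate = NULL) {
  df <- read.csv(path)
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(diff(df$time_s))
  track(df$time_s, df$x_cm, df$y_cm, sampling_rate)
}

#' @rdname session_io
#' @export
write_schedule <- function(schedule, path) {
  write.csv(data.frame(onset_s = fmt_num(schedule$onsets),
                       width_s = fmt_num(rep(schedule$pulse_width,
                                             length(schedule$onsets)))),
            path, row.names = FALSE, quote = FALSE)
  header <- list(protocol_name = schedule$protocol_name,
                 pulse_width_s = schedule$pulse_width,
                 block_boundaries = schedule$block_boundaries)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname session_io
#' @export
read_schedule <- function(path) {
  df <- read.csv(path)
  jpath <- paste0(path, ".json")
  if (file.exists(jpath)) {
    hd <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    bb <- hd$block_boundaries
    if (!is.null(bb) && is.matrix(bb)) bb <- asplit(bb, 1)
    stim_schedule(df$onset_s, hd$pulse_width_s, hd$protocol_name, bb)
  } else {
    stim_schedule(df$onset_s, df$width_s[1])
  }
}

#' Generate and write a complete synthetic session
#'
#' Builds a full session with known ground truth — a photometry trace, a
#' cohort of rate-stepped units, an evoked LFP channel driven by 0.2 Hz test
#' pulses, and an open-field track, all sharing one manipulation time — and
#' writes every signal as columnar CSV plus a JSON manifest and a JSON
#' ground-truth file into `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; all signal seeds derive from it.
#' @param duration session length, s (default 3600).
#' @param manipulation_time injection/protocol time, s (default 1800).
#' @param transient_rate_per_min photometry transient rate before the
#'   manipulation; multiplied by `transient_rate_gain` after.
#' @param transient_rate_gain post/pre transient-rate ratio.
#' @param unit_multipliers post/pre firing-rate multipliers, one unit each.
#' @param unit_base_rate baseline firing rate, Hz.
#' @param amp_pre,amp_post evoked LFP amplitudes, µV.
#' @param speed_pre,speed_post locomotion speeds, cm/s.
#' @return Invisibly, the manifest as a list.
#' @export
generate_full_session <- function(out_dir, seed = 1, duration = 3600,
                                  manipulation_time = 1800,
                                  transient_rate_per_min = 2,
                                  transient_rate_gain = 2,
                                  unit_multipliers = c(2, 1, 0.5),
                                  unit_base_rate = 5,
                                  amp_pre = 100, amp_post = 150,
                                  speed_pre = 2, speed_post = 6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  set.seed(seed)
  # photometry: piecewise-Poisson transient times
  n1 <- rpois(1, transient_rate_per_min / 60 * manipulation_time)
  n2 <- rpois(1, transient_rate_per_min * transient_rate_gain / 60 *
                 (duration - manipulation_time))
  tt <- sort(c(runif(n1, 0, manipulation_time),
               runif(n2, manipulation_time, duration)))
  pg <- photometry_gt(transient_times = tt,
                      transient_amplitudes = rep(0.10, length(tt)),
                      duration = duration)
  photo <- generate_photometry(pg, seed = seed + 1L)
  write_trace_csv(photo$trace, p("photometry.csv"))
  # units
  unit_files <- character(0)
  for (k in seq_along(unit_multipliers)) {
    ug <- unit_gt(unit_base_rate, unit_multipliers[k], manipulation_time)
    trn <- generate_spike_train(ug, duration, seed = seed + 10L + k)
    trn$unit_id <- sprintf("unit%02d", k)
    f <- sprintf("unit%02d.csv", k)
    write_spikes_csv(trn, p(f))
    unit_files <- c(unit_files, f)
  }
  # evoked LFP over test pulses
  sched <- build_test_pulses(duration)
  eg <- evoked_gt(amp_pre = amp_pre, amp_post = amp_post,
                  manipulation_time = manipulation_time)
  lfp <- generate_evoked_lfp(eg, sched, duration, seed = seed + 20L)
  write_trace_csv(lfp, p("lfp.csv"))
  write_schedule(sched, p("schedule.csv"))
  # locomotion
  tg <- track_gt(speed_pre, speed_post, change_time = manipulation_time)
  trk <- generate_track(tg, duration, seed = seed + 30L)
  write_track_csv(trk, p("track.csv"))
  manifest <- list(
    duration_s = duration, manipulation_time_s = manipulation_time,
    signals = list(
      photometry = list(file = "photometry.csv", sampling_rate_hz = pg$sampling_rate),
      units = list(files = unit_files),
      lfp = list(file = "lfp.csv", sampling_rate_hz = eg$sampling_rate,
                 schedule = "schedule.csv"),
      track = list(file = "track.csv", sampling_rate_hz = tg$sampling_rate)),
    pre_window_bins = 11:30, post_window_bins = 41:60)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  truth <- list(
    photometry = list(transient_rate_per_min = transient_rate_per_min,
                      transient_rate_gain = transient_rate_gain,
                      transient_times = tt, amplitude = 0.10),
    units = list(base_rate_hz = unit_base_rate,
                 post_multipliers = unit_multipliers),
    evoked = list(amp_pre = amp_pre, amp_post = amp_post),
    track = list(speed_pre = speed_pre, speed_post = speed_post))
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a session manifest
#'
#' @param path directory containing `manifest.json` or the file itself.
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  jsonlite::read_json(f, simplifyVector = TRUE)
}
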