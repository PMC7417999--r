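# optophys

Simulation and analysis of in vivo opto-physiology sessions in R.

`optophys` re-implements, as a tested and reusable pipeline, the signal
quantification used to study how a drug or an optogenetic plasticity
protocol changes striatal activity around a single manipulation time:

* **Fiber photometry** — dF/F normalization with a sliding 2-min baseline
  (bleach correction and normalization in one step), calcium-transient
  detection (> 5% dF/F, ≥ 1 s inter-event interval), an artifact screen
  calibrated on fluorophore-only (eYFP) controls, and 60-s binned,
  pre-normalized frequency time-courses.
* **Striatal units** — 60-s firing-rate binning and classification of each
  unit as potentiated / depressed / non-modulated by a Bonferroni-corrected
  paired t-test (α = 0.05/n) with the percent-of-pre direction rule
  (> 100% increase, < 100% decrease).
* **Opto-evoked LFP and spiking** — peri-pulse trial extraction (±100 ms
  around 0.2 Hz test pulses), peak-to-peak amplitude (max − min deflection),
  trial-by-trial wire-responsiveness screening, pre/post potentiation
  classification, and 25 ms ON/OFF evoked-firing analysis.
* **Stimulation protocols** — explicit pulse schedules for test pulses
  (0.2 Hz, 15 ms), LFS (5 Hz × 15 min), TBS (10 × 10 bursts at 10.5 Hz of
  4 pulses at 50 Hz) and HFS (2 × 5 min at 60 Hz, 14 min apart).
* **Spectra** — Bartlett-tapered Welch spectra on 512 frequency values over
  0–100 Hz, percent-of-total normalization, and the five canonical bands
  (delta 0–4, theta 4–10, beta 10–30, low-gamma 30–80, high-gamma
  80–100 Hz).
* **Behavior** — instant velocity (1 s) from X/Y tracking, 60-s binned
  percent-of-pre velocity time-courses, windowed distance moved, and the
  one-sided 3-SD subject-exclusion rule.

Because raw recordings of this kind are rarely shareable, the package ships
a **synthetic-session generator** with known ground truth (transient rates,
firing-rate multipliers, evoked amplitudes, running speeds), so every
analysis stage is verifiable by parameter recovery. See the methods
vignette (`vignettes/methods.Rmd`) for the signal models and the design
decisions behind the estimators.

## The statistics at the core

For a raw fluorescence sample x(t), the baseline is the mean over a
centered 2-min window, F(t) = mean{x(s): |s − t| ≤ 60 s}, and
dF/F = (x − F)/F. Events are strict local maxima above 5% dF/F with a
sharp-onset gate, thinned to ≥ 1 s separation; the per-session rate
estimate inverts the hard-core thinning the interval imposes,
λ̂ = −log(1 − 2Δr)/(2Δ) with Δ = 1 s.

A signal (unit firing rate, evoked amplitude) is **potentiated** when a
paired t-test between its pre- and post-manipulation 60-s bins (paired by
bin index, default bins 11–30 of each period) is significant at α/n and the
post mean exceeds 100% of the pre mean; **depressed** when significant and
below 100%.

## Worked example

```r
library(optophys)

dir <- file.path(tempdir(), "demo-session")
generate_full_session(dir, seed = 42, unit_multipliers = c(2, 1, 0.5),
                      amp_pre = 100, amp_post = 150)

trace  <- read_trace_csv(file.path(dir, "photometry.csv"), 100, kind = "raw")
events <- detect_transients(normalize_dff(trace))
print(events)
#> <transient_set> 171 events (> 0.05 dF/F, >= 1 s apart)
rates <- bin_event_rate(events, extent = c(0, 3600))
round(summarize_windows(percent_of_pre(rates)), 1)
#>  pre_mean post_mean
#>     108.7     156.5

trains <- lapply(1:3, function(k)
  read_spikes_csv(file.path(dir, sprintf("unit%02d.csv", k)),
                  extent = c(0, 3600), unit_id = paste0("unit", k)))
calls <- classify_cohort(trains)
print(calls[[1]])
#> <modulation_call> 'unit1': potentiated (p = 8.8e-22, alpha = 0.0167, 198.2% of pre)
cohort_pie(calls)
#>   potentiated     depressed non-modulated
#>             1             1             1

lfp    <- read_trace_csv(file.path(dir, "lfp.csv"), 1000, kind = "lfp")
sched  <- read_schedule(file.path(dir, "schedule.csv"))
trials <- extract_trials(lfp, sched, manipulation_time = 1800)
wire_is_responsive(trials)
#> [1] TRUE
evoked_amplitude_ratio(trials)
#> [1] 1.513
print(classify_lfp(trials))
#> <modulation_call> 'lfp': potentiated (p = 5.36e-26, alpha = 0.05, 145.9% of pre)

round(band_powers(power_spectrum(lfp)), 1)
#>      delta      theta       beta  low_gamma high_gamma
#>       39.8       12.0       31.1       14.7        2.4

trk <- read_track_csv(file.path(dir, "track.csv"))
mean(velocity_timecourse(trk)$values[41:60])
#> [1] 299.6
```

The session was simulated with a 2× transient-rate gain, unit multipliers
{2, 1, 0.5}, a 1.5× evoked-amplitude step and a 3× speed step at the 30-min
injection — and the pipeline recovers a potentiated photometry time-course,
one potentiated / one depressed / one non-modulated unit, an evoked ratio
of 1.51, and a post-injection velocity near 300% of baseline. (The
photometry window means carry visible Poisson noise: ~2 events/min pre
means each 60-s bin holds only a couple of events.)

## Command line

```sh
Rscript -e 'optophys::optophys_cli()' -- simulate full-session --out session/ --seed 7
Rscript -e 'optophys::optophys_cli()' -- protocol build hfs --out hfs.csv
Rscript -e 'optophys::optophys_cli()' -- photometry detect --trace session/photometry.csv --out events.csv
```

(or use the installed launcher at
`system.file("cli", "optophys", package = "optophys")`).
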