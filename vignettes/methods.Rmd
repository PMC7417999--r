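---
title: "Models, estimators and design decisions in optophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design decisions in optophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`optophys` quantifies in vivo recordings taken around a single
pharmacological or optogenetic manipulation: bulk calcium signals from
fiber photometry, striatal single/multi-unit firing, opto-evoked local
field potentials around sparse cortical test pulses, band-limited LFP
power, and open-field locomotion. This vignette documents the signal
models, the estimators, the tunable parameters that matter, and the design
decisions taken where the underlying conventions were genuinely open. No
empirical claim is made here that the test suite does not itself compute.

## 1. The synthetic-session world

Every stage is validated by parameter recovery on synthetic sessions with
known ground truth, because raw recordings of this kind are rarely
available. The generators state a world; it is deliberately simple:

**Photometry.** `trace(t) = B(t) (1 + s(t) + a(t) + ε(t))` where

* `B(t)` is a double-exponential photobleaching decay (default: initial
  level 100 a.u., 15% decaying with τ = 180 s, the rest with τ = 10,000 s;
  strictly positive throughout);
* `s(t)` is a sum of calcium transients: instantaneous rise, single-
  exponential decay with τ = 1.5 s (slow-indicator-like; any smooth
  unimodal kernel would serve, this one is realistic for GCaMP6s-class
  sensors), default amplitude 10% dF/F, Poisson-timed;
* `a(t)` are brief sharp artifact spikes (τ = 0.3 s) used in
  fluorophore-only (eYFP) control mode;
* `ε(t)` is white noise with SD expressed as a *fraction* of `B(t)`
  (default 1%, 0.5% in eYFP mode). Making the noise proportional to the
  instantaneous brightness is the physically realistic choice (photon and
  detector shot noise scale with collected light) and it keeps the dF/F
  noise floor constant as the session bleaches; with constant-amplitude
  additive noise, a session that bleaches to 40% of its initial level
  would more than double its dF/F noise late in the recording and the
  bleach-robustness property could not hold.

Photometry is sampled at 100 Hz and tracking at 25 Hz by default — the
acquisition rates of such streams are hardware conventions, not something
the analysis depends on, and both are configurable.

**Units.** Inhomogeneous Poisson spike trains: rate `r` before the
injection, `r × m` after. An optional stimulus-locked bump adds a fixed
rate during a short window after each pulse onset, with an optional
post-manipulation gain for evoked-plasticity scenarios.

**Evoked LFP.** Background noise is Gaussian shaped to a 1/f^α spectrum
(α = 1 by default) so spectra look field-like; each pulse adds a biphasic
damped-sine kernel (≤ 100 ms support) scaled so its peak-to-peak amplitude
equals `amp_pre` or `amp_post` depending on the pulse's phase.

**Locomotion.** A reflected random walk: the heading diffuses, per-step
speed is Gamma-distributed with mean `speed_pre`/`speed_post` (CV 0.2),
and positions fold specularly at the arena walls (30 × 30 cm default). A
deterministic straight-line mode exists for exact checks.

What the generators do **not** emulate: indicator binding kinetics,
isosbestic/hemodynamic channels, spike waveforms, volume conduction,
thigmotaxis, or any correlation between the modalities. A green recovery
test therefore establishes that the estimator is correct *for the stated
model*, not that it is robust to every pathology of real data.

## 2. Photometry: dF/F and transient detection

The baseline at each sample is the mean of the raw trace over a centered
2-min window clipped to the trace extent, and `dF/F = (x − F)/F`. The mean
(rather than median) and the clipped edge rule are conventions; the window
statistic matters little for 2-min windows over ~1.5 s transients. Two
consequences worth knowing:

* dF/F is exactly invariant under positive rescaling of the trace, and a
  constant trace maps to identically zero;
* within half a window of the trace start, a fast bleach component biases
  the clipped-window baseline low and dF/F up (by up to ~2.5% with the
  default bleach). Events in the first minute of a session should be
  interpreted with this in mind; the eYFP artifact defaults are calibrated
  so that control traces stay below the 5% screen despite this edge bias.

**Detection.** Events are strict local maxima above the 5% threshold with
at least 1 s between surviving events, enforced greedily in descending
amplitude order (ties: earlier peak wins). Two refinements were forced by
implementation experience rather than chosen a priori:

1. *Light smoothing + onset gate.* On raw 100 Hz samples with a 1% dF/F
   noise floor, the slow decay tail of a 10% transient stays near the
   threshold for over a second, and white-noise wiggles on that tail
   create secondary local maxima just beyond the 1 s interval: naive
   local-maxima detection double-counts by nearly a factor of two.
   Candidates are therefore taken from a 100-ms boxcar-smoothed copy of
   the trace and must rise more than `threshold/2` above the minimum of
   the smoothed trace over the preceding second. A real transient has an
   essentially instantaneous onset and passes trivially; a tail wiggle
   rises by only a noise-sized amount and is rejected. Both parameters are
   exposed (`smooth_window`, `min_rise`) and setting them to zero restores
   bare local-maxima detection.
2. *Dead-time correction.* The 1 s inter-event rule is a hard-core
   thinning: two true transients closer than 1 s can never both be
   counted, so the raw count rate under-estimates the true rate by ~9% at
   6 events/min. For Poisson events with i.i.d. amplitude ranks the
   surviving rate is `r = (1 − e^{−2Δλ})/(2Δ)`; `transient_rate()` inverts
   this (`λ̂ = −log(1 − 2Δr)/(2Δ)`) and recovers rates of 1–6 events/min
   without bias. Binned time-courses (`bin_event_rate`) deliberately stay
   on the raw counting scale, as a time-course convention; the correction
   applies to session-level rate estimates.

The artifact screen asks a cruder question — does *any* raw local maximum
exceed 5%? — and is applied to raw (unsmoothed) dF/F, because its job is
to certify that motion artifacts in fluorophore-only controls cannot reach
the event threshold at all, not to count events.

## 3. Modulation classification

Firing rates (and evoked amplitudes) are binned at 60 s. The
classification contract, shared by `classify_unit()` and `classify_lfp()`:

* two-sided paired t-test between the pre- and post-manipulation test
  windows, **paired by bin index within the window** — the only
  order-preserving pairing available when the bins themselves are the
  replicates;
* significant iff `p < α / n_comparisons`, with `n_comparisons` the number
  of signals classified together (Bonferroni);
* direction from the percent-of-pre rule: post mean > 100% of pre mean is
  a potentiation, < 100% a depression;
* identical windows (zero difference variance) are reported as p = 1,
  non-modulated, and flagged — a degenerate input should never look
  significant.

The default test windows are bins 11–30 of each 30-bin period (session
bins 11–30 and 41–60 for a 60-min session with the manipulation at
30 min). The source conventions for these windows are stated
inconsistently in the field ("10–30 min", "30 bins", "11–30/41–60"
variants); skipping the first ten post-injection minutes avoids the
pharmacokinetic onset and the matching pre-window keeps the pairing
symmetric. All windows are arguments.

Calibration properties verified by the suite: under a null multiplier the
flagged fraction stays at or below the corrected α, and a 2× step at 5 Hz
baseline is detected with power > 0.95.

## 4. Evoked responses

Trials cover ±100 ms around each 0.2 Hz test pulse; pulses inside
plasticity-protocol blocks (carried by the schedule) are excluded, and
pulses without full coverage are dropped with a warning. The headline
amplitude is the peak-to-peak (max − min) of the **post-onset (0, +100 ms]
window**; the pre-onset [−100, 0) window serves only as the within-trial
comparison for the responsiveness screen. The source phrasing covers both
windows without assigning roles; this split matches the screen's use of
the pre-window as its reference. The 15 ms light pulse is left inside the
response window because synthetic data carry no photovoltaic artifact; a
`blank_ms` argument exists for real recordings.

A wire is *responsive* when the trial-by-trial paired t-test (Pre-phase
trials only) is significant at α = 0.05 — the inclusion α is not printed
anywhere authoritative, so the conventional value is used — **and** the
response window is larger on average, since an evoked response adds a
deflection. Under pure noise this combination flags ~α/2 of wires.

**Noise-floor bias and the ratio estimator.** Peak-to-peak of
noise-plus-signal is biased upward by the expected extreme deviation of
the noise, and the bias does not cancel in a ratio of per-trial means:
with background at 20% of the kernel amplitude, a true post/pre ratio of
0.5 measured from per-trial amplitudes comes out near 0.65. Averaging the
~360 snippets of a phase into one waveform first reduces the noise ~19×
and all but removes the bias, so `evoked_amplitude_ratio()` measures the
peak-to-peak of phase-averaged waveforms and recovers ratios 0.5–2.0
within a few percent. The binned time-course offers the same choice
(`average_within_bin`), defaulting to the per-trial convention for
fidelity to common practice; classification is unaffected either way,
because an additive bias common to both windows does not move a paired
test or the >100%/<100% side.

Evoked firing uses 25 ms OFF/ON windows around each onset, counts
converted to Hz, a paired t-test across trials for the activation call,
and — across the manipulation — Pre- vs Post-phase ON rates paired by
chronological order (by design there are 360 trials in each phase;
unequal counts are truncated with a warning).

## 5. Spectra

`power_spectrum()` is a Welch estimate with a Bartlett (triangular) taper
and 50% segment overlap. The reported grid is fixed by contract — 512
frequency values spanning 0–100 Hz, spacing 100/511 ≈ 0.1956 Hz — so the
segment length is *derived*: `round(511 · fs / 100)` samples (5110 at
1 kHz). Per-segment means are removed (the DC bin would otherwise be the
trace offset), densities are one-sided, and the 0–100 Hz range is
renormalized to percent of total **within that range**, the only range
reported. "Overlap of 50" is ambiguous between 50% and 50 samples in the
acquisition software this emulates; 50% is the default, a sample count is
accepted. Band shares use half-open intervals `[lo, hi)` with high-gamma
closed at 100 Hz, so the five bands partition the grid exactly and always
sum to 100.

Group averaging is hierarchical: electrodes average within subject, then
subjects within group, so a subject with ten electrodes counts once. A
Parseval check (unnormalized one-sided power within 5% of the variance of
white noise) guards the absolute scaling.

## 6. Behavior

Instant velocity over 1 s windows is the *path length* accumulated within
the window divided by the window — robust to direction changes inside the
window, invariant under rigid motions of the coordinate frame, and exact
for straight-line motion. End-to-end displacement would under-estimate
curved paths; "instant velocity (1 s)" is not defined more precisely by
the convention this follows.

The 3-SD exclusion rule is one-sided (only abnormally *high* distances
are excluded) and computed leave-one-out: each candidate is compared
against the mean + 3 SD of the *other* subjects. With the candidate
included, a single extreme value inflates the SD enough that, in small
groups, it can never exceed its own cutoff — a 100 among {10, 11, 9, 12,
10} survives an included-SD rule but is the obvious outlier; the
leave-one-out (Grubbs-style) form actually excludes it. The rule is not
iterated.

## 7. Protocols

All builders put the first pulse at t = 0 of the protocol epoch; absolute
placement comes from the session manifest (`shift_schedule()`). Pulse
width is 15 ms throughout. Two details are conventions where the source is
silent: TBS repetitions start every 10 s (a repetition spans < 1 s, so
they can never overlap — enforced by the schedule invariant, not assumed),
and HFS is modelled as discrete 15 ms pulses at 60 Hz rather than
duty-cycled continuous light. Within a TBS repetition, bursts of 4 pulses
at 50 Hz (60 ms span) sit on a 10.5 Hz grid (95.2 ms spacing), so bursts
do not collide either. Serializing a schedule to CSV + JSON header and
reading it back is the identity.

## 8. Numerical choices and degenerate inputs

* Bins are half-open `[left, right)` everywhere; an event or spike exactly
  on an edge belongs to the later bin. Only complete bins are formed.
* A baseline window with mean F ≤ 0 raises a degenerate-baseline error
  naming the sample range, rather than returning infinities.
* Zero-variance paired tests return p = 1 with a flag; a zero pre-mean
  makes percent-of-pre an error (`optophys_normalization_undefined`), not
  an `Inf`.
* Greedy thinning ties (equal amplitudes) resolve toward the earlier peak.
* All generators are bit-reproducible for identical `(ground truth, seed)`
  inputs; every acceptance property runs under fixed seeds.
* The dead-time inversion saturates when `2Δr ≥ 1` (observed events every
  Δ on average); this is reported as an error rather than extrapolated.

## 9. Known limitations

* The transient detector is tuned for sparse, large events over a
  stationary noise floor; dense overlapping transients (≫ 6/min) merge
  and are under-counted even after the dead-time correction.
* Per-trial evoked amplitudes carry the noise-floor bias described above;
  absolute amplitude time-courses should be read as biased-up by a
  constant, or computed with `average_within_bin = TRUE`.
* The classification windows assume the standard 30 + 30 min session
  layout; other layouts must set the windows explicitly.
* `wire_is_responsive()` treats suppression-type evoked responses
  (post-onset amplitude *decrease*) as non-responsive by design.
* The synthetic world draws each modality independently; cross-modal
  couplings (e.g. movement-locked calcium artifacts) must be constructed
  manually by composing ground truths.
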