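---
title: "Blink-based synchronization of EEG and VR eye-tracking streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blink-based synchronization of EEG and VR eye-tracking streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrsync)
```

## The problem

Middleware such as LabStreamingLayer can merge an EEG/EMG amplifier stream
and a VR headset's eye-tracking stream onto one clock, but it cannot see the
hardware-intrinsic and transmission delays of either device. When an
analysis needs event-level temporal alignment — evoked potentials,
fixation-related analyses, online brain-computer interfaces — the constant
offset between the streams and its variability (jitter) must be measured
before the experiment.

`vrsync` implements a hardware-free-to-test version of a simple measurement
procedure: the participant blinks in time with a metronome (60 BPM), and
every blink appears in both streams — as an eye-closure onset in the eye
tracker's `both_blinking` channel and as a muscle burst on an EMG channel
recorded by the EEG amplifier. The per-blink lag between the two appearances
of the same physical event estimates the inter-stream offset; its standard
deviation estimates the jitter.

## The estimator

For each recording the pipeline is:

1. **Dejitter** both streams' timestamps: raw per-sample timestamps are
   replaced by an ordinary-least-squares line fitted to (sample index,
   timestamp). The estimator behind the regularization is deliberately
   exposed as configuration (`dejitter_method`), with a Theil–Sen option
   for clocks with isolated spikes, because middleware implementations vary
   and the operation is conventionally "fit a linear clock". The OLS fit
   preserves the mean clock exactly and is idempotent.
2. **Resample** the EMG stream from 500 Hz to the 250 Hz analysis rate.
   The anti-alias low-pass (Butterworth order 8, cutoff 0.45 × target
   rate) is applied forward–backward so that it contributes *zero* group
   delay: any filter lag here would contaminate the very latency being
   measured.
3. **Detect eye landmarks**: the eye tracker defines an eye as closed when
   its openness value drops strictly below 0.1. Each maximal run of 1s in
   `both_blinking` (derived from the openness channels when absent) is one
   blink; its first sample is the eye-side landmark.
4. **Detect EMG landmarks**: the EMG channel is band-passed at 0.75–5 Hz
   (Butterworth order 3, forward–backward, hence zero-phase). Within a
   padded window around each blink (0.5 s per side), the landmark is the
   *rising crossing of 90% of the window maximum*: walk back from the
   earliest absolute maximum along the contiguous run of samples at or
   above 0.9 × max. A fractional leading-edge landmark is invariant to
   burst amplitude and robust to plateaued peaks; with fraction 1.0 it
   degenerates to the peak itself.
5. **Per-blink offset**: `offset_ms = (emg_index − eye_index) × 1000 /
   250`. Positive offsets mean the eye tracker reports the event *earlier*
   than the EMG (the eye tracker is "faster"); correcting for the offset
   therefore delays the eye-tracker timestamps onto the EEG clock. Note
   that the index difference is multiplied by the sampling *interval*
   (1000/rate ms), which maps 9 samples at 250 Hz to 36 ms.
6. **Aggregate**: mean and standard deviation over valid blinks, followed
   by a *single* pass excluding blinks more than 3 standard deviations
   from the mean, then recomputation. The pass is not iterated; with the
   exclusion threshold at 3σ a second pass would rarely change anything
   and iterated trimming biases the variance estimate low.

Blinks are never silently dropped: each carries a validity flag and an
exclusion reason (`truncated` when the closure run touches the window edge,
`distorted_emg`, or `outlier`).

### Distorted-EMG rule

Real sessions contain the occasional double blink or movement artifact. A
window is flagged `distorted_emg` when (a) two or more local peaks above
70% of the window maximum lie more than 200 ms apart — no unique burst —
or (b) the window maximum is below 5 × the median absolute amplitude of
the whole filtered channel — no burst at all. Both thresholds are
configurable; they are a pragmatic stand-in for manual artifact screening,
not a validated artifact taxonomy.

### Trimming strategies

Recording files from live middleware often differ in length within a
session. `select_trimming()` evaluates candidate alignments — `none`,
trim-to-shortest-common-duration from the `head`, from the `tail`, or
`symmetric` — and keeps the strategy whose pooled per-blink offsets have
minimal standard deviation, ties going to the first listed. Minimal
pooled STD is the natural criterion because a misaligned trim that keeps a
corrupted segment inflates exactly that statistic.

### Resolution floor and sign conventions

The eye tracker samples at 120 Hz natively even though its stream is
transmitted at 250 Hz, so no estimate can resolve better than one device
sample, 1000/120 ≈ 8.33 ms. All recovery tolerances in the tests use this
granularity. Grid quantization alone puts a floor under the jitter: a
uniformly distributed closure phase contributes 8.33/√12 ≈ 2.4 ms of STD
before any transmission jitter, which is what the synthetic closure tests
reproduce (observed ≈ 2.7–3.3 ms including the 250 Hz detection ticks).

Indexing is R-native (1-based). Every offset is an index *difference*, so
no formula changes relative to a 0-based formulation. Epoch windows are
half-open `[start, end)`; timestamps are seconds on the shared clock.

## The SSVEP speller consumer

The demonstrated downstream use is a steady-state visually evoked
potential (SSVEP) speller: clusters of letters flicker at
4, 5, 5.5, 6, 7 and 7.4 Hz, and the attended frequency is read out of
occipito-parietal EEG (O1, Oz, O2, P3, P7, Pz, P8, P4).

- **Preprocessing** (`preprocess_epoch`): per channel, reflect-pad by
  0.5 s, apply a 50 Hz notch (biquad, Q = 30) and a 1–15 Hz Butterworth
  band-pass of order 3, both forward–backward, then unpad. Output length
  equals input length and the chain is zero-phase.
- **References** (`make_reference`): sine/cosine pairs at the stimulus
  frequency and its harmonics, phase zero at flicker onset. Two harmonics
  by default: the second harmonics of 4–7.4 Hz stay at or below 14.8 Hz,
  inside the analysis band, while third harmonics would be band-attenuated.
- **Decision statistic** (`cca_max_corr`): the largest canonical
  correlation between the multichannel epoch and each reference matrix;
  the predicted frequency is the argmax, ties resolving to the lower
  frequency. The implementation whitens the auto-covariance blocks by
  Cholesky factors and takes the largest singular value of the whitened
  cross-covariance. A trace-normalized ridge (1e-8, escalating) is applied
  *only* when a block is numerically rank-deficient (reciprocal condition
  below 1e-10); keeping the ridge off for well-conditioned inputs
  preserves CCA's exact invariance under invertible channel mixing.
- **Epoch alignment** (`extract_epoch`): the epoch starts at
  `flicker_onset + hardware_offset + ocular_delay`. The ocular delay
  (default 100 ms) is the retina-to-visual-cortex conduction time; the
  hardware offset is the measured inter-stream offset (e.g. 36 ms).
  Applying the combined delay as a window shift is the simplest
  formulation consistent with aligning signals at their cortical arrival;
  whether to shift before or after windowing is mathematically equivalent
  for a rigid window, which is why the shift formulation was chosen.
- **Scoring** (`score_session`, `itr_bpm`): accuracy and the Wolpaw
  information transfer rate `B = log2 N + P log2 P +
  (1−P) log2((1−P)/(N−1))` bits per selection, times `60/T` selections per
  minute. `N` defaults to 30 (the full letter set reachable through gaze
  pre-selection of 6-letter clusters) and `T` to the flicker period; both
  are explicit parameters because published ITR figures depend strongly on
  how selection time (gaze dwell, inter-trial gaps) is accounted, and no
  single convention is canonical. `itr_bpm` refuses below-chance
  accuracies (the formula's ITR is not meaningful there);
  `score_session` instead reports 0 bits/min for a below-chance session
  so that batch scoring never aborts.

## The synthetic session generator

`simulate_blink_recording()` emulates the acquisition conditions the
estimator was designed for; it is first-class, tested code, not a fixture.

- Blinks are paced at 60 BPM in sets of 10–20 (default 20; any count is
  configurable). Human metronome synchronization is good to a few tens of
  milliseconds, not to a sample: `pace_sd_ms` (default 25 ms) models this
  timing variability. It matters beyond realism — 1 s pacing is exactly
  120 cycles of the 120 Hz device grid, so perfectly metronomic blinks
  would all strike the same grid phase and the quantization jitter the
  method must tolerate would be invisible. With 25 ms of pacing noise the
  closure phase is effectively uniform on the grid.
- The eye-openness trace falls linearly over 30 ms (crossing the 0.1
  closure threshold exactly at the ground-truth closure instant), holds at
  0 for 70 ms, and reopens over 80 ms. It is sampled on the 120 Hz device
  grid at a uniform random phase, then emitted at 250 Hz by
  sample-and-hold, exactly as a polling transmitter would.
  `both_blinking` is bit-equal to the 0.1-threshold image of the emitted
  openness channels.
- The EMG burst is a raised cosine of 150 ms with log-normal amplitude
  variation (SD 0.15) and additive white noise (SD 0.02 of unit
  amplitude). The burst is placed so that its *filtered* 90% rising
  crossing lands at `closure + true_offset + jitter`: the band-pass
  widens the burst and advances its leading edge, so the generator
  calibrates the burst-start-to-crossing lag numerically on a 2 kHz grid
  before placement. Optionally a fraction of blinks receives a second
  burst 300 ms later, producing the double-peak distortion the estimator
  must reject.
- Timestamps carry 0.2 ms of Gaussian transmission noise, exercising the
  dejittering stage; the three sampling grids (120, 250, 500 Hz) start at
  independent random phases.

`simulate_ssvep_trial()` builds epochs as harmonics of the stimulus
frequency with a common random phase, mixed across channels by a random
weight vector, embedded in 1/f ("pink") background noise plus a 50 Hz
line component. SNR is defined in the 1–15 Hz analysis band — signal
power over noise power after band-passing both — because that is the band
the classifier sees. `make_colored_noise()` shapes white Gaussian noise in
the frequency domain by `f^(-exponent/2)` and standardizes to unit
variance. All generators are pure functions of their seed.

What the generator does *not* emulate: volume conduction and realistic
channel covariance, eye-tracker dropouts, drifting clocks (the offset is
constant within a recording), asymmetric or multi-phasic blink EMG beyond
the double-peak artifact, and any gaze geometry. Passing tests therefore
demonstrate correctness of the estimator arithmetic and its robustness to
grid quantization, injected jitter, and the modeled artifact — not
performance on any particular hardware, whose offset must always be
re-measured.

## Numerical choices and degenerate inputs

- `signal::filtfilt` applies no edge treatment of its own, so every
  zero-phase filter here first extends the signal by odd (point)
  reflection — about 2 s for the 0.75 Hz high-pass corner, 0.5 s for the
  epoch band-pass, 120 samples for the anti-alias low-pass — and discards
  the extension afterwards. On a constant input the full anti-alias chain
  is accurate to ~1e-9.
- The order-8 anti-alias low-pass at 0.45 × target rate has measurable
  passband droop from about 0.28 × target rate upward (two-pass gain
  ≈ 0.87 at 0.4 × target); content meant to survive resampling losslessly
  should sit below ~0.28 × the target rate.
- Down-sampling requires an exact integer decimation factor; anything else
  errors (`non-integer decimation`) rather than silently interpolating.
- `emg_peak_index` errors on constant or non-positive windows ("no EMG
  peak"); `single_blink_offset` converts that error into a
  `distorted_emg` exclusion so one flat window cannot abort a session.
- `aggregate_offsets` needs at least two valid blinks; with zero spread
  the outlier pass is skipped (nothing can exceed 0 × 3).
- Equal maxima in an EMG window resolve to the earliest; equal canonical
  correlations resolve to the lowest stimulus frequency. Both tie-breaks
  are deterministic and documented.
- CSV recordings store samples and timestamps with full double precision
  (`%.17g`), so file round trips are exact to 1e-9 s and beyond.

## Problem sizes used by the test-suite and acceptance runs

Simulated sessions in the shipped tests use 5–20 blinks for unit checks,
100 blinks per injected offset for recovery sweeps, and 500 blinks for
jitter-floor and injected-jitter checks — large enough that binomial and
variance estimates are stable, small enough that the whole suite runs in
about a minute. The SSVEP noise sweep uses 200 trials per SNR level at a
2 s flicker period. These sizes are the package's chosen study
conditions; rerunning with larger sessions only tightens the same
statistics.

## Known limitations

- Recording I/O is CSV-based (one file per stream plus a JSON manifest).
  Binary multi-stream containers are out of scope; export to CSV first.
- The estimator assumes a constant offset per recording; clock *drift*
  within a recording is not tracked (the linear dejittering absorbs a
  constant rate error per stream, not a changing inter-stream lag).
- The distortion rule is a heuristic stand-in for manual screening; tune
  `distortion_peak_frac`, `distortion_sep_ms` and `distortion_floor` to
  the noise floor of the actual hardware.
- The classifier is the training-free canonical-correlation decoder;
  trained decoders and ERP paradigms are out of scope.
- The correlation margin between the true frequency and the runner-up
  grows with flicker period only on average: for a single frequency the
  runner-up's spectral leakage depends on how many fractional cycles of a
  *competitor* the epoch truncates, which is not monotone in epoch
  length.
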