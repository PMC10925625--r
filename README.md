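# vrsync

Blink-based synchronization of EEG/EMG and VR eye-tracking streams, with an
SSVEP speller classifier as the demonstrated consumer, and a synthetic
multimodal-session simulator that makes both fully testable without any
hardware.

## The problem

Combining a commercial EEG amplifier with the eye tracker integrated in a
VR headset gives ecologically valid multimodal recordings — but middleware
stream merging (e.g. LabStreamingLayer) cannot account for the intrinsic
hardware and transmission delays of either device. For event-level
analyses and online brain-computer interfaces, the constant inter-stream
**offset** and its variability (**jitter**) must be measured first.

`vrsync` implements the blink-based measurement: a participant blinks in
time with a 60 BPM metronome; each blink appears both as an eye-closure
onset in the tracker stream (openness < 0.1 on the `both_blinking`
channel) and as a burst on an EMG channel recorded by the EEG amplifier.
With both streams at the 250 Hz analysis rate, the per-blink offset is

```
offset_ms = (i_EMG − i_eye) × 1000 / 250
```

where `i_eye` is the first sample of the closure run and `i_EMG` is the
rising crossing of 90% of the zero-phase band-pass filtered
(0.75–5 Hz, Butterworth order 3) EMG burst's peak. Offsets are aggregated
as mean ± STD over the blinks of a recording after a single 3σ outlier
pass; recordings of unequal length are aligned by the trimming strategy
with minimal pooled STD. A positive offset means the eye tracker reports
events earlier than the EEG. Resolution is bounded by the tracker's
native 120 Hz grid: one device sample ≙ 8.33 ms.

The downstream consumer is a steady-state visually evoked potential
(SSVEP) speller: occipito-parietal EEG epochs (channels O1, Oz, O2, P3,
P7, Pz, P8, P4; 50 Hz notch + 1–15 Hz zero-phase band-pass) are
classified by the largest canonical correlation ρ against sin/cos
references (with harmonics) at the six cluster flicker frequencies
4, 5, 5.5, 6, 7, 7.4 Hz. Epochs are aligned at
`flicker_onset + hardware_offset + 100 ms ocular delay`, and sessions are
scored by accuracy and the Wolpaw information transfer rate
`ITR = [log2 N + P log2 P + (1−P) log2((1−P)/(N−1))] × 60/T` bits/min.

## Worked example

```r
library(vrsync)

# a synthetic 20-blink session with a known 36 ms offset
sim <- simulate_blink_recording(
  blink_sim_params(n_blinks = 20, true_offset_ms = 36, seed = 7))
est <- estimate_offset(sim$recording)
print(est)
#> <offset_estimate> mean 30.20 ms, STD (jitter) 2.75 ms
#>   blinks used: 20, excluded: 0
```

The estimate sits within one 120 Hz device sample (8.33 ms) of the
injected 36 ms — the method's resolution floor — and the 2.75 ms STD is
the grid-quantization jitter floor itself (an exactly periodic blink would
hide it; the simulator's 25 ms human pacing variability exposes it).

```r
# feed the measured offset into the speller pipeline
cfg <- ssvep_config(hardware_offset_ms = round(est$mean_offset_ms))
sess <- simulate_ssvep_session(stimulus_set(flicker_period = 4),
                               snr_db = 0, cfg = cfg, seed = 1)
stim <- stimulus_set(flicker_period = 4)
trials <- lapply(seq_len(nrow(sess$truth)), function(i) {
  ep <- extract_epoch(sess$recording, sess$truth$onset_s[i],
                      sess$truth$period_s[i], cfg)
  classify_epoch(ep, attr(ep, "rate"), stim, cfg,
                 true_freq = sess$truth$freq[i], preprocess = TRUE)
})
print(score_session(trials, stim))
#> <session_score> accuracy 100.0% over 6 trials, ITR 73.60 bits/min (T = 4 s)
print(trials[[4]])
#> <ssvep_trial> predicted 6.0 Hz (true: 6.0 Hz)
#>     4     5   5.5     6     7   7.4
#> 0.368 0.270 0.415 0.934 0.221 0.283
```

At 0 dB in-band SNR all six frequencies classify correctly; the
correlation vector shows the 6 Hz reference standing far above the
competitors. The ITR of 73.6 bits/min is the `P = 1` limit
`log2(30) × 60/4` for `N = 30` selectable letters at one 4 s selection —
an upper bound under idealized timing, not a hardware claim.

There is also a command-line interface:

```sh
Rscript inst/cli/vrsync.R simulate blinks --out rec --seed 9 --truth truth.json
Rscript inst/cli/vrsync.R measure-offset rec --report offset.json
Rscript inst/cli/vrsync.R classify sess --markers FlickerMarkers --offset-ms 36
```

Reports are versioned JSON embedding the resolved configuration; excluded
blinks are logged to stderr with their reason (`truncated`,
`distorted_emg`, `outlier`).

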