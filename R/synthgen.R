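#' Parameters for a synthetic paced-blink session
#'
#' Describes one simulated blink-synchronization recording: metronome-paced
#' blinks (60 BPM), an eye tracker sampling on its native 120 Hz device
#' grid but transmitted at 250 Hz by sample-and-hold, an EMG stream at
#' 500 Hz, and a configurable ground-truth inter-stream offset and jitter.
#'
#' Human metronome synchronization is not sample-accurate: `pace_sd_ms`
#' models the blink-timing variability around the beat (default 25 ms,
#' typical of sensorimotor synchronization tapping error). It is what
#' spreads blink instants uniformly over the 120 Hz device grid — at an
#' exact 60 BPM pace every blink would hit the same grid phase, hiding the
#' quantization jitter the estimator must tolerate.
#'
#' @param n_blinks Number of blinks (sessions used sets of 10-20).
#' @param pace_bpm Metronome tempo, beats per minute.
#' @param true_offset_ms Ground-truth offset: the EMG landmark lags the
#'   true closure instant by this amount (positive = eye tracker faster).
#' @param jitter_sd_ms Gaussian SD of per-blink transmission jitter added
#'   to the offset, ms.
#' @param pace_sd_ms Gaussian SD of blink timing around the metronome
#'   beat, ms.
#' @param eye_device_rate Native eye-tracker rate, Hz.
#' @param stream_rate Transmission rate of the eye stream, Hz.
#' @param emg_rate EMG stream rate, Hz.
#' @param blink_duration_ms Raised-cosine EMG burst duration, ms.
#' @param emg_amp_jitter Relative SD of per-blink burst amplitude.
#' @param emg_noise_sd Additive white-noise SD on the EMG, relative to
#'   unit burst amplitude.
#' @param ts_noise_sd_s SD of timestamp transmission jitter, seconds
#'   (removed by dejittering).
#' @param distortion_fraction Fraction of blinks given a second EMG burst
#'   (a distorted double-peak artifact the estimator must reject).
#' @param closure_threshold Openness value defining closure.
#' @param lead_in_s Quiet seconds before the first and after the last
#'   blink.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A list of class `"blink_sim_params"`.
#' @export
blink_sim_params <- function(n_blinks = 20, pace_bpm = 60,
                             true_offset_ms = 36, jitter_sd_ms = 0,
                             pace_sd_ms = 25, eye_device_rate = 120,
                             stream_rate = 250, emg_rate = 500,
                             blink_duration_ms = 150, emg_amp_jitter = 0.15,
                             emg_noise_sd = 0.02, ts_noise_sd_s = 2e-4,
                             distortion_fraction = 0,
                             closure_threshold = 0.1, lead_in_s = 2,
                             seed = 1) {
  if (n_blinks < 1) stop("n_blinks must be >= 1")
  if (any(c(pace_bpm, eye_device_rate, stream_rate, emg_rate) <= 0)) {
    stop("rates must be positive")
  }
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be >= 0")
  if (distortion_fraction < 0 || distortion_fraction > 1) {
    stop("distortion_fraction must be in [0, 1]")
  }
  structure(as.list(environment()), class = "blink_sim_params")
}

# Eye-openness envelope around one closure instant: piecewise-linear fall
# (30 ms, crossing the closure threshold exactly at `closure`), 70 ms hold
# at zero, 80 ms linear reopen.
openness_envelope <- function(t, closure, threshold) {
  fall <- 0.030; hold <- 0.070; rise <- 0.080
  t_fall0 <- closure - (1 - threshold) * fall
  t_zero <- t_fall0 + fall
  t_rise0 <- t_zero + hold
  t_open <- t_rise0 + rise
  y <- rep(1, length(t))
  in_fall <- t >= t_fall0 & t < t_zero
  y[in_fall] <- 1 - (t[in_fall] - t_fall0) / fall
  y[t >= t_zero & t < t_rise0] <- 0
  in_rise <- t >= t_rise0 & t < t_open
  y[in_rise] <- (t[in_rise] - t_rise0) / rise
  y
}

raised_cosine <- function(t, t0, duration) {
  tau <- t - t0
  inside <- tau >= 0 & tau <= duration
  y <- numeric(length(t))
  y[inside] <- 0.5 * (1 - cos(2 * pi * tau[inside] / duration))
  y
}

# Lag from burst start to the filtered 90%-of-peak rising crossing.
# The zero-phase band-pass (0.75-5 Hz) widens a 150 ms raised-cosine burst,
# shifting its leading-edge crossing; the generator compensates so the
# filtered crossing lands exactly at closure + offset. Calibrated
# numerically on a fine grid with linear interpolation of the crossing.
emg_crossing_lag_s <- function(duration_s, peak_fraction = 0.9,
                               band_low = 0.75, band_high = 5, order = 3) {
  rate <- 2000
  t <- seq(0, 8, by = 1 / rate)
  t0 <- 4
  x <- raised_cosine(t, t0, duration_s)
  filt <- signal::butter(order, c(band_low, band_high) / (rate / 2), "pass")
  y <- zero_phase_filter(x, filt, pad = 2L * rate)
  p <- which.max(y)
  thr <- peak_fraction * y[p]
  i <- p
  while (i > 1 && y[i - 1] >= thr) i <- i - 1L
  # interpolate the exact crossing between samples i-1 and i
  frac <- if (i > 1 && y[i] > y[i - 1]) (thr - y[i - 1]) / (y[i] - y[i - 1]) else 0
  t_cross <- t[i - 1] + frac / rate
  t_cross - t0
}

#' Simulate a paced-blink recording with known ground truth
#'
#' Per blink k at metronome time t_k (plus pacing variability), a true
#' closure instant c_k is drawn; the eye-openness trace crosses the
#' closure threshold exactly at c_k, is sampled on the 120 Hz device grid
#' (uniform random grid phase), and emitted at the 250 Hz stream rate by
#' sample-and-hold, with `both_blinking` derived by the 0.1 rule. The EMG
#' burst is placed so its filtered 90% rising crossing lands at
#' `c_k + true_offset_ms + jitter_k`. Timestamps carry small transmission
#' noise (removed by dejittering). Deterministic given the seed.
#'
#' @param p A [blink_sim_params()].
#' @return List with `recording` (a [recording()]: streams `EyeTracking`
#'   at the stream rate and `EMG` at the EMG rate) and `truth` (per-blink
#'   closure instants, offsets, distortion flags, plus the parameters).
#' @export
simulate_blink_recording <- function(p = blink_sim_params()) {
  period <- 60 / p$pace_bpm
  envelope_s <- 0.030 + 0.070 + 0.080
  if (max(envelope_s, p$blink_duration_ms / 1000) >= period) {
    stop("blinks overlap")
  }
  withr::with_seed(p$seed, {
    t_blink <- p$lead_in_s + (seq_len(p$n_blinks) - 1) * period +
      stats::rnorm(p$n_blinks, 0, p$pace_sd_ms / 1000)
    closure <- t_blink
    offsets_ms <- p$true_offset_ms + stats::rnorm(p$n_blinks, 0, p$jitter_sd_ms)
    duration <- p$lead_in_s * 2 + p$n_blinks * period

    # eye tracker: native device grid with uniform random phase
    grid_phase <- stats::runif(1) / p$eye_device_rate
    g <- seq(grid_phase, duration, by = 1 / p$eye_device_rate)
    open_dev <- rep(1, length(g))
    for (k in seq_len(p$n_blinks)) {
      win <- which(g >= closure[k] - 0.2 & g <= closure[k] + 0.3)
      open_dev[win] <- pmin(open_dev[win],
                            openness_envelope(g[win], closure[k],
                                              p$closure_threshold))
    }
    # transmission at the stream rate: sample-and-hold of the device values
    eye_phase <- stats::runif(1) / p$stream_rate
    s <- seq(eye_phase, duration, by = 1 / p$stream_rate)
    hold <- findInterval(s, g)
    open_s <- ifelse(hold == 0, 1, open_dev[pmax(hold, 1)])
    both <- as.integer(open_s < p$closure_threshold)
    eye_samples <- cbind(left_closed = both, right_closed = both,
                         both_blinking = both,
                         left_openness = open_s, right_openness = open_s)
    eye_ts <- s + stats::rnorm(length(s), 0, p$ts_noise_sd_s)

    # EMG: raised-cosine bursts placed via the calibrated crossing lag
    lag <- emg_crossing_lag_s(p$blink_duration_ms / 1000)
    emg_phase <- stats::runif(1) / p$emg_rate
    e <- seq(emg_phase, duration, by = 1 / p$emg_rate)
    emg <- stats::rnorm(length(e), 0, p$emg_noise_sd)
    amps <- exp(stats::rnorm(p$n_blinks, 0, p$emg_amp_jitter))
    n_dist <- round(p$distortion_fraction * p$n_blinks)
    distorted <- sort(sample(p$n_blinks, n_dist))
    for (k in seq_len(p$n_blinks)) {
      t_cross <- closure[k] + offsets_ms[k] / 1000
      t0 <- t_cross - lag
      emg <- emg + amps[k] * raised_cosine(e, t0, p$blink_duration_ms / 1000)
      if (k %in% distorted) {
        emg <- emg + 0.8 * amps[k] *
          raised_cosine(e, t0 + 0.3, p$blink_duration_ms / 1000)
      }
    }
    emg_ts <- e + stats::rnorm(length(e), 0, p$ts_noise_sd_s)

    rec <- recording(list(
      timed_stream("EyeTracking", eye_samples, p$stream_rate, eye_ts),
      timed_stream("EMG", matrix(emg, ncol = 1, dimnames = list(NULL, "EMG")),
                   p$emg_rate, emg_ts)),
      metadata = list(session_id = sprintf("sim_seed_%d", p$seed),
                      simulated = TRUE))
    truth <- list(
      params = p,
      blinks = data.frame(blink = seq_len(p$n_blinks),
                          closure_s = closure, offset_ms = offsets_ms,
                          distorted = seq_len(p$n_blinks) %in% distorted))
    list(recording = rec, truth = truth)
  })
}

#' Parameters for a synthetic SSVEP trial
#'
#' @param freq Stimulus frequency, Hz.
#' @param flicker_period Epoch duration, seconds.
#' @param rate Sampling rate, Hz.
#' @param harmonic_amps Amplitudes of the fundamental and harmonics.
#' @param snr_db In-band (1-15 Hz) signal-to-noise ratio in dB; `Inf` for
#'   a noiseless epoch.
#' @param noise_exponent 1/f^exponent spectral slope of the background.
#' @param line_amp Amplitude of the 50 Hz line component relative to the
#'   unit-variance broadband noise.
#' @param n_channels Number of EEG channels.
#' @param channels Channel labels (defaults to the occipito-parietal set).
#' @param seed Integer seed.
#' @return A list of class `"ssvep_sim_params"`.
#' @export
ssvep_sim_params <- function(freq = 6, flicker_period = 4, rate = 250,
                             harmonic_amps = c(1, 0.5), snr_db = Inf,
                             noise_exponent = 1, line_amp = 1,
                             n_channels = 8,
                             channels = c("O1", "Oz", "O2", "P3", "P7",
                                          "Pz", "P8", "P4")[seq_len(n_channels)],
                             seed = 1) {
  if (freq <= 0) stop("freq must be positive")
  if (length(harmonic_amps) < 1) stop("need at least one harmonic amplitude")
  if (freq * length(harmonic_amps) >= rate / 2) {
    stop("harmonic at or above Nyquist")
  }
  structure(as.list(environment()), class = "ssvep_sim_params")
}

#' Colored-noise series: 1/f^exponent background plus 50 Hz line
#'
#' White Gaussian noise is spectrally shaped by `f^(-exponent/2)` in the
#' frequency domain, standardized to zero mean and unit variance, then a
#' 50 Hz sinusoid of amplitude `line_amp` is added. Deterministic given
#' the seed.
#'
#' @param n_samples Length (>= 2).
#' @param rate Sampling rate, Hz.
#' @param exponent Spectral exponent in \[0, 2\] (0 = white, 1 = pink).
#' @param line_amp 50 Hz line amplitude.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
make_colored_noise <- function(n_samples, rate, exponent = 1, line_amp = 0,
                               seed = 1) {
  if (n_samples < 2) stop("need at least 2 samples")
  if (exponent < 0 || exponent > 2) stop("exponent must be in [0, 2]")
  withr::with_seed(seed, {
    w <- stats::rnorm(n_samples)
    W <- stats::fft(w)
    k <- seq_len(n_samples) - 1
    f <- pmin(k, n_samples - k) * rate / n_samples
    H <- ifelse(f == 0, 0, f^(-exponent / 2))
    x <- Re(stats::fft(W * H, inverse = TRUE)) / n_samples
    x <- (x - mean(x)) / stats::sd(x)
    t <- (seq_len(n_samples) - 1) / rate
    x + line_amp * sin(2 * pi * 50 * t)
  })
}

#' Simulate one SSVEP trial with known ground truth
#'
#' The cortical response is a sum of harmonics of the stimulus frequency
#' with a common random phase, mixed across channels by a random weight
#' vector; 1/f-plus-line noise is added per channel and scaled so the
#' in-band (1-15 Hz) SNR matches `snr_db`. Deterministic given the seed.
#'
#' @param p An [ssvep_sim_params()].
#' @return An `ssvep_trial` with `epoch` (channels in columns),
#'   `true_freq`, and `predicted_freq = NA` (run [classify_epoch()]).
#' @export
simulate_ssvep_trial <- function(p = ssvep_sim_params()) {
  n <- as.integer(round(p$flicker_period * p$rate))
  t <- (seq_len(n) - 1) / p$rate
  withr::with_seed(p$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- rowSums(vapply(seq_along(p$harmonic_amps), function(h) {
      p$harmonic_amps[h] * sin(2 * pi * h * p$freq * t + h * phase)
    }, numeric(n)))
    weights <- stats::runif(p$n_channels, 0.5, 1.5)
  })
  epoch <- outer(sig, weights)
  colnames(epoch) <- p$channels
  if (is.finite(p$snr_db)) {
    bp <- signal::butter(3, c(1, 15) / (p$rate / 2), "pass")
    sub_seed <- (abs(p$seed) %% 2000000L) * 1000L
    for (ch in seq_len(p$n_channels)) {
      noise <- make_colored_noise(n, p$rate, p$noise_exponent, p$line_amp,
                                  seed = sub_seed + ch)
      ps <- stats::var(zero_phase_filter(epoch[, ch], bp))
      pn <- stats::var(zero_phase_filter(noise, bp))
      scale <- sqrt(ps / (pn * 10^(p$snr_db / 10)))
      epoch[, ch] <- epoch[, ch] + scale * noise
    }
  }
  ssvep_trial(epoch, true_freq = p$freq, predicted_freq = NA_real_,
              correlations = NULL, rate = p$rate)
}

#' Simulate a full SSVEP speller session as a recording
#'
#' Builds one EEG stream (background noise with SSVEP responses embedded)
#' and one flicker-marker stream on a shared clock. Each trial flickers one
#' frequency for `flicker_period` seconds; the cortical response starts
#' `hardware_offset_ms + ocular_delay_ms` after the marker onset, so
#' [extract_epoch()] with the same configuration recovers aligned epochs.
#'
#' @param stim A [stimulus_set()]; one trial per frequency, repeated
#'   `n_repeats` times.
#' @param n_repeats Repetitions of the frequency sweep.
#' @param snr_db In-band SNR of the embedded responses, dB.
#' @param gap_s Quiet gap between trials, seconds.
#' @param rate Sampling rate, Hz.
#' @param cfg An [ssvep_config()] (supplies delays and channel labels).
#' @param seed Integer seed.
#' @return List with `recording` (streams `EEG`, `FlickerMarkers`) and
#'   `truth` (per-trial onset, frequency, period).
#' @export
simulate_ssvep_session <- function(stim = stimulus_set(), n_repeats = 1,
                                   snr_db = Inf, gap_s = 1, rate = 250,
                                   cfg = ssvep_config(hardware_offset_ms = 36),
                                   seed = 1) {
  freqs <- rep(stim$frequencies, n_repeats)
  period <- stim$flicker_period
  delay_s <- (cfg$hardware_offset_ms + cfg$ocular_delay_ms) / 1000
  lead <- 2
  onsets <- lead + (seq_along(freqs) - 1) * (period + gap_s)
  duration <- lead * 2 + length(freqs) * (period + gap_s)
  n <- as.integer(round(duration * rate))
  t <- (seq_len(n) - 1) / rate
  n_ch <- length(cfg$channels)
  base_seed <- (abs(seed) %% 2000000L) * 1000L
  eeg <- vapply(seq_len(n_ch), function(ch) {
    amp <- if (is.finite(snr_db)) 1 else 1e-6  # near-silent floor when noiseless
    amp * make_colored_noise(n, rate, exponent = 1, line_amp = 1,
                             seed = base_seed + ch)
  }, numeric(n))
  colnames(eeg) <- cfg$channels
  for (i in seq_along(freqs)) {
    p <- ssvep_sim_params(freq = freqs[i], flicker_period = period,
                          rate = rate, snr_db = Inf, n_channels = n_ch,
                          channels = cfg$channels, seed = seed + i)
    trial <- simulate_ssvep_trial(p)
    amp <- if (is.finite(snr_db)) 10^(snr_db / 20) else 1
    i0 <- which(t >= onsets[i] + delay_s)[1]
    idx <- i0:(i0 + nrow(trial$epoch) - 1)
    eeg[idx, ] <- eeg[idx, ] + amp * trial$epoch
  }
  markers <- numeric(n)
  for (i in seq_along(freqs)) {
    markers[t >= onsets[i] & t < onsets[i] + period] <- freqs[i]
  }
  rec <- recording(list(
    timed_stream("EEG", eeg, rate, t),
    timed_stream("FlickerMarkers",
                 matrix(markers, ncol = 1, dimnames = list(NULL, "freq_hz")),
                 rate, t)),
    metadata = list(session_id = sprintf("ssvep_seed_%d", seed),
                    simulated = TRUE))
  list(recording = rec,
       truth = data.frame(trial = seq_along(freqs), onset_s = onsets,
                          freq = freqs, period_s = period))
}
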