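#' Stimulus set for the SSVEP speller
#'
#' Flicker frequencies of the letter clusters, the number of harmonics used
#' when building sinusoidal reference signals, and the flicker period. The
#' default six frequencies sit low (4-7.4 Hz) because low-frequency flicker
#' elicits stronger responses and the set avoids conflicting harmonics.
#'
#' @param frequencies Positive, distinct flicker frequencies, Hz.
#' @param n_harmonics Harmonics per reference (>= 1). With the 1-15 Hz
#'   analysis band, 2 harmonics keep all reference content in-band
#'   (7.4 x 2 = 14.8 Hz); a warning is emitted if
#'   `max(frequencies) * n_harmonics` exceeds `band_high`.
#' @param flicker_period Seconds a cluster flickers per selection.
#' @param band_high Upper band-pass edge used for the harmonic warning, Hz.
#' @return A list of class `"stimulus_set"`.
#' @export
stimulus_set <- function(frequencies = c(4, 5, 5.5, 6, 7, 7.4),
                         n_harmonics = 2, flicker_period = 4,
                         band_high = 15) {
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (anyDuplicated(frequencies)) stop("frequencies must be distinct")
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  if (flicker_period <= 0) stop("flicker_period must be > 0")
  if (max(frequencies) * n_harmonics > band_high) {
    warning(sprintf(
      "highest harmonic (%.1f Hz) exceeds the band-pass edge (%g Hz)",
      max(frequencies) * n_harmonics, band_high))
  }
  structure(list(frequencies = sort(frequencies), n_harmonics = n_harmonics,
                 flicker_period = flicker_period),
            class = "stimulus_set")
}

#' Configuration for SSVEP epoch processing and classification
#'
#' @param notch_hz Line-noise notch center, Hz.
#' @param band Band-pass corners, Hz.
#' @param filter_order Butterworth order (applied forward-backward).
#' @param ocular_delay_ms Retina-to-visual-cortex conduction delay added
#'   when aligning epochs to stimulus onsets (default 100 ms).
#' @param hardware_offset_ms Inter-stream hardware offset from
#'   [estimate_offset()] (e.g. 36 ms), added on top of the ocular delay.
#' @param channels Occipito-parietal channel subset used for classification.
#' @param pad_s Reflection padding per side during filtering, seconds; the
#'   padding is removed afterwards so the epoch keeps its length.
#' @param notch_q Notch quality factor.
#' @param cca_ridge Trace-normalized ridge added to the CCA auto-covariance
#'   diagonals for stability on short epochs.
#' @param eeg_stream Name of the EEG stream; `NULL` auto-detects by channels.
#' @return A list of class `"ssvep_config"`.
#' @export
ssvep_config <- function(notch_hz = 50, band = c(1, 15), filter_order = 3,
                         ocular_delay_ms = 100, hardware_offset_ms = 0,
                         channels = c("O1", "Oz", "O2", "P3", "P7", "Pz",
                                      "P8", "P4"),
                         pad_s = 0.5, notch_q = 30, cca_ridge = 1e-8,
                         eeg_stream = NULL) {
  if (!(length(band) == 2 && band[1] > 0 && band[1] < band[2])) {
    stop("band must be an increasing positive pair")
  }
  if (ocular_delay_ms < 0) stop("delays must be >= 0")
  structure(list(notch_hz = notch_hz, band = band, filter_order = filter_order,
                 ocular_delay_ms = ocular_delay_ms,
                 hardware_offset_ms = hardware_offset_ms,
                 channels = channels, pad_s = pad_s, notch_q = notch_q,
                 cca_ridge = cca_ridge, eeg_stream = eeg_stream),
            class = "ssvep_config")
}

#' Preprocess an EEG epoch: notch, zero-phase band-pass, unpad
#'
#' Per channel: the epoch is extended by `pad_s` seconds of reflected
#' samples on each side, a 50 Hz notch (biquad, Q = 30) and a Butterworth
#' band-pass (1-15 Hz, order 3) are applied forward-backward, and the
#' padding is removed so the output length equals the input length. The
#' zero-phase chain leaves symmetric landmarks in place.
#'
#' @param epoch Numeric matrix (`n_samples x n_channels`) or vector.
#' @param rate Sampling rate, Hz.
#' @param cfg An [ssvep_config()].
#' @return Filtered epoch, same dimensions as the input.
#' @export
preprocess_epoch <- function(epoch, rate, cfg = ssvep_config()) {
  vec_in <- !is.matrix(epoch)
  if (vec_in) epoch <- matrix(epoch, ncol = 1)
  if (any(cfg$band >= rate / 2)) stop("band must lie inside (0, rate/2)")
  pad <- as.integer(round(cfg$pad_s * rate))
  if (nrow(epoch) <= 2 * pad) stop("epoch shorter than padding")
  notch <- design_notch(cfg$notch_hz, rate, cfg$notch_q)
  notch_filt <- signal::Arma(b = notch$b, a = notch$a)
  bp <- signal::butter(cfg$filter_order, cfg$band / (rate / 2), type = "pass")
  out <- apply(epoch, 2, function(x) {
    y <- zero_phase_filter(x, notch_filt, pad = pad)
    zero_phase_filter(y, bp, pad = pad)
  })
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(epoch))
  colnames(out) <- colnames(epoch)
  if (vec_in) out[, 1] else out
}

#' Sinusoidal reference matrix for one stimulus frequency
#'
#' Standard CCA-SSVEP references: paired sine and cosine columns at the
#' stimulus frequency and its harmonics, with phase zero at flicker onset
#' (t = 0 at the first sample). Over whole stimulus cycles every column has
#' zero mean.
#'
#' @param freq Stimulus frequency, Hz.
#' @param rate Sampling rate, Hz.
#' @param n_samples Epoch length in samples; at least one stimulus cycle.
#' @param n_harmonics Number of harmonics (columns = `2 * n_harmonics`).
#' @return Matrix `n_samples x 2 * n_harmonics`, columns
#'   `sin_h1, cos_h1, sin_h2, ...`.
#' @export
make_reference <- function(freq, rate, n_samples, n_harmonics = 2) {
  if (freq <= 0) stop("freq must be positive")
  if (n_harmonics * freq >= rate / 2) stop("harmonic at or above Nyquist")
  if (n_samples < rate / freq) stop("epoch shorter than one stimulus cycle")
  t <- (seq_len(n_samples) - 1) / rate
  cols <- lapply(seq_len(n_harmonics), function(h) {
    cbind(sin(2 * pi * h * freq * t), cos(2 * pi * h * freq * t))
  })
  ref <- do.call(cbind, cols)
  colnames(ref) <- as.vector(vapply(seq_len(n_harmonics), function(h) {
    c(sprintf("sin_h%d", h), sprintf("cos_h%d", h))
  }, character(2)))
  ref
}

#' Largest canonical correlation between two multichannel signals
#'
#' Canonical correlation analysis finds the linear combinations of the
#' columns of `X` and of `Y` that correlate maximally; the largest
#' canonical correlation is the SSVEP decision statistic. Computed from the
#' centered covariance blocks via Cholesky whitening and an SVD, with a
#' small trace-normalized ridge on the auto-covariance diagonals for
#' stability on short epochs. The ridge is a rescue: it is only engaged
#' (and escalated) when the covariance blocks are numerically
#' rank-deficient, so well-conditioned problems keep CCA's exact
#' invariance under invertible linear mixing of either side's columns; for
#' single columns the statistic reduces to the absolute Pearson
#' correlation.
#'
#' @param X,Y Numeric matrices with equal row counts, rows >= columns + 2.
#' @param ridge Relative rescue ridge (fraction of the mean diagonal).
#' @return The largest canonical correlation, in \[0, 1\].
#' @export
cca_max_corr <- function(X, Y, ridge = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("row-count mismatch")
  n <- nrow(X)
  if (n < max(ncol(X), ncol(Y)) + 2) stop("too few rows for CCA")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  dx <- mean(diag(Sxx)); dy <- mean(diag(Syy))
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0) {
    stop("degenerate covariance")
  }
  safe_chol <- function(S) {
    if (rcond(S) < 1e-10) return(NULL)
    tryCatch(chol(S), error = function(e) NULL)
  }
  Rx <- Ry <- NULL
  for (eps in c(0, ridge, ridge * 1e2, ridge * 1e4)) {
    Sxx_r <- Sxx; Syy_r <- Syy
    diag(Sxx_r) <- diag(Sxx_r) + eps * dx
    diag(Syy_r) <- diag(Syy_r) + eps * dy
    Rx <- safe_chol(Sxx_r)
    Ry <- safe_chol(Syy_r)
    if (!is.null(Rx) && !is.null(Ry)) break
  }
  if (is.null(Rx) || is.null(Ry)) stop("degenerate covariance")
  # K = Rx^{-T} Sxy Ry^{-1}; singular values of K are the canonical corrs
  A <- forwardsolve(t(Rx), Sxy)
  K <- t(forwardsolve(t(Ry), t(A)))
  rho <- svd(K, nu = 0, nv = 0)$d[1]
  min(1, max(0, rho))
}

ssvep_trial <- function(epoch, true_freq, predicted_freq, correlations,
                        rate = NULL) {
  structure(list(epoch = epoch, true_freq = true_freq,
                 predicted_freq = predicted_freq,
                 correlations = correlations, rate = rate),
            class = "ssvep_trial")
}

#' @export
print.ssvep_trial <- function(x, ...) {
  cat(sprintf("<ssvep_trial> predicted %.1f Hz (true: %s)\n",
              x$predicted_freq,
              if (is.na(x$true_freq)) "unknown" else sprintf("%.1f Hz", x$true_freq)))
  print(round(x$correlations, 3))
  invisible(x)
}

#' Classify an EEG epoch by maximal canonical correlation
#'
#' Builds the sinusoidal reference for every stimulus frequency and
#' predicts the frequency whose reference attains the largest canonical
#' correlation with the epoch. Ties break toward the lower frequency.
#'
#' @param epoch Preprocessed EEG matrix (`n_samples x n_channels`); set
#'   `preprocess = TRUE` to run [preprocess_epoch()] first.
#' @param rate Sampling rate, Hz.
#' @param stim A [stimulus_set()].
#' @param cfg An [ssvep_config()].
#' @param true_freq Ground-truth frequency, if known (for scoring).
#' @param preprocess Apply [preprocess_epoch()] before classification.
#' @return An `ssvep_trial`: `predicted_freq`, per-frequency
#'   `correlations`, `true_freq`, `epoch`.
#' @export
classify_epoch <- function(epoch, rate, stim = stimulus_set(),
                           cfg = ssvep_config(), true_freq = NA,
                           preprocess = FALSE) {
  if (!is.matrix(epoch)) epoch <- matrix(epoch, ncol = 1)
  if (preprocess) epoch <- preprocess_epoch(epoch, rate, cfg)
  corrs <- vapply(stim$frequencies, function(f) {
    ref <- make_reference(f, rate, nrow(epoch), stim$n_harmonics)
    cca_max_corr(epoch, ref, ridge = cfg$cca_ridge)
  }, numeric(1))
  names(corrs) <- sprintf("%g", stim$frequencies)
  # frequencies are sorted ascending; which.max takes the first maximum,
  # so ties already resolve toward the lower frequency
  predicted <- stim$frequencies[which.max(corrs)]
  ssvep_trial(epoch, true_freq, predicted, corrs, rate)
}

#' Extract an EEG epoch aligned to a flicker onset
#'
#' The epoch window starts at
#' `flicker_onset + (hardware_offset_ms + ocular_delay_ms) / 1000`: signals
#' are aligned on their arrival at the visual cortex, not on when the
#' stimulus software displayed the flicker. With the measured 36 ms
#' hardware offset and the 100 ms ocular delay, an onset at 10.000 s yields
#' an epoch starting at 10.136 s.
#'
#' @param rec A [recording()] with an EEG stream.
#' @param flicker_onset Onset time on the stimulus clock, seconds.
#' @param period Flicker period, seconds; epoch length is
#'   `round(period * rate)` samples.
#' @param cfg An [ssvep_config()]; supplies delays and the channel subset.
#' @return Numeric matrix (`round(period * rate) x length(cfg$channels)`)
#'   with attributes `rate` and `start_time`.
#' @export
extract_epoch <- function(rec, flicker_onset, period, cfg = ssvep_config()) {
  eeg <- find_stream(rec, cfg$eeg_stream, channels = cfg$channels)
  miss <- setdiff(cfg$channels, eeg$channel_labels)
  if (length(miss)) stop(sprintf("missing channel '%s'", miss[1]))
  rate <- eeg$nominal_rate
  start <- flicker_onset + (cfg$hardware_offset_ms + cfg$ocular_delay_ms) / 1000
  i0 <- which(eeg$timestamps >= start)[1]
  len <- as.integer(round(period * rate))
  if (is.na(i0) || i0 + len - 1 > nrow(eeg$samples)) stop("epoch out of bounds")
  epoch <- eeg$samples[i0:(i0 + len - 1), cfg$channels, drop = FALSE]
  attr(epoch, "rate") <- rate
  attr(epoch, "start_time") <- eeg$timestamps[i0]
  epoch
}

#' Information transfer rate (Wolpaw), bits per minute
#'
#' Bits per selection
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`
#' (with the `P = 1` limit `log2 N`), scaled by `60 / T` selections per
#' minute. Zero at chance accuracy `P = 1/N`; undefined below chance.
#'
#' @param P Accuracy fraction, in `[1/N, 1]`.
#' @param N Number of selectable targets (>= 2).
#' @param T_s Seconds per selection.
#' @return ITR in bits per minute.
#' @export
itr_bpm <- function(P, N = 30, T_s) {
  if (N < 2) stop("N must be >= 2")
  if (T_s <= 0) stop("selection time must be > 0")
  if (P > 1) stop("accuracy cannot exceed 1")
  if (P < 1 / N - 1e-12) stop("below chance; ITR undefined here")
  B <- if (P >= 1) {
    log2(N)
  } else {
    log2(N) + P * log2(P) + (1 - P) * log2((1 - P) / (N - 1))
  }
  max(B, 0) * 60 / T_s
}

#' Score a classified SSVEP session
#'
#' Accuracy is the fraction of trials whose predicted frequency equals the
#' true one; the ITR uses the Wolpaw formula with a configurable target
#' count and selection time. Below-chance sessions score 0 bits/min.
#'
#' @param trials List of `ssvep_trial` objects with known `true_freq`.
#' @param stim A [stimulus_set()] (defines the flicker period default).
#' @param selection_time Seconds per selection; defaults to the stimulus
#'   set's flicker period.
#' @param n_targets Selectable targets `N` for the ITR (default 30: the
#'   full letter set reachable via gaze pre-selection of clusters).
#' @return A list of class `"session_score"`: `accuracy`, `itr_bpm`,
#'   `n_trials`, `flicker_period`.
#' @export
score_session <- function(trials, stim = stimulus_set(),
                          selection_time = NULL, n_targets = 30) {
  if (length(trials) == 0) stop("no trials to score")
  truth <- vapply(trials, function(tr) tr$true_freq, numeric(1))
  if (any(is.na(truth))) stop("every trial needs a known true_freq")
  pred <- vapply(trials, function(tr) tr$predicted_freq, numeric(1))
  if (is.null(selection_time)) selection_time <- stim$flicker_period
  accuracy <- mean(pred == truth)
  itr <- if (accuracy < 1 / n_targets) 0 else {
    itr_bpm(accuracy, n_targets, selection_time)
  }
  structure(list(accuracy = accuracy, itr_bpm = itr,
                 n_trials = length(trials),
                 flicker_period = selection_time),
            class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf("<session_score> accuracy %.1f%% over %d trials, ITR %.2f bits/min (T = %g s)\n",
              100 * x$accuracy, x$n_trials, x$itr_bpm, x$flicker_period))
  invisible(x)
}
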