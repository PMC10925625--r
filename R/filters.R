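#' Zero-phase filtering with reflected edge padding
#'
#' Forward-backward application of an IIR filter after odd (point-reflected)
#' extension of the signal at both ends, which suppresses the start-up
#' transients a plain forward-backward pass leaves at the edges. The net
#' phase response is zero, so symmetric landmarks (pulse peaks) do not move.
#'
#' @param x Numeric vector.
#' @param filt A filter object from [signal::butter()] (or anything
#'   [signal::filtfilt()] accepts), or a list with `b`/`a` coefficients.
#' @param pad Number of reflected samples per side; capped at `length(x) - 1`.
#' @return Filtered vector, same length as `x`.
#' @keywords internal
zero_phase_filter <- function(x, filt, pad = NULL) {
  n <- length(x)
  if (any(!is.finite(x))) stop("non-finite sample")
  if (is.null(pad)) {
    nf <- max(length(filt$b), length(filt$a))
    pad <- max(3L * (nf - 1L), 100L)
  }
  pad <- min(as.integer(pad), n - 1L)
  if (pad > 0) {
    head_ext <- 2 * x[1] - x[(pad + 1):2]
    tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
    ext <- c(head_ext, x, tail_ext)
  } else {
    ext <- x
  }
  y <- signal::filtfilt(filt, ext)
  y[(pad + 1):(pad + n)]
}

#' Second-order IIR notch filter coefficients
#'
#' Standard audio-EQ-cookbook biquad notch: unit gain away from the center
#' frequency, a spectral zero exactly at it. Applied forward-backward the
#' phase is zero and the stop-band attenuation doubles (in dB).
#'
#' @param f0 Center frequency, Hz.
#' @param rate Sampling rate, Hz.
#' @param q Quality factor (center frequency / -3 dB bandwidth).
#' @return A list with `b` and `a` coefficient vectors (length 3).
#' @keywords internal
design_notch <- function(f0, rate, q = 30) {
  if (f0 <= 0 || f0 >= rate / 2) stop("notch frequency must be inside (0, rate/2)")
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass filter an EMG trace for blink-landmark detection
#'
#' Zero-phase Butterworth band-pass (defaults 0.75-5 Hz, order 3). The low
#' corner removes DC and drift; the high corner removes line noise and
#' muscle-spike content so the blink burst's envelope is smooth enough for a
#' reliable 90%-of-peak rising crossing. Zero phase means the landmark is
#' not displaced by filter group delay.
#'
#' @param x Numeric EMG trace.
#' @param rate Sampling rate in Hz.
#' @param cfg A [blink_sync_config()] supplying `band_low`, `band_high`,
#'   `filter_order`.
#' @return Filtered trace, same length as `x`.
#' @export
filter_emg <- function(x, rate, cfg = blink_sync_config()) {
  if (length(x) <= 3 * cfg$filter_order * 2) stop("signal too short")
  if (any(!is.finite(x))) stop("non-finite sample")
  filt <- signal::butter(cfg$filter_order,
                         c(cfg$band_low, cfg$band_high) / (rate / 2),
                         type = "pass")
  # low 0.75 Hz corner => long transients; pad with up to ~2 s of signal
  zero_phase_filter(x, filt, pad = min(length(x) - 1L, as.integer(2 * rate)))
}
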