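# FFT-based upsampling of a real series by an integer factor (zero-padded
# spectrum); exact for band-limited periodic content, used as the
# independent reconstruction oracle in resampling tests.
fft_upsample <- function(x, factor) {
  n <- length(x)
  N <- n * factor
  X <- stats::fft(x)
  Z <- complex(real = rep(0, N))
  half <- n %/% 2
  Z[1:half] <- X[1:half]
  Z[(N - half + 2):N] <- X[(half + 2):n]
  Z[half + 1] <- X[half + 1] / 2
  Z[N - half + 1] <- Conj(X[half + 1]) / 2
  Re(stats::fft(Z, inverse = TRUE)) / N * factor
}

# Minimal two-stream recording with analytic content, for I/O and replay
# tests that do not need physiology.
make_simple_recording <- function(duration = 10, rate_a = 250, rate_b = 500) {
  ta <- seq(0, duration - 1 / rate_a, by = 1 / rate_a)
  tb <- seq(0, duration - 1 / rate_b, by = 1 / rate_b)
  a <- timed_stream("alpha", cbind(x = sin(2 * pi * 2 * ta),
                                   y = cos(2 * pi * 3 * ta)), rate_a, ta)
  b <- timed_stream("beta", cbind(z = sin(2 * pi * 5 * tb)), rate_b, tb)
  recording(list(a, b), metadata = list(session_id = "fixture"))
}

# Shift every timestamp of every stream in a recording by `by` seconds.
shift_recording <- function(rec, by) {
  rec$streams <- lapply(rec$streams, function(s) {
    s$timestamps <- s$timestamps + by
    s
  })
  rec
}

# Concatenate two recordings in time (streams matched by name); the second
# recording's clock is appended after the first's.
concat_recordings <- function(r1, r2) {
  streams <- lapply(names(r1$streams), function(nm) {
    s1 <- r1$streams[[nm]]; s2 <- r2$streams[[nm]]
    gap <- 1 / s1$nominal_rate
    off <- s1$timestamps[length(s1$timestamps)] + gap - s2$timestamps[1]
    timed_stream(nm, rbind(s1$samples, s2$samples), s1$nominal_rate,
                 c(s1$timestamps, s2$timestamps + off), s1$channel_labels)
  })
  recording(streams, metadata = r1$metadata)
}
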