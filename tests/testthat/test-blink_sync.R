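test_that("blink onsets are the first samples of maximal closure runs", {
  expect_identical(find_blink_onsets(c(0, 0, 1, 1, 0, 0, 1, 0)), c(3L, 7L))
  expect_identical(find_blink_onsets(rep(0, 8)), integer(0))
  expect_identical(find_blink_onsets(c(1, 1, 0)), 1L)
  expect_error(find_blink_onsets(c(0, 0.5, 1)), "binary")
})

test_that("closure derives from openness by a strict 0.1 threshold", {
  expect_identical(closure_from_openness(c(1.0, 0.5, 0.05, 0.0, 0.3)),
                   c(0L, 0L, 1L, 1L, 0L))
  expect_identical(closure_from_openness(0.1), 0L)  # strictly "less than"
  expect_identical(closure_from_openness(rep(1, 5)), rep(0L, 5))
  expect_error(closure_from_openness(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("EMG landmark is the rising crossing of the peak fraction", {
  # triangle rising 0..1 over 50 samples after the window start: value at
  # sample i (1-based) is (i - 1) / 50, so 0.9 is first reached at i = 46
  # and the maximum sits at i = 51
  tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1])
  expect_identical(emg_peak_index(tri, 0.9), 46L)
  expect_identical(emg_peak_index(tri, 1.0), 51L)
  expect_error(emg_peak_index(rep(0, 100)), "no EMG peak")
  expect_error(emg_peak_index(-tri), "no EMG peak")
})

test_that("index differences convert to milliseconds at the analysis rate", {
  expect_equal(offset_ms_from_indices(30, 39, 250), 36)
  expect_equal(offset_ms_from_indices(30, 30, 250), 0)
  expect_equal(offset_ms_from_indices(30, 21, 250), -36)
  # swapping the roles of the two streams negates the offset exactly
  for (seed in 1:10) {
    set.seed(seed)
    i <- sample(500, 2)
    expect_identical(offset_ms_from_indices(i[1], i[2], 250),
                     -offset_ms_from_indices(i[2], i[1], 250))
  }
})

test_that("a single blink's offset comes from the two landmark indices", {
  eye <- numeric(250); eye[31:55] <- 1
  emg <- numeric(250)
  emg[20:60] <- 1 - abs(seq(-1, 1, length.out = 41))  # symmetric peak at 40
  peak <- emg_peak_index(emg, 0.9)
  ev <- single_blink_offset(eye, emg, emg_filtered = TRUE)
  expect_true(ev$valid)
  expect_equal(ev$eye_onset_index, 31L)
  expect_equal(ev$offset_ms, (peak - 31) * 1000 / 250)

  expect_error(single_blink_offset(numeric(250), emg, emg_filtered = TRUE),
               "no closure found")
})

test_that("blinks touching the window edge are marked truncated", {
  emg <- numeric(250)
  emg[100:140] <- 1 - abs(seq(-1, 1, length.out = 41))
  eye_start <- c(rep(1, 10), numeric(240))
  ev <- single_blink_offset(eye_start, emg, emg_filtered = TRUE)
  expect_false(ev$valid)
  expect_identical(ev$exclusion_reason, "truncated")
  eye_end <- c(numeric(240), rep(1, 10))
  ev2 <- single_blink_offset(eye_end, emg, emg_filtered = TRUE)
  expect_identical(ev2$exclusion_reason, "truncated")
})

test_that("double-peaked EMG windows are flagged distorted", {
  pulse <- 1 - abs(seq(-1, 1, length.out = 41))
  win <- numeric(400)
  win[50:90] <- pulse
  win[200:240] <- 0.9 * pulse  # 150 samples = 600 ms apart, both > 70% max
  expect_true(is_distorted_emg(win, 250))
  clean <- numeric(400); clean[180:220] <- pulse
  expect_false(is_distorted_emg(clean, 250))
  # rule (b): no burst above the channel background
  expect_true(is_distorted_emg(clean * 0.01, 250, channel_mad = 0.02))

  eye <- numeric(400); eye[60:80] <- 1
  ev <- single_blink_offset(eye, win, emg_filtered = TRUE)
  expect_false(ev$valid)
  expect_identical(ev$exclusion_reason, "distorted_emg")
})

test_that("aggregation computes mean and jitter and applies one 3-sigma pass", {
  ev3 <- do.call(rbind, lapply(1:3, function(i) {
    single_blink_offset(c(numeric(30), rep(1, 20), numeric(200)),
                        {e <- numeric(250); e[20:60] <- 1 - abs(seq(-1, 1, length.out = 41)); e},
                        emg_filtered = TRUE)
  }))
  est <- aggregate_offsets(ev3)
  expect_equal(est$std_ms, 0)
  expect_equal(est$n_used, 3)
  expect_equal(est$n_excluded, 0)

  # hand-checked outlier rule: offsets = 20 x 36 ms plus one at 500 ms.
  # mean = 58.10, sd = 101.25, 3 sd = 303.76 < |500 - 58.10| = 441.90,
  # so only the 500 ms event is excluded and the retained mean is 36.
  ev <- data.frame(eye_onset_index = 1L, emg_peak_index = 1L,
                   offset_ms = c(rep(36, 20), 500),
                   valid = TRUE, exclusion_reason = "none")
  est2 <- aggregate_offsets(ev)
  expect_equal(est2$mean_offset_ms, 36)
  expect_equal(est2$n_used, 20)
  expect_equal(est2$n_excluded, 1)
  expect_identical(est2$events$exclusion_reason[21], "outlier")

  expect_error(aggregate_offsets(ev[1, ]), "insufficient blinks")
})

test_that("the outlier pass never increases the jitter of the retained set", {
  for (seed in 1:20) {
    set.seed(seed)
    off <- rnorm(30, 36, 3)
    if (seed %% 2 == 0) off[1] <- off[1] + sample(c(-1, 1), 1) * 60
    ev <- data.frame(eye_onset_index = 1L, emg_peak_index = 1L,
                     offset_ms = off, valid = TRUE, exclusion_reason = "none")
    est <- aggregate_offsets(ev)
    expect_lte(est$std_ms, sd(off) + 1e-12)
  }
})

test_that("the full pipeline recovers injected offsets within one device sample", {
  sim <- simulate_blink_recording(
    blink_sim_params(n_blinks = 20, true_offset_ms = 36, jitter_sd_ms = 0,
                     seed = 7))
  est <- estimate_offset(sim$recording)
  expect_lte(abs(est$mean_offset_ms - 36), index_granularity_ms(120))

  sim0 <- simulate_blink_recording(
    blink_sim_params(n_blinks = 20, true_offset_ms = 0, seed = 8))
  est0 <- estimate_offset(sim0$recording)
  expect_lte(abs(est0$mean_offset_ms), index_granularity_ms(120))
})

test_that("a recording without blinks reports that no closure was found", {
  ts_e <- seq(0, 4, by = 1 / 250)
  eye <- timed_stream("EyeTracking",
                      cbind(left_closed = 0 * ts_e, right_closed = 0 * ts_e,
                            both_blinking = 0 * ts_e,
                            left_openness = 1 + 0 * ts_e,
                            right_openness = 1 + 0 * ts_e), 250, ts_e)
  ts_m <- seq(0, 4, by = 1 / 500)
  emg <- timed_stream("EMG", matrix(rnorm(length(ts_m), 0, 0.01), ncol = 1,
                                    dimnames = list(NULL, "EMG")), 500, ts_m)
  expect_error(estimate_offset(recording(list(eye, emg))), "no closure found")
})

test_that("delaying the EMG stream shifts the mean offset by the sample period", {
  sim <- simulate_blink_recording(
    blink_sim_params(n_blinks = 15, true_offset_ms = 36, seed = 21))
  base <- estimate_offset(sim$recording)
  k <- 4L  # samples at 500 Hz = 2 samples at the 250 Hz analysis rate
  shifted <- sim$recording
  x <- shifted$streams$EMG$samples[, 1]
  shifted$streams$EMG$samples[, 1] <- c(rep(x[1], k), x[1:(length(x) - k)])
  est <- estimate_offset(shifted)
  expect_equal(est$mean_offset_ms - base$mean_offset_ms, k / 500 * 1000,
               tolerance = 1e-8)
})

test_that("trimming strategy selection minimizes pooled jitter", {
  # clean single recording: every strategy gives the same events, so the
  # first listed strategy wins the tie
  sim <- simulate_blink_recording(blink_sim_params(n_blinks = 12, seed = 31))
  sel <- select_trimming(sim$recording, cfg = blink_sync_config())
  expect_identical(sel$strategy, "none")
  expect_lte(diff(range(sel$pooled_std)), 1e-9)

  expect_error(select_trimming(sim$recording, strategies = character(0)),
               "empty strategy list")
})

test_that("a corrupted head segment makes the head-trim strategy win", {
  bad <- simulate_blink_recording(
    blink_sim_params(n_blinks = 5, true_offset_ms = 150, seed = 41,
                     lead_in_s = 1))
  good <- simulate_blink_recording(
    blink_sim_params(n_blinks = 12, true_offset_ms = 36, seed = 42,
                     lead_in_s = 1))
  long_rec <- concat_recordings(bad$recording, good$recording)
  clean <- simulate_blink_recording(
    blink_sim_params(n_blinks = 12, true_offset_ms = 36, seed = 43,
                     lead_in_s = 1))
  sel <- select_trimming(list(long_rec, clean$recording))
  expect_identical(sel$strategy, "head")
  expect_lt(sel$pooled_std[["head"]], sel$pooled_std[["none"]])
  expect_lte(abs(sel$estimate$mean_offset_ms - 36), index_granularity_ms(120))
})
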