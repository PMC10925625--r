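test_that("epoch preprocessing notches 50 Hz, passes 6 Hz, and keeps length", {
  rate <- 250
  t <- (0:999) / rate
  y50 <- preprocess_epoch(sin(2 * pi * 50 * t), rate)
  expect_lt(max(abs(y50[400:600])), 0.03)
  y6 <- preprocess_epoch(sin(2 * pi * 6 * t), rate)
  expect_gt(max(abs(y6[400:600])), 0.95)
  expect_lt(max(abs(y6[400:600])), 1.05)
  expect_length(y50, 1000)

  z <- preprocess_epoch(matrix(0, 600, 3), rate)
  expect_identical(dim(z), c(600L, 3L))
  expect_true(all(z == 0))
  expect_error(preprocess_epoch(matrix(rnorm(100), 50, 2), rate),
               "epoch shorter than padding")
})

test_that("re-applying preprocessing barely changes in-band content", {
  rate <- 250
  t <- (0:1499) / rate
  x <- sin(2 * pi * 6 * t) + 0.4 * sin(2 * pi * 7.4 * t)
  once <- preprocess_epoch(x, rate)
  twice <- preprocess_epoch(once, rate)
  mid <- 300:1200
  rel <- sqrt(mean((twice[mid] - once[mid])^2)) / sqrt(mean(once[mid]^2))
  expect_lt(rel, 0.01)
})

test_that("preprocessing is zero-phase: a symmetric pulse peak stays put", {
  x <- numeric(1500)
  x[601:801] <- 1 - abs(seq(-1, 1, length.out = 201))  # peak at 701
  y <- preprocess_epoch(x, 250)
  expect_lte(abs(which.max(y) - 701), 1)
})

test_that("reference matrices hold sin/cos harmonics with zero cycle means", {
  ref <- make_reference(6, 250, 1000, n_harmonics = 2)
  expect_identical(dim(ref), c(1000L, 4L))
  expect_identical(colnames(ref), c("sin_h1", "cos_h1", "sin_h2", "cos_h2"))
  # column content sits at 6 and 12 Hz: project onto analytic sinusoids
  t <- (0:999) / 250
  expect_gt(abs(stats::cor(ref[, "sin_h1"], sin(2 * pi * 6 * t))), 0.999)
  expect_gt(abs(stats::cor(ref[, "cos_h2"], cos(2 * pi * 12 * t))), 0.999)
  # phase zero at onset
  expect_equal(unname(ref[1, "sin_h1"]), 0)
  expect_equal(unname(ref[1, "cos_h1"]), 1)

  one_cycle <- make_reference(5, 250, 50, n_harmonics = 2)  # exactly 1 period
  expect_lt(max(abs(colMeans(one_cycle))), 1e-10)

  expect_silent(make_reference(7.4, 250, 1000, 2))  # 14.8 < 125
  expect_error(make_reference(70, 250, 1000, 2), "Nyquist")
  expect_error(make_reference(6, 250, 20, 2), "one stimulus cycle")
})

test_that("canonical correlation matches its closed-form and library oracles", {
  set.seed(11)
  x <- rnorm(300)
  expect_equal(cca_max_corr(matrix(x), matrix(2 * x + 1)), 1,
               tolerance = 1e-8)
  # multi-column case against the reference implementation
  X <- matrix(rnorm(900), 300)
  Y <- X %*% matrix(rnorm(12), 3) + matrix(rnorm(1200), 300)
  expect_equal(cca_max_corr(X, Y), max(stats::cancor(X, Y)$cor),
               tolerance = 1e-7)
  # orthogonal sinusoids over whole cycles decorrelate
  t <- (0:999) / 250
  A <- cbind(sin(2 * pi * 5 * t), cos(2 * pi * 5 * t))
  B <- cbind(sin(2 * pi * 20 * t), cos(2 * pi * 20 * t))
  expect_lt(cca_max_corr(A, B), 0.05)

  expect_error(cca_max_corr(matrix(rnorm(10)), matrix(rnorm(12))),
               "row-count mismatch")
  expect_error(cca_max_corr(matrix(1, 50, 2), matrix(rnorm(50))),
               "degenerate covariance")
})

test_that("canonical correlation is invariant to channel mixing", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- simulate_ssvep_trial(ssvep_sim_params(freq = 6, snr_db = 0,
                                                seed = seed))
    ref <- make_reference(6, 250, nrow(tr$epoch), 2)
    rho <- cca_max_corr(tr$epoch, ref)
    M <- matrix(rnorm(64), 8)
    while (abs(det(M)) < 1e-3) M <- matrix(rnorm(64), 8)
    expect_equal(cca_max_corr(tr$epoch %*% M, ref), rho, tolerance = 1e-6)
  }
})

test_that("noiseless epochs classify to their true frequency at every stimulus", {
  stim <- stimulus_set()
  for (f in stim$frequencies) {
    tr <- simulate_ssvep_trial(ssvep_sim_params(freq = f, flicker_period = 4,
                                                seed = 100 + round(10 * f)))
    cl <- classify_epoch(tr$epoch, 250, stim, preprocess = TRUE,
                         true_freq = f)
    expect_identical(cl$predicted_freq, f)
    expect_true(all(cl$correlations >= 0 & cl$correlations <= 1))
  }
})

test_that("classification of noise is deterministic and reports correlations", {
  set.seed(5)
  noise <- matrix(rnorm(8000), 1000, 8)
  stim <- stimulus_set()
  a <- classify_epoch(noise, 250, stim)
  b <- classify_epoch(noise, 250, stim)
  expect_identical(a$predicted_freq, b$predicted_freq)
  expect_identical(a$correlations, b$correlations)
  expect_true(a$predicted_freq %in% stim$frequencies)
  expect_lt(max(a$correlations), 0.5)
})

test_that("accuracy degrades monotonically as SNR falls", {
  stim <- stimulus_set(flicker_period = 2)
  levels <- c(10, 0, -10, -20)
  acc <- vapply(seq_along(levels), function(li) {
    hits <- vapply(1:200, function(i) {
      f <- stim$frequencies[1 + (i %% 6)]
      tr <- simulate_ssvep_trial(ssvep_sim_params(
        freq = f, flicker_period = 2, snr_db = levels[li],
        seed = li * 1000 + i))
      cl <- classify_epoch(tr$epoch, 250, stim, preprocess = TRUE)
      cl$predicted_freq == f
    }, logical(1))
    mean(hits)
  }, numeric(1))
  # non-increasing within 5-percentage-point sampling slack
  expect_true(all(diff(acc) <= 0.05))
  expect_gt(acc[1], acc[4])
})

test_that("longer flicker periods widen noiseless correlation margins on average", {
  # the margin (top correlation minus runner-up) fluctuates with the
  # fractional number of competitor cycles an epoch truncates, so the
  # comparison is made on the frequency-averaged trend, longest vs
  # shortest period
  stim <- stimulus_set()
  margin_at <- function(per) {
    mean(vapply(stim$frequencies, function(f) {
      tr <- simulate_ssvep_trial(ssvep_sim_params(
        freq = f, flicker_period = per, seed = 300 + round(10 * f) + per))
      cl <- classify_epoch(tr$epoch, 250, stim, preprocess = TRUE)
      sorted <- sort(cl$correlations, decreasing = TRUE)
      sorted[1] - sorted[2]
    }, numeric(1)))
  }
  m2 <- margin_at(2); m6 <- margin_at(6)
  expect_gte(m6, m2)
  expect_gt(m2, 0.5)  # decisively separable even at the shortest period
})

test_that("epochs align to flicker onset plus hardware and ocular delays", {
  n <- 250 * 20
  t <- (0:(n - 1)) / 250
  chans <- c("O1", "Oz", "O2", "P3", "P7", "Pz", "P8", "P4")
  eeg <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, chans))
  rec <- recording(list(timed_stream("EEG", eeg, 250, t)))

  cfg <- ssvep_config(hardware_offset_ms = 36, ocular_delay_ms = 100)
  ep <- extract_epoch(rec, 10.000, 2, cfg)
  expect_equal(attr(ep, "start_time"), 10.136)
  expect_identical(dim(ep), c(500L, 8L))

  cfg0 <- ssvep_config(hardware_offset_ms = 0, ocular_delay_ms = 0)
  ep0 <- extract_epoch(rec, 4.0, 2, cfg0)
  expect_equal(attr(ep0, "start_time"), 4.0)

  expect_error(extract_epoch(rec, 19.5, 2, cfg0), "epoch out of bounds")
  bad_cfg <- ssvep_config(channels = c("O1", "Cz"))
  expect_error(extract_epoch(rec, 4, 2, bad_cfg), "missing channel 'Cz'")
})

test_that("information transfer rate follows the Wolpaw closed form", {
  expect_equal(itr_bpm(1, 2, 60), 1.0)
  expect_equal(itr_bpm(0.25, 4, 7), 0)     # chance level
  expect_equal(itr_bpm(1 / 30, 30, 3), 0)
  # hand evaluation: B = 2 + 0.5 log2 0.5 + 0.5 log2(0.5/3) = 0.20752,
  # ITR = B * 60 / 4 = 3.1128 bits/min
  expect_equal(itr_bpm(0.5, 4, 4), 3.112781, tolerance = 1e-6)
  expect_error(itr_bpm(0.1, 4, 4), "below chance")
})

test_that("session scoring aggregates accuracy and ITR over trials", {
  mk <- function(true, pred) ssvep_trial(NULL, true, pred, NULL)
  stim <- stimulus_set(flicker_period = 4)
  all_ok <- lapply(rep(6, 10), function(f) mk(f, f))
  s1 <- score_session(all_ok, stim, n_targets = 30)
  expect_equal(s1$accuracy, 1)
  expect_equal(s1$itr_bpm, log2(30) * 60 / 4)

  alternating <- lapply(1:10, function(i) mk(6, if (i %% 2) 6 else 5))
  s2 <- score_session(alternating, stim)
  expect_equal(s2$accuracy, 0.5)

  expect_error(score_session(list(), stim), "no trials")
})

test_that("stimulus sets warn when harmonics leave the analysis band", {
  expect_warning(stimulus_set(frequencies = c(6, 9), n_harmonics = 2),
                 "band-pass edge")
  expect_silent(stimulus_set())
})
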