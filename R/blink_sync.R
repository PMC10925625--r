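#' Configuration for blink-based offset estimation
#'
#' Bundles the tunable parameters of the blink synchronization estimator.
#' Defaults follow the method's reference settings: a 0.75-5 Hz 3rd-order
#' zero-phase Butterworth band-pass on the EMG, the 90%-of-peak rising
#' crossing as the EMG landmark, the 0.1 openness threshold defining eye
#' closure, a single 3-sigma outlier pass, and 0.5 s (125 samples at the
#' 250 Hz analysis rate) of padding around each blink window.
#'
#' @param band_low,band_high EMG band-pass corners, Hz.
#' @param filter_order Butterworth order (applied forward-backward).
#' @param peak_fraction Fraction of the window maximum defining the EMG
#'   landmark crossing, in (0, 1].
#' @param closure_threshold Openness value below which an eye counts as
#'   closed.
#' @param outlier_k Exclusion threshold in multiples of the STD.
#' @param padding Samples of padding added on each side of a blink window,
#'   at `analysis_rate`.
#' @param analysis_rate Common analysis rate in Hz; both streams are
#'   compared at this rate.
#' @param eye_device_rate Native granularity of the eye tracker, Hz; one
#'   device sample (8.33 ms at 120 Hz) is the method's resolution floor.
#' @param distortion_peak_frac,distortion_sep_ms A blink window is flagged
#'   `distorted_emg` when two or more peaks above `distortion_peak_frac`
#'   of the window maximum are separated by more than `distortion_sep_ms`.
#' @param distortion_floor Windows whose maximum is below
#'   `distortion_floor` times the filtered channel's median absolute
#'   amplitude are also flagged `distorted_emg`.
#' @param emg_channel Label of the EMG channel.
#' @param emg_stream,eye_stream Stream names; `NULL` auto-detects by
#'   channel labels.
#' @param dejitter_method Passed to [dejitter_timestamps()].
#' @return A list of class `"blink_sync_config"`.
#' @export
blink_sync_config <- function(band_low = 0.75, band_high = 5,
                              filter_order = 3, peak_fraction = 0.9,
                              closure_threshold = 0.1, outlier_k = 3,
                              padding = 125, analysis_rate = 250,
                              eye_device_rate = 120,
                              distortion_peak_frac = 0.7,
                              distortion_sep_ms = 200,
                              distortion_floor = 5,
                              emg_channel = "EMG",
                              emg_stream = NULL, eye_stream = NULL,
                              dejitter_method = "ols") {
  if (!(band_low > 0 && band_low < band_high && band_high < analysis_rate / 2)) {
    stop("need 0 < band_low < band_high < analysis_rate/2")
  }
  if (!(peak_fraction > 0 && peak_fraction <= 1)) {
    stop("peak_fraction must be in (0, 1]")
  }
  if (outlier_k <= 0) stop("outlier_k must be > 0")
  if (padding < 0) stop("padding must be >= 0")
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = filter_order, peak_fraction = peak_fraction,
                 closure_threshold = closure_threshold, outlier_k = outlier_k,
                 padding = padding, analysis_rate = analysis_rate,
                 eye_device_rate = eye_device_rate,
                 distortion_peak_frac = distortion_peak_frac,
                 distortion_sep_ms = distortion_sep_ms,
                 distortion_floor = distortion_floor,
                 emg_channel = emg_channel, emg_stream = emg_stream,
                 eye_stream = eye_stream, dejitter_method = dejitter_method),
            class = "blink_sync_config")
}

#' Index granularity of a sampling rate, in milliseconds
#'
#' One sample period: `1000 / rate`. At the eye tracker's native 120 Hz
#' this is 8.33 ms, the resolution floor of any index-based offset.
#'
#' @param rate Sampling rate, Hz.
#' @return Milliseconds per sample.
#' @export
index_granularity_ms <- function(rate) {
  if (rate <= 0) stop("rate must be positive")
  1000 / rate
}

#' Convert an index difference into a latency in milliseconds
#'
#' `offset_ms = (emg_peak_index - eye_onset_index) * 1000 / rate`. Positive
#' offsets mean the eye-tracker event precedes the EMG landmark (the eye
#' tracker is "faster"); swapping the two indices negates the offset
#' exactly. Nine samples at 250 Hz give 36 ms.
#'
#' @param eye_onset_index Sample index of eye-closure onset.
#' @param emg_peak_index Sample index of the EMG landmark.
#' @param rate Analysis rate, Hz.
#' @return Offset in milliseconds.
#' @export
offset_ms_from_indices <- function(eye_onset_index, emg_peak_index, rate) {
  (emg_peak_index - eye_onset_index) * 1000 / rate
}

#' Find blink onsets in a binary closure channel
#'
#' Returns the first index of every maximal run of 1s in the
#' `both_blinking` channel: the samples at which the tracker first reports
#' both eyes fully closed.
#'
#' @param both_blinking Binary vector ({0, 1} or logical).
#' @return Integer vector of onset indices, strictly increasing.
#' @export
find_blink_onsets <- function(both_blinking) {
  x <- as.numeric(both_blinking)
  if (length(x) == 0) return(integer(0))
  if (any(!x %in% c(0, 1))) stop("both_blinking must be binary (0/1)")
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  as.integer(starts[r$values == 1])
}

#' Derive a binary closure channel from continuous openness
#'
#' An eye counts as closed when its openness is strictly below the
#' threshold (default 0.1, the tracker API's definition).
#'
#' @param openness Numeric vector in \[0, 1\].
#' @param threshold Closure threshold.
#' @return Integer vector of 0/1.
#' @export
closure_from_openness <- function(openness, threshold = 0.1) {
  if (any(!is.finite(openness)) || any(openness < 0 | openness > 1)) {
    stop("openness values must lie in [0, 1]")
  }
  as.integer(openness < threshold)
}

#' Locate the EMG landmark: the rising crossing of 90% of the peak
#'
#' Finds the earliest index of the window's absolute maximum, then walks
#' back along the contiguous run of samples at or above
#' `peak_fraction x max` — the rising-slope crossing. Using a fractional
#' leading-edge landmark instead of the peak itself is invariant to
#' amplitude scaling and robust to plateaued peaks; with
#' `peak_fraction = 1` it reduces to the (earliest) maximum.
#'
#' @param window Filtered EMG window.
#' @param peak_fraction Fraction of the maximum, in (0, 1].
#' @return Index of the crossing sample.
#' @export
emg_peak_index <- function(window, peak_fraction = 0.9) {
  if (length(window) < 2 || diff(range(window)) == 0 || max(window) <= 0) {
    stop("no EMG peak")
  }
  p <- which.max(window)
  thr <- peak_fraction * window[p]
  i <- p
  while (i > 1 && window[i - 1] >= thr) i <- i - 1L
  i
}

local_peak_indices <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Flag a distorted EMG blink window
#'
#' A window is considered distorted when (a) it holds two or more peaks,
#' each above `distortion_peak_frac` of the window maximum, separated by
#' more than `distortion_sep_ms` — a double burst cannot yield a unique
#' blink landmark — or (b) its maximum is below `distortion_floor` times
#' the filtered channel's median absolute amplitude, i.e. no burst stands
#' out of the background at all.
#'
#' @param window Filtered EMG window.
#' @param rate Analysis rate, Hz.
#' @param cfg A [blink_sync_config()].
#' @param channel_mad Median absolute amplitude of the whole filtered EMG
#'   channel; `NULL` disables rule (b).
#' @return Logical.
#' @export
is_distorted_emg <- function(window, rate, cfg = blink_sync_config(),
                             channel_mad = NULL) {
  mx <- max(window)
  if (!is.null(channel_mad) && is.finite(channel_mad) && channel_mad > 0 &&
      mx < cfg$distortion_floor * channel_mad) {
    return(TRUE)
  }
  peaks <- local_peak_indices(window)
  peaks <- peaks[window[peaks] > cfg$distortion_peak_frac * mx]
  if (length(peaks) >= 2) {
    sep_ms <- (max(peaks) - min(peaks)) * 1000 / rate
    if (sep_ms > cfg$distortion_sep_ms) return(TRUE)
  }
  FALSE
}

blink_event <- function(eye_onset_index = NA_integer_,
                        emg_peak_index = NA_integer_,
                        offset_ms = NA_real_, valid = FALSE,
                        exclusion_reason = "none") {
  data.frame(eye_onset_index = as.integer(eye_onset_index),
             emg_peak_index = as.integer(emg_peak_index),
             offset_ms = offset_ms, valid = valid,
             exclusion_reason = exclusion_reason,
             stringsAsFactors = FALSE)
}

#' Offset of a single blink from paired eye and EMG windows
#'
#' Both windows must cover the same clock interval at the analysis rate.
#' The eye landmark is the first sample of the first closure run; the EMG
#' landmark is the 90%-of-peak rising crossing of the (filtered) burst.
#' The offset is their index difference converted to milliseconds.
#' Events are marked invalid — never silently dropped — when the closure
#' run touches the window edge (`truncated`) or the EMG burst fails the
#' distortion rules (`distorted_emg`).
#'
#' @param eye_window Binary both-blinking window.
#' @param emg_window EMG window over the same interval.
#' @param cfg A [blink_sync_config()].
#' @param emg_filtered Set `TRUE` when `emg_window` was cut from an
#'   already-filtered channel (the [estimate_offset()] pipeline filters the
#'   channel once, before windowing).
#' @param channel_mad Median absolute amplitude of the filtered channel,
#'   for distortion rule (b).
#' @return One-row data frame: `eye_onset_index`, `emg_peak_index`,
#'   `offset_ms`, `valid`, `exclusion_reason`.
#' @export
single_blink_offset <- function(eye_window, emg_window,
                                cfg = blink_sync_config(),
                                emg_filtered = FALSE, channel_mad = NULL) {
  onsets <- find_blink_onsets(eye_window)
  if (length(onsets) == 0) stop("no closure found")
  onset <- onsets[1]
  runs <- rle(as.numeric(eye_window))
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  k <- which(run_starts == onset)
  touches_edge <- onset == 1L || run_ends[k] == length(eye_window)
  fw <- if (emg_filtered) emg_window else {
    filter_emg(emg_window, cfg$analysis_rate, cfg)
  }
  peak <- tryCatch(emg_peak_index(fw, cfg$peak_fraction), error = function(e) NA)
  if (is.na(peak)) {
    return(blink_event(onset, NA, NA_real_, FALSE, "distorted_emg"))
  }
  if (touches_edge) {
    return(blink_event(onset, peak, NA_real_, FALSE, "truncated"))
  }
  if (is_distorted_emg(fw, cfg$analysis_rate, cfg, channel_mad)) {
    return(blink_event(onset, peak, NA_real_, FALSE, "distorted_emg"))
  }
  blink_event(onset, peak,
              offset_ms_from_indices(onset, peak, cfg$analysis_rate),
              TRUE, "none")
}

#' Aggregate per-blink offsets into a mean offset and jitter estimate
#'
#' Computes mean and standard deviation over the valid events, then runs a
#' single outlier pass: events farther than `outlier_k` standard deviations
#' from the mean are excluded (reason `outlier`) and the statistics are
#' recomputed over the retained set. The pass is not iterated.
#'
#' @param events Data frame of blink events ([single_blink_offset()] rows,
#'   optionally with a `recording` column for a per-recording breakdown).
#' @param cfg A [blink_sync_config()].
#' @return An object of class `"offset_estimate"`: `mean_offset_ms`,
#'   `std_ms`, `n_used`, `n_excluded`, `per_recording`, `events`.
#' @export
aggregate_offsets <- function(events, cfg = blink_sync_config()) {
  if (!"recording" %in% names(events)) events$recording <- "recording_1"
  use <- events$valid & events$exclusion_reason == "none"
  if (sum(use) < 2) stop("insufficient blinks")
  m <- mean(events$offset_ms[use])
  s <- stats::sd(events$offset_ms[use])
  if (is.finite(s) && s > 0) {
    out <- use & abs(events$offset_ms - m) > cfg$outlier_k * s
    events$exclusion_reason[out] <- "outlier"
    use <- use & !out
    if (sum(use) < 2) stop("insufficient blinks")
    m <- mean(events$offset_ms[use])
    s <- stats::sd(events$offset_ms[use])
  }
  per_rec <- do.call(rbind, lapply(split(seq_len(nrow(events)),
                                         events$recording), function(idx) {
    u <- idx[use[idx]]
    data.frame(recording = events$recording[idx[1]],
               mean_offset_ms = if (length(u)) mean(events$offset_ms[u]) else NA_real_,
               std_ms = if (length(u) > 1) stats::sd(events$offset_ms[u]) else NA_real_,
               n = length(u), stringsAsFactors = FALSE)
  }))
  rownames(per_rec) <- NULL
  structure(list(mean_offset_ms = m, std_ms = s,
                 n_used = sum(use), n_excluded = sum(!use),
                 per_recording = per_rec, events = events),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("<offset_estimate> mean %.2f ms, STD (jitter) %.2f ms\n",
              x$mean_offset_ms, x$std_ms))
  cat(sprintf("  blinks used: %d, excluded: %d\n", x$n_used, x$n_excluded))
  if (nrow(x$per_recording) > 1) {
    print(x$per_recording, row.names = FALSE)
  }
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Estimate the inter-stream offset and jitter of a recording
#'
#' Full pipeline: dejitter timestamps, bring both streams to the analysis
#' rate (integer-factor anti-aliased downsampling), derive the binary
#' closure channel (from `both_blinking`, or from the minimum of the two
#' openness channels when absent), zero-phase band-pass the whole EMG
#' channel once, cut a padded window around every closure run, compute each
#' blink's offset, and aggregate with the outlier pass. Deterministic given
#' input and configuration. Blink windows are aligned across streams by
#' nearest timestamp, so the index arithmetic compares like with like even
#' when the two sampling grids have different phases.
#'
#' @param rec A [recording()] holding an EMG stream and an eye-tracking
#'   stream on one shared clock.
#' @param cfg A [blink_sync_config()].
#' @return An [aggregate_offsets()] estimate.
#' @export
estimate_offset <- function(rec, cfg = blink_sync_config()) {
  eye <- with_stage("locate-streams", find_stream(
    rec, cfg$eye_stream,
    channels = if (is.null(cfg$eye_stream)) "both_blinking" else NULL))
  if (!"both_blinking" %in% eye$channel_labels &&
      !all(c("left_openness", "right_openness") %in% eye$channel_labels)) {
    eye <- with_stage("locate-streams", find_stream(
      rec, NULL, channels = c("left_openness", "right_openness")))
  }
  emg <- with_stage("locate-streams", find_stream(
    rec, cfg$emg_stream, channels = cfg$emg_channel))

  eye$timestamps <- with_stage("dejitter",
    dejitter_timestamps(eye$timestamps, cfg$dejitter_method))
  emg$timestamps <- with_stage("dejitter",
    dejitter_timestamps(emg$timestamps, cfg$dejitter_method))

  if (emg$nominal_rate != cfg$analysis_rate) {
    emg <- with_stage("resample", downsample(emg, cfg$analysis_rate))
  }
  if (eye$nominal_rate != cfg$analysis_rate) {
    eye <- with_stage("resample", downsample(eye, cfg$analysis_rate))
  }

  closure <- with_stage("closure-channel", {
    if ("both_blinking" %in% eye$channel_labels) {
      bb <- eye$samples[, "both_blinking"]
      if (any(!bb %in% c(0, 1))) stop("both_blinking must be binary (0/1)")
      as.integer(bb)
    } else {
      closure_from_openness(
        pmin(eye$samples[, "left_openness"], eye$samples[, "right_openness"]),
        cfg$closure_threshold)
    }
  })

  filtered <- with_stage("filter-emg",
    filter_emg(emg$samples[, cfg$emg_channel], cfg$analysis_rate, cfg))
  channel_mad <- stats::median(abs(filtered))

  onsets <- with_stage("find-onsets", find_blink_onsets(closure))
  if (length(onsets) == 0) stop("[find-onsets] no closure found", call. = FALSE)

  runs <- rle(as.numeric(closure))
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  run_end_of <- stats::setNames(run_ends[runs$values == 1],
                                run_starts[runs$values == 1])

  pad_s <- cfg$padding / cfg$analysis_rate
  n_eye <- length(eye$timestamps)
  n_emg <- length(emg$timestamps)
  events <- do.call(rbind, lapply(onsets, function(on) {
    t_on <- eye$timestamps[on]
    t_end <- eye$timestamps[run_end_of[[as.character(on)]]]
    w_lo <- t_on - pad_s
    w_hi <- t_end + pad_s
    if (w_lo < eye$timestamps[1] || w_hi > eye$timestamps[n_eye]) {
      return(blink_event(exclusion_reason = "truncated"))
    }
    i0 <- which.min(abs(eye$timestamps - w_lo))
    i1 <- which.min(abs(eye$timestamps - w_hi))
    j0 <- which.min(abs(emg$timestamps - eye$timestamps[i0]))
    j1 <- j0 + (i1 - i0)
    if (j1 > n_emg || emg$timestamps[j0] < emg$timestamps[1]) {
      return(blink_event(exclusion_reason = "truncated"))
    }
    ev <- with_stage("blink-offset", single_blink_offset(
      closure[i0:i1], filtered[j0:j1], cfg,
      emg_filtered = TRUE, channel_mad = channel_mad))
    ev$eye_onset_index <- ev$eye_onset_index + i0 - 1L
    ev$emg_peak_index <- if (is.na(ev$emg_peak_index)) NA_integer_ else
      ev$emg_peak_index + j0 - 1L
    ev
  }))
  events$recording <- if (!is.null(rec$metadata$session_id)) {
    as.character(rec$metadata$session_id)
  } else "recording_1"
  with_stage("aggregate", aggregate_offsets(events, cfg))
}

trim_recording <- function(rec, strategy, target_duration) {
  starts <- vapply(rec$streams, function(s) s$timestamps[1], numeric(1))
  ends <- vapply(rec$streams, function(s) s$timestamps[length(s$timestamps)],
                 numeric(1))
  dur <- min(ends) - max(starts)
  excess <- max(0, dur - target_duration)
  lo <- max(starts) + switch(strategy, none = 0, head = excess,
                             tail = 0, symmetric = excess / 2)
  hi <- if (strategy == "none") min(ends) else lo + target_duration
  rec$streams <- lapply(rec$streams, function(s) {
    keep <- s$timestamps >= lo & s$timestamps <= hi
    timed_stream(s$name, s$samples[keep, , drop = FALSE], s$nominal_rate,
                 s$timestamps[keep], s$channel_labels)
  })
  rec
}

#' Choose the trimming strategy minimizing pooled jitter
#'
#' Blink recordings of one session often differ in length. Each candidate
#' strategy trims every recording to the shortest common duration — keeping
#' the tail (`head` trim), the head (`tail` trim), the middle (`symmetric`),
#' or everything (`none`) — before estimation; the strategy whose pooled
#' per-blink offsets have the smallest standard deviation wins. Ties go to
#' the first-listed strategy.
#'
#' @param recordings A [recording()] or list of them.
#' @param strategies Character vector from
#'   `c("none", "head", "tail", "symmetric")`.
#' @param cfg A [blink_sync_config()].
#' @return List with `strategy` (name), `estimate` (pooled
#'   [aggregate_offsets()] result), and `pooled_std` per candidate.
#' @export
select_trimming <- function(recordings,
                            strategies = c("none", "head", "tail", "symmetric"),
                            cfg = blink_sync_config()) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  if (length(recordings) < 1) stop("need at least one recording")
  if (length(strategies) < 1) stop("empty strategy list")
  strategies <- match.arg(strategies, c("none", "head", "tail", "symmetric"),
                          several.ok = TRUE)
  target <- min(vapply(recordings, function(r) {
    starts <- vapply(r$streams, function(s) s$timestamps[1], numeric(1))
    ends <- vapply(r$streams, function(s) s$timestamps[length(s$timestamps)],
                   numeric(1))
    min(ends) - max(starts)
  }, numeric(1)))

  candidates <- lapply(strategies, function(strat) {
    events <- NULL
    for (i in seq_along(recordings)) {
      est <- tryCatch({
        trimmed <- trim_recording(recordings[[i]], strat, target)
        estimate_offset(trimmed, cfg)
      }, error = function(e) NULL)
      if (!is.null(est)) {
        ev <- est$events
        ev$recording <- sprintf("recording_%d", i)
        events <- rbind(events, ev)
      }
    }
    if (is.null(events)) return(NULL)
    tryCatch(aggregate_offsets(events, cfg), error = function(e) NULL)
  })
  names(candidates) <- strategies
  ok <- !vapply(candidates, is.null, logical(1))
  if (!any(ok)) stop("all trimming strategies failed")
  stds <- vapply(candidates, function(c) if (is.null(c)) Inf else c$std_ms,
                 numeric(1))
  best <- which.min(stds)  # ties: first listed
  list(strategy = strategies[best], estimate = candidates[[best]],
       pooled_std = stds)
}
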