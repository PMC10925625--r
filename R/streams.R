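#' Timestamped multichannel stream
#'
#' Container for one modality's samples: a label, an `n_samples x n_channels`
#' numeric matrix, a nominal sampling rate, and per-sample timestamps in
#' seconds on the session's shared clock. Raw timestamps may carry
#' transmission jitter; [dejitter_timestamps()] regularizes them onto a
#' fitted linear clock, after which they are strictly increasing.
#'
#' @param name Text label, e.g. `"EMG"` or `"EyeTracking"`.
#' @param samples Numeric matrix (`n_samples x n_channels`) or vector
#'   (treated as a single channel).
#' @param nominal_rate Nominal sampling rate in Hz, positive.
#' @param timestamps Numeric vector of per-sample times in seconds, same
#'   length as the sample count.
#' @param channel_labels Character vector of channel names; defaults to the
#'   matrix column names, or `ch1, ch2, ...`.
#' @return An object of class `"timed_stream"`.
#' @export
timed_stream <- function(name, samples, nominal_rate, timestamps,
                         channel_labels = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  storage.mode(samples) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("channel_labels length must match the number of sample columns")
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1 ||
      !is.finite(nominal_rate) || nominal_rate <= 0) {
    stop("nominal_rate must be a positive number")
  }
  if (length(timestamps) != nrow(samples)) {
    stop("samples row count must equal timestamps length")
  }
  colnames(samples) <- channel_labels
  structure(
    list(name = as.character(name), channel_labels = as.character(channel_labels),
         samples = samples, nominal_rate = as.numeric(nominal_rate),
         timestamps = as.numeric(timestamps)),
    class = "timed_stream")
}

#' @export
print.timed_stream <- function(x, ...) {
  cat(sprintf("<timed_stream '%s'> %d samples x %d channels @ %g Hz\n",
              x$name, nrow(x$samples), ncol(x$samples), x$nominal_rate))
  cat(sprintf("  channels: %s\n", paste(x$channel_labels, collapse = ", ")))
  if (length(x$timestamps)) {
    cat(sprintf("  clock: %.4f .. %.4f s\n",
                x$timestamps[1], x$timestamps[length(x$timestamps)]))
  }
  invisible(x)
}

#' Duration covered by a stream, in seconds
#' @param stream A [timed_stream()].
#' @return Last minus first timestamp, or 0 for streams shorter than 2 samples.
#' @export
stream_duration <- function(stream) {
  n <- length(stream$timestamps)
  if (n < 2) return(0)
  stream$timestamps[n] - stream$timestamps[1]
}

#' Multi-stream recording on one shared clock
#'
#' Groups the streams of one session (eye tracker, EMG/EEG, stimulus
#' markers, ...). Stream names must be unique; streams must be non-empty.
#'
#' @param streams List of [timed_stream()] objects.
#' @param metadata Free-form named list (session id, calibration note, ...).
#' @param validate Internal: skip non-empty checks (used by [replay_chunks()],
#'   whose chunks may lack samples for a stream).
#' @return An object of class `"recording"`; streams are named by their label.
#' @export
recording <- function(streams, metadata = list(), validate = TRUE) {
  if (!is.list(streams) || length(streams) == 0) {
    stop("a recording needs at least one stream")
  }
  ok <- vapply(streams, inherits, logical(1), what = "timed_stream")
  if (!all(ok)) stop("all streams must be timed_stream objects")
  nms <- vapply(streams, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("stream names must be unique")
  if (validate) {
    empty <- vapply(streams, function(s) nrow(s$samples) == 0, logical(1))
    if (any(empty)) stop(sprintf("stream '%s' is empty", nms[which(empty)[1]]))
  }
  names(streams) <- nms
  structure(list(streams = streams, metadata = metadata), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d stream(s)\n", length(x$streams)))
  for (s in x$streams) {
    cat(sprintf("  %-14s %7d x %d @ %g Hz\n", s$name,
                nrow(s$samples), ncol(s$samples), s$nominal_rate))
  }
  invisible(x)
}

#' Find a stream by name or by required channels
#'
#' @param rec A [recording()].
#' @param name Stream name; if `NULL`, searches for the first stream carrying
#'   all of `channels`.
#' @param channels Channel labels the stream must contain.
#' @return The matching [timed_stream()].
#' @keywords internal
find_stream <- function(rec, name = NULL, channels = NULL) {
  if (!is.null(name)) {
    if (!name %in% names(rec$streams)) {
      stop(sprintf("no stream named '%s' in recording", name))
    }
    s <- rec$streams[[name]]
    if (!is.null(channels)) {
      miss <- setdiff(channels, s$channel_labels)
      if (length(miss)) stop(sprintf("missing channel '%s' in stream '%s'",
                                     miss[1], name))
    }
    return(s)
  }
  overlap <- vapply(rec$streams, function(s) {
    sum(channels %in% s$channel_labels)
  }, integer(1))
  if (max(overlap) == length(channels)) {
    return(rec$streams[[which.max(overlap)]])
  }
  # name the first channel absent from the closest-matching stream
  best <- rec$streams[[which.max(overlap)]]
  miss <- setdiff(channels, best$channel_labels)
  stop(sprintf("missing channel '%s' in recording", miss[1]))
}

#' Regularize raw stream timestamps onto a fitted linear clock
#'
#' Network-transported streams carry per-sample timestamp jitter. Dejittering
#' replaces the raw timestamps with the values of a line fitted to
#' (sample index, timestamp), so that inter-sample spacing is uniform while
#' the mean clock is preserved (for the default least-squares fit the mean of
#' output minus input is exactly zero). Idempotent: a second application is
#' a no-op.
#'
#' @param ts Numeric vector of raw timestamps (seconds), length >= 2,
#'   non-decreasing on average.
#' @param method `"ols"` (ordinary least squares, the default) or
#'   `"theil_sen"` (median-of-pairwise-slopes, robust to isolated clock
#'   spikes).
#' @return Numeric vector of regularized, strictly increasing timestamps.
#' @export
dejitter_timestamps <- function(ts, method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  n <- length(ts)
  if (n < 2) stop("stream too short")
  if (any(!is.finite(ts))) stop("non-finite timestamp")
  idx <- seq_len(n) - 1
  if (method == "ols") {
    mx <- mean(idx); my <- mean(ts)
    slope <- sum((idx - mx) * (ts - my)) / sum((idx - mx)^2)
    intercept <- my - slope * mx
  } else {
    # Theil-Sen: median of pairwise slopes; for long series restrict to a
    # deterministic set of lags so cost stays O(n * n_lags).
    if (n <= 400) {
      pairs <- utils::combn(n, 2)
      slopes <- (ts[pairs[2, ]] - ts[pairs[1, ]]) /
        (idx[pairs[2, ]] - idx[pairs[1, ]])
    } else {
      lags <- unique(pmax(1L, round(n * c(0.05, 0.1, 0.2, 0.3, 0.5))))
      slopes <- unlist(lapply(lags, function(L) {
        (ts[(L + 1):n] - ts[1:(n - L)]) / L
      }))
    }
    slope <- stats::median(slopes)
    intercept <- stats::median(ts - slope * idx)
  }
  if (!is.finite(slope) || slope <= 0) stop("non-monotone clock")
  intercept + slope * idx
}

#' Dejitter every stream of a recording
#' @param rec A [recording()].
#' @inheritParams dejitter_timestamps
#' @return The recording with regularized timestamps.
#' @export
dejitter_recording <- function(rec, method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  rec$streams <- lapply(rec$streams, function(s) {
    s$timestamps <- dejitter_timestamps(s$timestamps, method)
    s
  })
  rec
}

#' Downsample a stream by an integer factor with anti-alias filtering
#'
#' Applies a zero-phase Butterworth low-pass (order 8, cutoff 0.45 x the
#' target rate) before decimation, so no filter-induced group delay can
#' contaminate downstream latency estimates, then keeps every
#' `nominal_rate / target_rate`-th sample.
#'
#' @param stream A [timed_stream()].
#' @param target_rate Target rate in Hz; must divide the nominal rate.
#' @return A [timed_stream()] at `target_rate` with
#'   `ceiling(n / factor)` samples.
#' @export
downsample <- function(stream, target_rate) {
  if (target_rate >= stream$nominal_rate) {
    stop("target rate must be below the nominal rate")
  }
  factor <- stream$nominal_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) stop("non-integer decimation")
  factor <- as.integer(round(factor))
  wc <- 0.45 * target_rate / (stream$nominal_rate / 2)
  filt <- signal::butter(8, wc, type = "low")
  filtered <- apply(stream$samples, 2, function(x) {
    zero_phase_filter(x, filt, pad = min(length(x) - 1L, 120L))
  })
  if (!is.matrix(filtered)) filtered <- matrix(filtered, ncol = ncol(stream$samples))
  keep <- seq(1L, nrow(stream$samples), by = factor)
  timed_stream(stream$name, filtered[keep, , drop = FALSE], target_rate,
               stream$timestamps[keep], stream$channel_labels)
}

#' Write a recording to disk as CSV streams plus a JSON manifest
#'
#' Each stream becomes one CSV file (header row of channel labels, first
#' column `timestamp_s`, "." decimal separator, UTF-8); `manifest.json`
#' records stream names, files, rates and labels so a round trip is lossless
#' (samples and timestamps are written with full double precision).
#'
#' @param rec A [recording()].
#' @param path Directory to create/populate.
#' @param format Only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = "csv") {
  if (!identical(format, "csv")) {
    stop(sprintf("unsupported recording format '%s' (only 'csv')", format))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema = 1L, metadata = rec$metadata, streams = list())
  for (s in rec$streams) {
    file <- paste0(gsub("[^A-Za-z0-9_.-]", "_", s$name), ".csv")
    manifest$streams[[s$name]] <- list(
      file = file, nominal_rate = s$nominal_rate,
      channel_labels = as.list(s$channel_labels))
    cols <- cbind(sprintf("%.17g", s$timestamps),
                  apply(s$samples, 2, function(x) sprintf("%.17g", x)))
    header <- paste(c("timestamp_s", s$channel_labels), collapse = ",")
    con <- file(file.path(path, file), "w", encoding = "UTF-8")
    writeLines(header, con)
    writeLines(apply(cols, 1, paste, collapse = ","), con)
    close(con)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_stream_csv <- function(file, name, nominal_rate = NULL, labels = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"timestamp_s" %in% names(df)) {
    stop(sprintf("stream without timestamps: %s", file))
  }
  ts <- as.numeric(df$timestamp_s)
  sm <- as.matrix(df[setdiff(names(df), "timestamp_s")])
  if (is.null(labels)) labels <- colnames(sm)
  if (is.null(nominal_rate)) {
    if (length(ts) < 2) stop(sprintf("stream too short to infer rate: %s", file))
    nominal_rate <- round(1 / stats::median(diff(ts)), 6)
  }
  timed_stream(name, sm, nominal_rate, ts, labels)
}

#' Read a recording from disk
#'
#' Accepts either a directory written by [write_recording()] (CSV streams +
#' `manifest.json`) or a single CSV file in the same dialect, which becomes a
#' one-stream recording named after the file (its rate is inferred from the
#' median timestamp spacing unless given).
#'
#' @param path Directory or `.csv` file.
#' @param format `"auto"` or `"csv"`.
#' @param nominal_rate Rate override for single-file reads, Hz.
#' @param require_channels Channel labels that must be present somewhere in
#'   the recording; the first missing one is named in the error.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = "auto", nominal_rate = NULL,
                           require_channels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such recording: %s", path))
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf)) stop(sprintf("no manifest.json in %s", path))
    manifest <- jsonlite::read_json(mf)
    streams <- lapply(names(manifest$streams), function(nm) {
      entry <- manifest$streams[[nm]]
      read_stream_csv(file.path(path, entry$file), nm,
                      nominal_rate = entry$nominal_rate,
                      labels = unlist(entry$channel_labels))
    })
    meta <- manifest$metadata
    rec <- recording(streams, metadata = if (is.null(meta)) list() else meta)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    nm <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
    rec <- recording(list(read_stream_csv(path, nm, nominal_rate)))
  } else {
    stop(sprintf("cannot parse recording: %s", path))
  }
  if (!is.null(require_channels)) {
    have <- unlist(lapply(rec$streams, function(s) s$channel_labels))
    miss <- setdiff(require_channels, have)
    if (length(miss)) stop(sprintf("missing channel '%s' in %s", miss[1], path))
  }
  rec
}

#' Split a recording into consecutive time chunks
#'
#' Emulates online, chunked arrival of stream data: the shared clock is cut
#' at `chunk`-second boundaries starting from the earliest sample, and each
#' chunk holds every stream's samples whose timestamps fall in the half-open
#' window `[edge, edge + chunk)`. Concatenating the chunks reproduces the
#' original recording.
#'
#' @param rec A [recording()].
#' @param chunk Chunk duration in seconds, > 0.
#' @return List of [recording()] objects (streams may be empty in chunks a
#'   stream does not cover).
#' @export
replay_chunks <- function(rec, chunk) {
  if (!is.numeric(chunk) || length(chunk) != 1 || chunk <= 0) {
    stop("chunk duration must be > 0")
  }
  t0 <- min(vapply(rec$streams, function(s) s$timestamps[1], numeric(1)))
  t1 <- max(vapply(rec$streams, function(s) s$timestamps[length(s$timestamps)],
                   numeric(1)))
  n_chunks <- floor((t1 - t0) / chunk) + 1L
  lapply(seq_len(n_chunks), function(k) {
    lo <- t0 + (k - 1) * chunk
    hi <- lo + chunk
    streams <- lapply(rec$streams, function(s) {
      keep <- s$timestamps >= lo & s$timestamps < hi
      timed_stream(s$name, s$samples[keep, , drop = FALSE], s$nominal_rate,
                   s$timestamps[keep], s$channel_labels)
    })
    recording(streams, metadata = c(rec$metadata, list(chunk_index = k)),
              validate = FALSE)
  })
}
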