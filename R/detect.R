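#' Trough-detection parameters
#'
#' The detection pipeline downsamples the trace to `target_fs_hz`, band-pass
#' filters it into each band (4-30 Hz and 30-100 Hz by default), thresholds
#' each filtered trace at `threshold_k` times a baseline deviation estimate,
#' takes one trough per contiguous sub-threshold excursion, pools the per-band
#' trains and removes cross-band duplicates closer than `dedup_window_ms`.
#'
#' `baseline` selects the deviation estimate: `"mad"` (default) uses the
#' scaled median absolute deviation `1.4826 * MAD`, a robust estimate of the
#' quiet-background standard deviation that is insensitive to the troughs
#' themselves; `"sd"` uses the plain standard deviation of the whole filtered
#' trace, which at sustained event rates is inflated by the event energy and
#' can place the threshold above every trough (see the methods vignette).
#'
#' @param target_fs_hz analysis sampling rate (default 1000).
#' @param bands list of `c(lo, hi)` band edges in Hz.
#' @param threshold_k threshold in multiples of the baseline deviation
#'   (default 8).
#' @param dedup_window_ms cross-band exclusion window, ms (default 8).
#' @param baseline `"mad"` or `"sd"`.
#' @return a `bq_detection_params` list.
#' @export
detection_params <- function(target_fs_hz = 1000,
                             bands = list(c(4, 30), c(30, 100)),
                             threshold_k = 8,
                             dedup_window_ms = 8,
                             baseline = c("mad", "sd")) {
  check_number(target_fs_hz, "target_fs_hz", lower = 0, strict_lower = TRUE)
  check_number(threshold_k, "threshold_k", lower = 0, strict_lower = TRUE)
  check_number(dedup_window_ms, "dedup_window_ms", lower = 0, strict_lower = TRUE)
  baseline <- match.arg(baseline)
  for (b in bands) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2] || b[2] >= target_fs_hz / 2) {
      rlang::abort("Each band must satisfy 0 < lo < hi < target_fs_hz / 2.")
    }
  }
  structure(list(target_fs_hz = target_fs_hz, bands = bands,
                 threshold_k = threshold_k, dedup_window_ms = dedup_window_ms,
                 baseline = baseline),
            class = "bq_detection_params")
}

#' Downsample a recording
#'
#' Anti-alias low-pass filters at `0.4 * target_fs_hz` (order-4 Butterworth,
#' zero-phase) and decimates. The source rate must be an integer multiple of
#' the target rate; equal rates return the recording unchanged.
#'
#' @param recording a `bq_recording`.
#' @param target_fs_hz target sampling rate, Hz.
#' @return a `bq_recording` at `target_fs_hz`.
#' @export
downsample_recording <- function(recording, target_fs_hz = 1000) {
  fs <- sampling_rate(recording)
  check_number(target_fs_hz, "target_fs_hz", lower = 0, strict_lower = TRUE)
  if (target_fs_hz > fs) rlang::abort("Upsampling is not supported.")
  if (target_fs_hz == fs) return(recording)
  ratio <- fs / target_fs_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    rlang::abort("Source rate must be an integer multiple of the target rate.")
  }
  ratio <- round(ratio)
  bf <- signal::butter(4, 0.4 * target_fs_hz / (fs / 2), type = "low")
  uv <- signal::filtfilt(bf, recording$uv)
  out <- lfp_recording(uv[seq(1, length(uv), by = ratio)],
                       fs_hz = target_fs_hz,
                       preset = attr(recording, "preset"),
                       seed = attr(recording, "seed"),
                       recording_id = attr(recording, "recording_id"))
  out
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass realized as an order-2 high-pass
#' cascaded with an order-2 low-pass, each applied forward and backward
#' (zero-phase), so trough timestamps are not phase-shifted.
#'
#' @param recording a `bq_recording`.
#' @param lo_hz,hi_hz corner frequencies, `0 < lo < hi < fs/2`.
#' @return the filtered `bq_recording`.
#' @export
bandpass_recording <- function(recording, lo_hz, hi_hz) {
  fs <- sampling_rate(recording)
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2)) {
    rlang::abort("Corner frequencies must satisfy 0 < lo < hi < fs/2.")
  }
  hp <- signal::butter(2, lo_hz / (fs / 2), type = "high")
  lp <- signal::butter(2, hi_hz / (fs / 2), type = "low")
  uv <- signal::filtfilt(lp, signal::filtfilt(hp, recording$uv))
  out <- lfp_recording(uv, fs_hz = fs,
                       preset = attr(recording, "preset"),
                       seed = attr(recording, "seed"),
                       recording_id = attr(recording, "recording_id"))
  attr(out, "band") <- c(lo_hz, hi_hz)
  out
}

#' Detect troughs in a band-pass-filtered trace
#'
#' Applies a threshold at `threshold_k` times the baseline deviation (see
#' [detection_params()]) below zero and reports one timestamp per contiguous
#' sub-threshold excursion, at the excursion's minimum sample.
#'
#' @param filtered a band-pass-filtered `bq_recording`.
#' @param threshold_k threshold multiplier (default 8).
#' @param baseline `"mad"` (robust, default) or `"sd"`.
#' @return a `bq_events` tibble with a `band` column; a constant trace yields
#'   an empty train with a warning.
#' @export
detect_troughs <- function(filtered, threshold_k = 8,
                           baseline = c("mad", "sd")) {
  baseline <- match.arg(baseline)
  check_number(threshold_k, "threshold_k", lower = 0, strict_lower = TRUE)
  fs <- sampling_rate(filtered)
  x <- filtered$uv
  sigma <- switch(baseline,
                  sd = stats::sd(x),
                  mad = stats::mad(x, center = stats::median(x)))
  band <- attr(filtered, "band")
  band_lbl <- if (is.null(band)) NA_character_ else paste0(band[1], "-", band[2])
  if (!is.finite(sigma) || sigma == 0) {
    rlang::warn("Baseline deviation is zero; returning an empty train.")
    return(event_train(numeric(0), duration(filtered),
                       band = character(0),
                       recording_id = attr(filtered, "recording_id") %||% NA_character_))
  }
  thr <- -threshold_k * sigma
  below <- x < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_sel <- which(r$values)
  t_idx <- vapply(run_sel, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.min(x[seg])]
  }, integer(1))
  event_train((t_idx - 1L) / fs, duration(filtered),
              band = rep(band_lbl, length(t_idx)),
              recording_id = attr(filtered, "recording_id") %||% NA_character_)
}

#' Pool per-band trough trains and remove duplicates
#'
#' Merges trains from the same recording, sorts by time, and scans greedily
#' from the earliest trough, accepting a trough only if it occurs at least
#' `dedup_window_ms` after the last accepted one. This removes the same
#' trough detected in both filter bands.
#'
#' @param trains a list of `bq_events` sharing one recording id.
#' @param dedup_window_ms exclusion window, ms (default 8).
#' @return a deduplicated `bq_events` tibble.
#' @examples
#' a <- event_train(0.100, 1, recording_id = "r1")
#' b <- event_train(0.105, 1, recording_id = "r1")
#' pool_troughs(list(a, b))$time_s  # 0.100 only
#' @export
pool_troughs <- function(trains, dedup_window_ms = 8) {
  check_number(dedup_window_ms, "dedup_window_ms", lower = 0, strict_lower = TRUE)
  stopifnot(is.list(trains), length(trains) >= 1)
  ids <- unique(unlist(lapply(trains, function(tr) unique(tr$recording_id))))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    rlang::abort("All trains must come from the same recording.")
  }
  merged <- dplyr::bind_rows(lapply(trains, tibble::as_tibble)) |>
    dplyr::arrange(.data$time_s)
  dur <- max(vapply(trains, duration, numeric(1)))
  if (nrow(merged) == 0) {
    return(event_train(numeric(0), dur,
                       recording_id = if (length(ids)) ids else NA_character_))
  }
  win <- dedup_window_ms / 1000
  keep <- logical(nrow(merged))
  last <- -Inf
  for (i in seq_len(nrow(merged))) {
    if (merged$time_s[i] - last >= win) {
      keep[i] <- TRUE
      last <- merged$time_s[i]
    }
  }
  out <- restore_events(merged[keep, , drop = FALSE], NULL, duration_s = dur)
  out
}

#' Trough rate and median instantaneous frequency
#'
#' `trough_rate()` is the event count scaled to events per minute.
#' `median_trough_frequency()` is the median of the reciprocal consecutive
#' inter-trough intervals (instantaneous frequency of trough *i* is
#' `1 / (t_i - t_{i-1})`); it requires at least three timestamps.
#'
#' @param train a `bq_events` tibble.
#' @param duration_s recording span, seconds; defaults to the train's
#'   `duration_s` attribute.
#' @return a single number: events/min, or Hz.
#' @examples
#' tr <- event_train(c(1, 1.25, 1.75, 2.75), duration_s = 60)
#' trough_rate(tr)                # 4 events/min
#' median_trough_frequency(tr)    # median of 4, 2, 1 Hz = 2
#' @export
trough_rate <- function(train, duration_s = NULL) {
  dur <- duration_s %||% attr(train, "duration_s")
  check_number(dur, "duration_s", lower = 0, strict_lower = TRUE)
  nrow(train) * 60 / dur
}

#' @rdname trough_rate
#' @export
median_trough_frequency <- function(train) {
  if (nrow(train) < 3) {
    rlang::abort("At least 3 timestamps are required for a median instantaneous frequency.")
  }
  stats::median(1 / diff(train$time_s))
}

#' Full dual-band trough-detection pipeline
#'
#' Downsamples, filters into each configured band, detects per-band troughs,
#' and pools them with deduplication.
#'
#' @param recording a `bq_recording`.
#' @param params a `bq_detection_params` (defaults from [detection_params()]).
#' @return a `bq_events` tibble of pooled troughs.
#' @examples
#' sim <- generate_preset_recording("M1_anesthetized", duration_s = 60, seed = 1)
#' detected <- detect_events(sim$recording)
#' trough_rate(detected)
#' @export
detect_events <- function(recording, params = detection_params()) {
  stopifnot(inherits(params, "bq_detection_params"))
  rec <- downsample_recording(recording, params$target_fs_hz)
  trains <- lapply(params$bands, function(b) {
    rec |>
      bandpass_recording(b[1], b[2]) |>
      detect_troughs(params$threshold_k, baseline = params$baseline)
  })
  pool_troughs(trains, params$dedup_window_ms)
}
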