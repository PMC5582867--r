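#' Select a representative replay window
#'
#' The replay procedure extracts a 3 min stretch of a recording "representing
#' typical properties of activity". Operationalized deterministically:
#' candidate windows of `window_s` seconds start at every whole second, and
#' the window whose event rate is closest to the whole-recording event rate
#' wins; ties go to the earliest start.
#'
#' @param train a `bq_events` tibble (detected or ground-truth).
#' @param recording_duration_s recording span, seconds; defaults to the
#'   train's `duration_s` attribute.
#' @param window_s window length, seconds (default 180).
#' @return a named numeric vector `c(start_s, end_s)`.
#' @export
select_representative_window <- function(train, recording_duration_s = NULL,
                                         window_s = 180) {
  dur <- recording_duration_s %||% attr(train, "duration_s")
  check_number(dur, "recording_duration_s", lower = 0, strict_lower = TRUE)
  check_number(window_s, "window_s", lower = 0, strict_lower = TRUE)
  if (dur < window_s) {
    rlang::abort("Recording is shorter than the requested window.")
  }
  if (nrow(train) == 0) {
    rlang::warn("Empty train; returning the window starting at 0.")
    return(c(start_s = 0, end_s = window_s))
  }
  global_rate <- nrow(train) / dur
  starts <- seq(0, floor(dur - window_s), by = 1)
  t <- train$time_s
  counts <- vapply(starts, function(s) sum(t >= s & t < s + window_s), numeric(1))
  dev <- abs(counts / window_s - global_rate)
  best <- starts[which.min(dev)]   # which.min takes the earliest tie
  c(start_s = best, end_s = best + window_s)
}

#' Build a replay stimulation protocol from an event train
#'
#' Stimulus times are the event times inside `[start_s, end_s)` shifted to be
#' relative to the window start; inter-stimulus intervals are therefore
#' identical to the source inter-event intervals. The pulse descriptor
#' (amplitude in hardware-dependent units, pulse width) is carried as opaque
#' metadata.
#'
#' @param train a `bq_events` tibble.
#' @param window `c(start_s, end_s)`, e.g. from
#'   [select_representative_window()].
#' @param amplitude,width_ms pulse descriptor attached to every stimulus.
#' @return a `bq_protocol` tibble with columns `time_s`, `amplitude`,
#'   `width_ms` and attributes `window`, `source_id`.
#' @examples
#' tr <- event_train(c(10, 20, 30), duration_s = 180)
#' build_protocol(tr, c(0, 180))$time_s
#' @export
build_protocol <- function(train, window, amplitude = 1, width_ms = 0.2) {
  if (length(window) != 2 || !is.numeric(window) || window[2] <= window[1]) {
    rlang::abort("`window` must be c(start_s, end_s) with end > start.")
  }
  sel <- train$time_s >= window[1] & train$time_s < window[2]
  times <- train$time_s[sel] - window[1]
  out <- tibble::tibble(
    time_s = times,
    amplitude = rep(amplitude, length(times)),
    width_ms = rep(width_ms, length(times))
  )
  attr(out, "window") <- c(start_s = unname(window[1]), end_s = unname(window[2]))
  attr(out, "source_id") <- unique(train$recording_id)[1] %||% NA_character_
  class(out) <- c("bq_protocol", class(out))
  out
}

#' Stimulus rate of a protocol
#'
#' @param protocol a `bq_protocol`.
#' @return stimuli per minute over the protocol window.
#' @export
protocol_rate <- function(protocol) {
  w <- attr(protocol, "window")
  if (is.null(w)) rlang::abort("`protocol` carries no window attribute.")
  nrow(protocol) * 60 / (w[["end_s"]] - w[["start_s"]])
}

#' End-to-end replay protocol from a recording
#'
#' Convenience composition: detect troughs, select the representative window,
#' and build the stimulation protocol.
#'
#' @param recording a `bq_recording`.
#' @param params detection parameters.
#' @param window_s replay window length, seconds.
#' @inheritParams build_protocol
#' @return a `bq_protocol`.
#' @export
replay_from_recording <- function(recording, params = detection_params(),
                                  window_s = 180, amplitude = 1,
                                  width_ms = 0.2) {
  detected <- detect_events(recording, params)
  win <- select_representative_window(detected, window_s = window_s)
  build_protocol(detected, win, amplitude = amplitude, width_ms = width_ms)
}
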