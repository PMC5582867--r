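#' LFP recording and event-train containers
#'
#' A recording is a tibble with columns `time_s` and `uv` (microvolts) plus
#' attributes `fs_hz` (sampling rate), `preset` and `seed`; an event train is
#' a tibble with a `time_s` column (seconds, strictly increasing) plus optional
#' provenance columns `kind`, `band` and `recording_id`, and a `duration_s`
#' attribute giving the span of the source recording.
#'
#' @param uv numeric vector of samples in microvolts.
#' @param fs_hz sampling rate in Hz.
#' @param preset,seed,recording_id optional provenance metadata.
#' @return `lfp_recording()` returns a `bq_recording` tibble; `event_train()`
#'   a `bq_events` tibble.
#' @examples
#' rec <- lfp_recording(rnorm(1000), fs_hz = 1000)
#' sampling_rate(rec)
#' duration(rec)
#' @export
lfp_recording <- function(uv, fs_hz, preset = NA_character_, seed = NA_integer_,
                          recording_id = NA_character_) {
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  stopifnot(is.numeric(uv))
  out <- tibble::tibble(time_s = (seq_along(uv) - 1) / fs_hz, uv = as.numeric(uv))
  attr(out, "fs_hz") <- fs_hz
  attr(out, "preset") <- preset
  attr(out, "seed") <- seed
  attr(out, "recording_id") <- recording_id
  class(out) <- c("bq_recording", class(out))
  out
}

#' @param time_s numeric vector of event times in seconds.
#' @param duration_s span of the source recording in seconds.
#' @param kind,band optional per-event annotations ("slow"/"fast" event class,
#'   detection band).
#' @rdname lfp_recording
#' @export
event_train <- function(time_s, duration_s, kind = NULL, band = NULL,
                        recording_id = NA_character_) {
  stopifnot(is.numeric(time_s))
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (is.unsorted(time_s, strictly = FALSE)) {
    rlang::abort("`time_s` must be sorted non-decreasing.")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s))
  if (!is.null(kind)) out$kind <- kind
  if (!is.null(band)) out$band <- band
  out$recording_id <- recording_id
  attr(out, "duration_s") <- duration_s
  class(out) <- c("bq_events", class(out))
  out
}

#' @param x a `bq_recording` or `bq_events` object.
#' @rdname lfp_recording
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "fs_hz")
  if (is.null(fs)) rlang::abort("`x` has no `fs_hz` attribute; not a recording?")
  fs
}

#' @rdname lfp_recording
#' @export
duration <- function(x) {
  if (inherits(x, "bq_recording")) return(nrow(x) / sampling_rate(x))
  d <- attr(x, "duration_s")
  if (is.null(d)) rlang::abort("`x` has no `duration_s` attribute.")
  d
}

# Rebuild class/attrs after dplyr verbs strip them.
restore_events <- function(df, template, duration_s = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "duration_s") <- duration_s %||% attr(template, "duration_s")
  class(out) <- c("bq_events", class(out))
  out
}
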