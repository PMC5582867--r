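#' Rendering parameters for synthetic LFP traces
#'
#' Each trough is rendered as a one-cycle, negative-first, raised-cosine
#' (Hann-windowed sine) biphasic wavelet whose minimum is aligned to the event
#' timestamp and scaled so the trough depth equals the requested amplitude.
#' Cluster-initial (`"slow"`) events use `trough_amplitude_uv` /
#' `trough_width_ms` — an 80 ms wavelet carries its power inside the 4-30 Hz
#' detection band; within-cluster (`"fast"`) events use `fast_amplitude_uv` /
#' `fast_width_ms` — a 15 ms wavelet lands in the 30-100 Hz band. Background
#' noise is Gaussian white by default (`noise_spectrum = "one_over_f"` gives
#' 1/f-shaped noise of the same standard deviation).
#'
#' @param fs_hz sampling rate, Hz.
#' @param trough_amplitude_uv,trough_width_ms depth (µV) and width (ms) of
#'   slow troughs.
#' @param fast_amplitude_uv,fast_width_ms depth and width of fast troughs;
#'   default to the slow values when `NULL`.
#' @param noise_sd_uv background noise standard deviation, µV.
#' @param noise_spectrum `"white"` or `"one_over_f"`.
#' @return a `bq_render_params` list.
#' @export
render_params <- function(fs_hz = 1000,
                          trough_amplitude_uv = 150,
                          trough_width_ms = 80,
                          fast_amplitude_uv = NULL,
                          fast_width_ms = NULL,
                          noise_sd_uv = 10,
                          noise_spectrum = c("white", "one_over_f")) {
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  check_number(trough_amplitude_uv, "trough_amplitude_uv", lower = 0)
  check_number(trough_width_ms, "trough_width_ms", lower = 0, strict_lower = TRUE)
  check_number(noise_sd_uv, "noise_sd_uv", lower = 0)
  noise_spectrum <- match.arg(noise_spectrum)
  out <- list(
    fs_hz = fs_hz,
    trough_amplitude_uv = trough_amplitude_uv,
    trough_width_ms = trough_width_ms,
    fast_amplitude_uv = fast_amplitude_uv %||% trough_amplitude_uv,
    fast_width_ms = fast_width_ms %||% trough_width_ms,
    noise_sd_uv = noise_sd_uv,
    noise_spectrum = noise_spectrum
  )
  class(out) <- "bq_render_params"
  out
}

# One-cycle negative-first raised-cosine wavelet sampled at fs, unit depth.
# Returns the sample values and the index (1-based) of the trough.
trough_wavelet <- function(width_ms, fs_hz) {
  n <- max(3L, round(width_ms / 1000 * fs_hz))
  x <- seq(0, 1, length.out = n)
  g <- function(u) -sin(2 * pi * u) * sin(pi * u)^2
  w <- g(x)
  peak <- stats::optimize(g, c(0, 0.5))  # most negative point of the first lobe
  w <- w / abs(peak$objective)
  list(values = w, trough_idx = which.min(w))
}

#' Render an event train into an LFP trace
#'
#' @param train a `bq_events` tibble (e.g. from [make_event_train()]); a
#'   `kind` column selects slow/fast wavelets, otherwise all events are slow.
#' @param render a `bq_render_params` object.
#' @param duration_s trace length, seconds; all event times must lie below it.
#' @param seed integer seed for the noise stream.
#' @return a `bq_recording` tibble with `round(duration_s * fs_hz)` rows.
#' @examples
#' tr <- event_train(c(0.5, 1.0), duration_s = 2)
#' rec <- render_lfp(tr, render_params(noise_sd_uv = 0), duration_s = 2, seed = 1)
#' rec$time_s[which.min(rec$uv)]
#' @export
render_lfp <- function(train, render, duration_s, seed) {
  if (!inherits(render, "bq_render_params")) {
    rlang::abort("`render` must be created with render_params().")
  }
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (nrow(train) > 0 && any(train$time_s >= duration_s)) {
    rlang::abort("All event timestamps must be < `duration_s`.")
  }
  fs <- render$fs_hz
  n <- round(duration_s * fs)
  uv <- if (render$noise_sd_uv > 0) {
    with_stream(seed, "render_lfp_noise",
                make_noise(n, render$noise_sd_uv, render$noise_spectrum))
  } else {
    numeric(n)
  }
  if (nrow(train) > 0) {
    kind <- if ("kind" %in% names(train)) train$kind else rep("slow", nrow(train))
    specs <- list(
      slow = c(render$trough_amplitude_uv, render$trough_width_ms),
      fast = c(render$fast_amplitude_uv, render$fast_width_ms)
    )
    for (k in unique(kind)) {
      spec <- specs[[k]] %||% specs$slow
      wav <- trough_wavelet(spec[2], fs)
      vals <- wav$values * spec[1]
      len <- length(vals)
      centers <- round(train$time_s[kind == k] * fs) + 1L
      for (c0 in centers) {
        i0 <- c0 - wav$trough_idx + 1L
        idx <- i0:(i0 + len - 1L)
        ok <- idx >= 1L & idx <= n
        uv[idx[ok]] <- uv[idx[ok]] + vals[ok]
      }
    }
  }
  lfp_recording(uv, fs_hz = fs, seed = seed)
}

make_noise <- function(n, sd_uv, spectrum) {
  z <- stats::rnorm(n)
  if (spectrum == "one_over_f") {
    zf <- stats::fft(z)
    f <- c(1, seq_len(n - 1))                       # guard DC
    f <- pmin(f, n - f + 1)                         # symmetric frequency index
    zf <- zf / sqrt(f)
    z <- Re(stats::fft(zf, inverse = TRUE)) / n
    z <- z / stats::sd(z)
  }
  z * sd_uv
}
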