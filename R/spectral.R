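#' Segment a recording for spectral averaging
#'
#' Splits the first `analysis_len_s` seconds of a recording into
#' non-overlapping, contiguous segments of `segment_len_s` seconds starting at
#' `t = 0`; a trailing remainder shorter than one segment is discarded. With
#' the defaults a 180 s recording yields 36 segments of 5 s.
#'
#' @param recording a `bq_recording`.
#' @param segment_len_s segment length, seconds (default 5).
#' @param analysis_len_s analysis window, seconds (default 180); recordings
#'   shorter than this are used in full.
#' @return a `bq_segments` tibble with columns `segment` and list-column `uv`.
#' @examples
#' rec <- lfp_recording(rnorm(12000), fs_hz = 1000)
#' nrow(segment_recording(rec))  # 2 segments of 5 s, 2 s discarded
#' @export
segment_recording <- function(recording, segment_len_s = 5,
                              analysis_len_s = 180) {
  check_number(segment_len_s, "segment_len_s", lower = 0, strict_lower = TRUE)
  check_number(analysis_len_s, "analysis_len_s", lower = segment_len_s)
  fs <- sampling_rate(recording)
  if (duration(recording) < segment_len_s) {
    rlang::abort("Recording is shorter than one segment.")
  }
  n_seg_samples <- round(segment_len_s * fs)
  usable <- min(nrow(recording), round(analysis_len_s * fs))
  n_segments <- floor(usable / n_seg_samples)
  uv <- recording$uv[seq_len(n_segments * n_seg_samples)]
  out <- tibble::tibble(
    segment = seq_len(n_segments),
    uv = split(uv, rep(seq_len(n_segments), each = n_seg_samples))
  )
  attr(out, "fs_hz") <- fs
  attr(out, "segment_len_s") <- segment_len_s
  class(out) <- c("bq_segments", class(out))
  out
}

#' Segment-averaged power spectrum
#'
#' Computes a one-sided, rectangular-taper periodogram for every segment and
#' averages them bin-wise. The normalization is such that the sum of the
#' one-sided spectrum over all bins equals the segment's mean-square amplitude
#' (discrete Parseval identity); the bin width is `1/segment_len_s` (0.2 Hz
#' for 5 s segments).
#'
#' @param segments a `bq_segments` tibble from [segment_recording()].
#' @param detrend subtract each segment's mean before transforming
#'   (default off).
#' @return a `bq_spectrum` tibble with columns `freq_hz`, `power_uv2` and
#'   attributes `n_segments`, `segment_len_s`, `fs_hz`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 10 * (0:4999) / 1000), fs_hz = 1000)
#' spec <- rec |> segment_recording() |> mean_power_spectrum()
#' spec$freq_hz[which.max(spec$power_uv2)]  # 10 Hz
#' @export
mean_power_spectrum <- function(segments, detrend = FALSE) {
  if (!inherits(segments, "bq_segments") || nrow(segments) == 0) {
    rlang::abort("`segments` must be a non-empty result of segment_recording().")
  }
  fs <- attr(segments, "fs_hz")
  n <- length(segments$uv[[1]])
  if (!all(vapply(segments$uv, length, 1L) == n)) {
    rlang::abort("All segments must have the same length.")
  }
  half <- floor(n / 2) + 1L
  acc <- numeric(half)
  for (x in segments$uv) {
    if (detrend) x <- x - mean(x)
    p <- Mod(stats::fft(x))^2 / n^2
    one_sided <- p[seq_len(half)]
    dbl <- 2:(half - if (n %% 2 == 0) 1L else 0L)  # all but DC (and Nyquist if even)
    one_sided[dbl] <- 2 * one_sided[dbl]
    acc <- acc + one_sided
  }
  out <- tibble::tibble(
    freq_hz = (seq_len(half) - 1) * fs / n,
    power_uv2 = acc / nrow(segments)
  )
  attr(out, "n_segments") <- nrow(segments)
  attr(out, "segment_len_s") <- attr(segments, "segment_len_s")
  attr(out, "fs_hz") <- fs
  class(out) <- c("bq_spectrum", class(out))
  out
}

#' Band-power summation
#'
#' Sums the spectrum's power bins with `band_lo_hz <= f <= band_hi_hz`
#' (inclusive endpoints). The published "delta to gamma" summary band is
#' operationalized as 1-100 Hz.
#'
#' @param spectrum a `bq_spectrum`.
#' @param band_lo_hz,band_hi_hz band edges, Hz.
#' @return total band power (µV²), a single number.
#' @export
band_power <- function(spectrum, band_lo_hz = 1, band_hi_hz = 100) {
  if (!inherits(spectrum, "bq_spectrum")) {
    rlang::abort("`spectrum` must be a bq_spectrum.")
  }
  check_number(band_lo_hz, "band_lo_hz", lower = 0)
  check_number(band_hi_hz, "band_hi_hz", lower = 0)
  if (band_lo_hz >= band_hi_hz) {
    rlang::abort("`band_lo_hz` must be below `band_hi_hz`.")
  }
  if (band_hi_hz > max(spectrum$freq_hz)) {
    rlang::abort("Band exceeds the spectrum's frequency range.")
  }
  sel <- spectrum$freq_hz >= band_lo_hz & spectrum$freq_hz <= band_hi_hz
  sum(spectrum$power_uv2[sel])
}
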