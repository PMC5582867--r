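#' Read and write pipeline objects
#'
#' All on-disk formats are plain text. A recording is a two-column CSV
#' (`time_s`, `uv`) with a JSON sidecar (`<path>.meta.json`) holding `fs_hz`,
#' `preset`, `seed` and `recording_id`. Event trains, cell maps, density
#' tables and spectra are plain CSV; a protocol is a CSV
#' (`time_s`, `amplitude`, `width_ms`) with a JSON header sidecar carrying
#' the source id, window and stimulus rate.
#'
#' @param recording,train,cells,table,spectrum,protocol the object to write.
#' @param path file path.
#' @return the input (writers, invisibly) or the reconstructed object
#'   (readers).
#' @name burstquant-io
NULL

#' @rdname burstquant-io
#' @export
write_recording <- function(recording, path) {
  utils::write.csv(tibble::as_tibble(recording)[, c("time_s", "uv")],
                   path, row.names = FALSE)
  meta <- list(fs_hz = sampling_rate(recording),
               preset = attr(recording, "preset") %||% NA_character_,
               seed = attr(recording, "seed") %||% NA_integer_,
               recording_id = attr(recording, "recording_id") %||% NA_character_)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(recording)
}

#' @rdname burstquant-io
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  lfp_recording(df$uv, fs_hz = meta$fs_hz,
                preset = meta$preset %||% NA_character_,
                seed = meta$seed %||% NA_integer_,
                recording_id = meta$recording_id %||% NA_character_)
}

#' @rdname burstquant-io
#' @export
write_events <- function(train, path) {
  df <- tibble::as_tibble(train)
  df$duration_s <- attr(train, "duration_s")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(train)
}

#' @rdname burstquant-io
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  out <- event_train(df$time_s, duration_s = df$duration_s[1] %||% max(df$time_s),
                     kind = df$kind, band = df$band,
                     recording_id = df$recording_id %||% NA_character_)
  if ("cluster" %in% names(df)) out$cluster <- df$cluster
  out
}

#' @rdname burstquant-io
#' @export
write_cell_map <- function(cells, path) {
  utils::write.csv(tibble::as_tibble(cells), path, row.names = FALSE)
  invisible(cells)
}

#' @rdname burstquant-io
#' @export
read_cell_map <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("x_mm", "depth_frac") %in% names(df))) {
    rlang::abort("A cell map CSV needs columns x_mm and depth_frac.")
  }
  class(df) <- c("bq_cellmap", class(df))
  df
}

#' @rdname burstquant-io
#' @export
write_density <- function(table, path) {
  utils::write.csv(tibble::as_tibble(table), path, row.names = FALSE)
  invisible(table)
}

#' @rdname burstquant-io
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(tibble::as_tibble(spectrum), path, row.names = FALSE)
  invisible(spectrum)
}

#' @rdname burstquant-io
#' @export
write_protocol <- function(protocol, path) {
  utils::write.csv(tibble::as_tibble(protocol), path, row.names = FALSE)
  w <- attr(protocol, "window")
  hdr <- list(source_id = attr(protocol, "source_id") %||% NA_character_,
              window = as.list(w),
              rate_per_min = protocol_rate(protocol),
              n_stimuli = nrow(protocol))
  jsonlite::write_json(hdr, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(protocol)
}

#' @rdname burstquant-io
#' @export
read_protocol <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  hdr <- jsonlite::read_json(paste0(path, ".meta.json"))
  attr(df, "window") <- c(start_s = hdr$window$start_s, end_s = hdr$window$end_s)
  attr(df, "source_id") <- hdr$source_id %||% NA_character_
  class(df) <- c("bq_protocol", class(df))
  df
}
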