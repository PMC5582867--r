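#' Condition presets
#'
#' The package ships a registry of recording presets that carry the published
#' condition statistics as simulation ground truth: anesthetized S1/M1 trough
#' rates of 156 and 63 events/min with median instantaneous frequencies of
#' 1.43 and 0.82 Hz; non-anesthetized (awake) rates of 159.7 and 51.9
#' events/min; replay-source exemplars at 125 and 24 events/min; and the
#' pharmacologically induced slice regimes (4-AP at 0.3 Hz / 106 µV,
#' gabazine at 0.24 Hz / 358.5 µV discharges). A cell-map intensity preset
#' (`P5_7_in_vivo`) carries the layer- and sector-resolved apoptotic-cell
#' densities of the P5-7 cortex.
#'
#' @return `preset_names()` returns the registered recording preset names;
#'   `get_preset(name)` a list with elements `train` (`bq_train_params`) and
#'   `render` (`bq_render_params`); `get_intensity_preset(name)` an intensity
#'   tibble suitable for [generate_cell_map()].
#' @examples
#' preset_names()
#' get_preset("S1_anesthetized")$train
#' @export
preset_names <- function() {
  names(preset_registry()$recordings)
}

preset_registry <- function() {
  env <- getOption("burstquant.preset_cache", NULL)
  if (!is.null(env)) return(env)
  path <- system.file("extdata", "presets.yaml", package = "burstquant",
                      mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  options(burstquant.preset_cache = reg)
  reg
}

#' @param name a registered preset name.
#' @rdname preset_names
#' @export
get_preset <- function(name) {
  reg <- preset_registry()$recordings
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    rlang::abort(sprintf(
      "Unknown preset %s. Registered presets: %s.",
      deparse(name), paste(names(reg), collapse = ", ")
    ))
  }
  spec <- reg[[name]]
  list(
    name = name,
    train = do.call(train_params, spec$train),
    render = do.call(render_params, spec$render)
  )
}

#' @rdname preset_names
#' @export
get_intensity_preset <- function(name = "P5_7_in_vivo") {
  reg <- preset_registry()$cell_maps
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    rlang::abort(sprintf(
      "Unknown intensity preset %s. Registered: %s.",
      deparse(name), paste(names(reg), collapse = ", ")
    ))
  }
  spec <- reg[[name]]
  purrr::imap_dfr(spec, function(sectors, layer) {
    tibble::tibble(
      layer = layer_label(layer),
      sector = names(sectors),
      intensity_per_mm2 = as.numeric(unlist(sectors))
    )
  })
}

layer_label <- function(x) {
  c(L1_4 = "I-IV", L5 = "V", L6 = "VI")[[x]]
}

#' Generate a preset LFP recording with ground truth
#'
#' Draws the ground-truth trough train for a registered preset and renders it
#' into an LFP trace. Both outputs are reproduced bit-for-bit from
#' `(name, duration_s, seed)`.
#'
#' @param name a registered preset name (see [preset_names()]).
#' @param duration_s recording length, seconds.
#' @param seed integer seed.
#' @return a list with elements `recording` (`bq_recording`) and `truth`
#'   (`bq_events`, the ground-truth train).
#' @examples
#' sim <- generate_preset_recording("M1_anesthetized", duration_s = 60, seed = 1)
#' trough_rate(sim$truth)
#' @export
generate_preset_recording <- function(name, duration_s, seed) {
  preset <- get_preset(name)
  train <- make_event_train(preset$train, duration_s, seed)
  train$recording_id <- sprintf("%s_seed%03d", name, as.integer(seed))
  rec <- render_lfp(train, preset$render, duration_s, seed)
  attr(rec, "preset") <- name
  attr(rec, "recording_id") <- sprintf("%s_seed%03d", name, as.integer(seed))
  list(recording = rec, truth = train)
}
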