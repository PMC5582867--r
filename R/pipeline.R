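#' Run configuration
#'
#' Builds and validates the configuration for an end-to-end run. A single
#' base seed fans out into per-stage, per-replicate named streams, so adding
#' a stage or a replicate never reshuffles the randomness of the others.
#'
#' @param presets recording preset names to simulate.
#' @param duration_s recording length per replicate, seconds.
#' @param n_seeds replicates per preset (seeds derived from `seed`).
#' @param seed base integer seed.
#' @param detection list of arguments for [detection_params()].
#' @param spectral list with `segment_len_s`, `analysis_len_s`, `band_lo_hz`,
#'   `band_hi_hz`.
#' @param replay `NULL` to skip, or a list with `window_s`.
#' @param cell_maps `NULL` to skip, or a list with `intensity_preset` and
#'   `n_maps`.
#' @return a `bq_run_config` list.
#' @examples
#' cfg <- run_config(presets = "M1_anesthetized", duration_s = 60, n_seeds = 1)
#' validate_run_config(cfg)
#' @export
run_config <- function(presets,
                       duration_s = 600,
                       n_seeds = 1,
                       seed = 1,
                       detection = list(),
                       spectral = list(segment_len_s = 5, analysis_len_s = 180,
                                       band_lo_hz = 1, band_hi_hz = 100),
                       replay = list(window_s = 180),
                       cell_maps = NULL) {
  structure(list(presets = presets, duration_s = duration_s,
                 n_seeds = n_seeds, seed = seed, detection = detection,
                 spectral = spectral, replay = replay, cell_maps = cell_maps),
            class = "bq_run_config")
}

#' @param config a `bq_run_config`, or the path to a YAML file holding one.
#' @rdname run_config
#' @return `validate_run_config()` returns a tibble of diagnostics
#'   (`field`, `message`); zero rows means the configuration is valid.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  diag <- list()
  note <- function(field, message) {
    diag[[length(diag) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  known <- preset_names()
  for (p in config$presets) {
    if (!p %in% known) note("presets", sprintf("unknown preset '%s'", p))
  }
  if (!is.numeric(config$duration_s) || config$duration_s <= 0) {
    note("duration_s", "must be a positive number")
  }
  if (!is.numeric(config$n_seeds) || config$n_seeds < 1) {
    note("n_seeds", "must be >= 1")
  }
  dp <- tryCatch(do.call(detection_params, config$detection), error = identity)
  if (inherits(dp, "error")) {
    note("detection", conditionMessage(dp))
  }
  sp <- config$spectral
  if (!is.null(sp)) {
    if ((sp$segment_len_s %||% 5) <= 0) {
      note("spectral.segment_len_s", "must be > 0")
    }
    if ((sp$analysis_len_s %||% 180) < (sp$segment_len_s %||% 5)) {
      note("spectral.analysis_len_s", "must be >= segment_len_s")
    }
    if ((sp$band_lo_hz %||% 1) >= (sp$band_hi_hz %||% 100)) {
      note("spectral.band", "band_lo_hz must be below band_hi_hz")
    }
  }
  if (!is.null(config$replay) &&
      (config$replay$window_s %||% 180) > config$duration_s) {
    note("replay.window_s", "window exceeds recording duration")
  }
  if (!is.null(config$cell_maps)) {
    ip <- config$cell_maps$intensity_preset %||% "P5_7_in_vivo"
    ok <- tryCatch({get_intensity_preset(ip); TRUE}, error = function(e) FALSE)
    if (!ok) note("cell_maps.intensity_preset", sprintf("unknown preset '%s'", ip))
  }
  if (length(diag) == 0) {
    tibble::tibble(field = character(0), message = character(0))
  } else {
    dplyr::bind_rows(diag)
  }
}

#' Execute an end-to-end run
#'
#' Simulates every configured preset replicate, runs detection, spectral
#' analysis and (optionally) replay-protocol construction and cell-map
#' quantification, writes all stage outputs into a deterministic directory
#' layout (`recordings/`, `events/`, `spectra/`, `protocols/`, `densities/`,
#' `report.json`, `manifest.json`) and returns the run report invisibly.
#' Invalid configurations are rejected before any file is written.
#'
#' @param config a `bq_run_config`.
#' @param out_dir output directory (created if missing).
#' @param write_recordings write the (large) raw trace CSVs (default FALSE;
#'   events, spectra and summaries are always written).
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, write_recordings = FALSE) {
  diag <- validate_run_config(config)
  if (nrow(diag) > 0) {
    rlang::abort(paste0("Invalid configuration:\n", paste0(
      "  - ", diag$field, ": ", diag$message, collapse = "\n")))
  }
  dirs <- file.path(out_dir, c("recordings", "events", "spectra",
                               "protocols", "densities"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  dp <- do.call(detection_params, config$detection)
  sp <- config$spectral
  results <- list()
  for (p in config$presets) {
    for (r in seq_len(config$n_seeds)) {
      sd <- stream_seed(config$seed, sprintf("sim/%s/%d", p, r))
      sim <- generate_preset_recording(p, config$duration_s, sd)
      id <- attr(sim$recording, "recording_id")
      if (isTRUE(write_recordings)) {
        write_recording(sim$recording, file.path(out_dir, "recordings",
                                                 paste0(id, ".csv")))
      }
      detected <- detect_events(sim$recording, dp)
      write_events(detected, file.path(out_dir, "events", paste0(id, ".csv")))
      entry <- list(
        preset = p, seed = sd, recording_id = id,
        n_troughs = nrow(detected),
        rate_per_min = trough_rate(detected),
        median_freq_hz = if (nrow(detected) >= 3) {
          median_trough_frequency(detected)
        } else NA_real_
      )
      if (!is.null(sp)) {
        spec <- sim$recording |>
          segment_recording(sp$segment_len_s %||% 5, sp$analysis_len_s %||% 180) |>
          mean_power_spectrum()
        write_spectrum(spec, file.path(out_dir, "spectra", paste0(id, ".csv")))
        entry$band_power_uv2 <- band_power(spec, sp$band_lo_hz %||% 1,
                                           sp$band_hi_hz %||% 100)
      }
      if (!is.null(config$replay)) {
        win <- select_representative_window(
          detected, window_s = config$replay$window_s %||% 180)
        prot <- build_protocol(detected, win)
        write_protocol(prot, file.path(out_dir, "protocols", paste0(id, ".csv")))
        entry$protocol_rate_per_min <- protocol_rate(prot)
        entry$protocol_window <- as.list(win)
      }
      results[[id]] <- entry
    }
  }

  densities <- NULL
  if (!is.null(config$cell_maps)) {
    geom <- section_geometry()
    intensity <- get_intensity_preset(config$cell_maps$intensity_preset %||%
                                        "P5_7_in_vivo")
    n_maps <- config$cell_maps$n_maps %||% 1
    densities <- purrr::map_dfr(seq_len(n_maps), function(r) {
      sd <- stream_seed(config$seed, sprintf("cells/%d", r))
      cells <- generate_cell_map(geom, intensity, sd)
      tab <- cells |> assign_bins(geom) |> density_table(geom)
      write_density(tab, file.path(out_dir, "densities",
                                   sprintf("map_seed%03d.csv", r)))
      dplyr::mutate(area_aggregate(tab), map = r, seed = sd)
    })
  }

  report <- pipeline_report(results, densities = densities, config = config)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       dataframe = "rows", pretty = TRUE)
  manifest <- list(
    package = "burstquant",
    version = as.character(utils::packageVersion("burstquant")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    derived_seeds = lapply(results, function(e) e$seed)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(report)
}

#' Assemble a machine-readable run report
#'
#' Summarises stage outputs (per-recording trough rates, median frequencies,
#' band powers, protocol rates; pooled cell densities) and, when two or more
#' presets were run with at least two replicates each, adds a Mann-Whitney
#' comparison of the per-replicate trough rates between the first two
#' presets.
#'
#' @param results named list of per-recording summaries (see [run_pipeline()]).
#' @param densities optional tibble of pooled density results.
#' @param config the originating configuration, echoed into the report.
#' @return a list ready for JSON serialisation.
#' @export
pipeline_report <- function(results, densities = NULL, config = NULL) {
  report <- list(
    n_recordings = length(results),
    recordings = unname(results)
  )
  if (length(results) > 0) {
    df <- purrr::map_dfr(results, function(e) {
      tibble::tibble(preset = e$preset, rate_per_min = e$rate_per_min)
    })
    presets <- unique(df$preset)
    if (length(presets) >= 2) {
      two <- df[df$preset %in% presets[1:2], ]
      if (all(table(two$preset) >= 1)) {
        tst <- compare_two_groups(two, rate_per_min, preset,
                                  method = "mann_whitney")
        td <- tidy(tst)
        mu <- tapply(two$rate_per_min, two$preset, mean)
        report$rate_comparison <- list(
          presets = presets[1:2],
          method = "mann_whitney",
          statistic = td$statistic,
          p.value = td$p.value,
          direction = sprintf("%s > %s", names(mu)[which.max(mu)],
                              names(mu)[which.min(mu)])
        )
      }
    }
  }
  if (!is.null(densities)) {
    report$densities <- densities |>
      dplyr::group_by(.data$area, .data$layer) |>
      dplyr::summarise(mean_density_per_mm2 = mean(.data$density_per_mm2),
                       n_maps = dplyr::n(), .groups = "drop")
  }
  if (!is.null(config)) report$config <- unclass(config)
  report
}
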