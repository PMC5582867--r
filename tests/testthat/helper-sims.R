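# Shared simulation cache so the rate- and frequency-recovery tests reuse the
# same preset recordings instead of regenerating them per test block.
sim_cache <- new.env(parent = emptyenv())

preset_recovery <- function(preset, n_seeds = 20, duration_s = 600) {
  key <- sprintf("%s_%d_%d", preset, n_seeds, duration_s)
  if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
  res <- lapply(seq_len(n_seeds), function(s) {
    sim <- generate_preset_recording(preset, duration_s, s)
    det <- detect_events(sim$recording)
    list(truth_rate = trough_rate(sim$truth),
         det_rate = trough_rate(det),
         det_intervals = diff(det$time_s))
  })
  out <- list(
    truth_rates = vapply(res, `[[`, numeric(1), "truth_rate"),
    det_rates = vapply(res, `[[`, numeric(1), "det_rate"),
    pooled_medf = stats::median(1 / unlist(lapply(res, `[[`, "det_intervals")))
  )
  sim_cache[[key]] <- out
  out
}
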