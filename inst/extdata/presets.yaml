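# Recording presets. Each preset carries the published condition statistics as
# generator ground truth: mean trough rate (events/min) and, for in vivo
# presets, the median instantaneous trough frequency (Hz). The replay_source
# presets emulate the exemplar recordings from which the replay stimulation
# files were built (24 and 125 stimuli/min), whose rates differ from the
# across-animal condition means. Shape parameters (cluster size, log-scale
# spreads) are package choices; gap jitter for the S1-like presets is small
# because the published (mean rate, median frequency) pair pins the upper half
# of the interval distribution into a narrow band (see the methods vignette).
# Render widths/amplitudes are chosen so each trough class carries its power
# in exactly one detection band: 80 ms slow troughs in 4-30 Hz, 15 ms fast
# troughs in 30-100 Hz, 120 ms slice discharges in 4-30 Hz.
recordings:
  S1_anesthetized:
    train: {mean_rate_per_min: 156.0, median_freq_hz: 1.43,
            events_per_cluster_mean: 1.92, sigma_intra: 0.35, sigma_gap: 0.008,
            refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 150, trough_width_ms: 80,
             fast_amplitude_uv: 100, fast_width_ms: 15, noise_sd_uv: 10,
             noise_spectrum: white}
  M1_anesthetized:
    train: {mean_rate_per_min: 63.0, median_freq_hz: 0.82,
            events_per_cluster_mean: 1.85, sigma_intra: 0.35, sigma_gap: 0.15,
            refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 150, trough_width_ms: 80,
             fast_amplitude_uv: 100, fast_width_ms: 15, noise_sd_uv: 10,
             noise_spectrum: white}
  S1_awake:
    train: {mean_rate_per_min: 159.7, median_freq_hz: 1.43,
            events_per_cluster_mean: 1.94, sigma_intra: 0.30, sigma_gap: 0.005,
            refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 150, trough_width_ms: 80,
             fast_amplitude_uv: 100, fast_width_ms: 15, noise_sd_uv: 10,
             noise_spectrum: white}
  M1_awake:
    train: {mean_rate_per_min: 51.9, median_freq_hz: 0.82,
            events_per_cluster_mean: 1.85, sigma_intra: 0.35, sigma_gap: 0.25,
            refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 150, trough_width_ms: 80,
             fast_amplitude_uv: 100, fast_width_ms: 15, noise_sd_uv: 10,
             noise_spectrum: white}
  M1_replay_source:
    train: {mean_rate_per_min: 24.0, median_freq_hz: 0.82,
            events_per_cluster_mean: 1.90, sigma_intra: 0.35, sigma_gap: 0.65,
            refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 150, trough_width_ms: 80,
             fast_amplitude_uv: 100, fast_width_ms: 15, noise_sd_uv: 10,
             noise_spectrum: white}
  S1_replay_source:
    train: {mean_rate_per_min: 125.0, median_freq_hz: 1.43,
            events_per_cluster_mean: 1.92, sigma_intra: 0.35, sigma_gap: 0.10,
            refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 150, trough_width_ms: 80,
             fast_amplitude_uv: 100, fast_width_ms: 15, noise_sd_uv: 10,
             noise_spectrum: white}
  slice_4AP:
    # repetitive discharges at 0.3 Hz, mean amplitude 106 uV
    train: {mean_rate_per_min: 18.0, events_per_cluster_mean: 1.0,
            sigma_gap: 0.20, refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 106, trough_width_ms: 120,
             noise_sd_uv: 12, noise_spectrum: white}
  slice_gabazine:
    # repetitive single discharges at 0.24 Hz, mean amplitude 358.5 uV
    train: {mean_rate_per_min: 14.4, events_per_cluster_mean: 1.0,
            sigma_gap: 0.20, refractory_s: 0.012}
    render: {fs_hz: 1000, trough_amplitude_uv: 358.5, trough_width_ms: 120,
             noise_sd_uv: 35, noise_spectrum: white}

# Apoptotic-cell intensity presets, cells/mm^2 per (sector, layer band).
# P5_7_in_vivo carries the published layer I-IV densities (sectors a/b pooled
# 57.76, c-f pooled 14.86), the layer V densities (a/b 13.79, c-f 29.97) and
# the area-uniform layer VI density 6.76.
cell_maps:
  P5_7_in_vivo:
    L1_4: {a: 57.76, b: 57.76, c: 14.86, d: 14.86, e: 14.86, f: 14.86}
    L5:   {a: 13.79, b: 13.79, c: 29.97, d: 29.97, e: 29.97, f: 29.97}
    L6:   {a: 6.76,  b: 6.76,  c: 6.76,  d: 6.76,  e: 6.76,  f: 6.76}
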