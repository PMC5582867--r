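---
title: "Methods: simulating and quantifying neonatal cortical activity and apoptosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying neonatal cortical activity and apoptosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

In the developing mouse neocortex, programmed cell death and spontaneous
electrical activity are regionally patterned and negatively correlated: the
primary motor cortex (M1) shows sparse spindle-burst activity and dense
apoptosis, the adjacent somatosensory cortex (S1) the reverse. burstquant
implements the complete quantitative chain used to establish such a
correlation — spectral and trough-based quantification of local field
potential (LFP) recordings, conversion of recorded activity into replay
stimulation protocols, and sectorized laminar quantification of
apoptotic-cell density — together with a synthetic-data generator that makes
every stage testable by parameter recovery. This vignette documents the
models, the parameters that matter, and the design decisions taken where the
procedure left choices open.

# The trough train generator

## Model

Neonatal cortical activity arrives in clusters (spindle bursts): a slow
trough initiates each cluster and fast, gamma-range troughs follow within
it. `make_event_train()` draws from a renewal cluster process:

* cluster sizes are $K = 1 + \mathrm{Poisson}(m - 1)$ with mean cluster size
  $m$;
* intra-cluster (fast) intervals are log-normal
  $\mathrm{LN}(\mu_i, \sigma_i)$;
* the gap from the last event of one cluster to the first event of the next
  is log-normal $\mathrm{LN}(\mu_g, \sigma_g)$;
* every interval is floored at a refractory period (12 ms by default, just
  above the 8 ms deduplication window of the detector, so ground truth maps
  one-to-one onto detectable events);
* the first cluster onset is placed uniformly within one mean cycle, making
  the process approximately stationary from $t = 0$.

Events are tagged `"slow"` (cluster-initial) or `"fast"` (within-cluster);
the renderer uses the tag to choose the wavelet class.

## Solving the interval distributions from published statistics

Each condition is summarised by two published numbers: the mean trough rate
$\lambda$ (events/min) and the median *instantaneous* frequency $f_{med}$
(the median of reciprocal consecutive inter-trough intervals). The solver in
`train_params()` fixes $\mu_g$ and $\mu_i$ from these:

* the expected fraction of all intervals that are gaps is $1/m$, so with
  intra-cluster intervals lying below the pooled median the median interval
  is the $\alpha$-quantile of the gap distribution with
  $\alpha = 1 - m/2$; $\mu_g$ places that quantile at $1/f_{med}$;
* $\mu_i$ then follows from the mean rate:
  $\tfrac{m-1}{m}\,E_i + \tfrac{1}{m}\,E_g = 60/\lambda$.

This construction requires $m < 2$ (gaps must be the majority interval class
at the median), and it exposes a strong constraint hidden in the published
S1 numbers: a mean interval of 0.385 s (156 min⁻¹) combined with a median
interval of 0.699 s (1.43 Hz) forces at least half of all intervals to lie
in a narrow band just above 0.699 s, and the remaining intervals to average
below 70 ms. Any generator matching both statistics is therefore strongly
bimodal, with an almost rhythmic slow-trough recurrence; the shipped S1
presets use a small gap jitter ($\sigma_g \approx 0.01$) for exactly this
reason, and this should be read as a consequence of the published summary
statistics, not as a physiological claim. The M1-like conditions
(63 min⁻¹ / 0.82 Hz) are far less constrained and use wider jitter.

Because the interval distribution has little mass between the fast clump
and the gap clump, the *per-recording* median frequency is sensitive to the
realized gap fraction crossing one half; the package therefore pools
intervals across replicate recordings when estimating the median (as do the
recovery tests and the acceptance script), which stabilises the estimate at
the cost of treating replicates as exchangeable.

## Rendering

`render_lfp()` renders each trough as a one-cycle negative-first
raised-cosine (Hann-windowed sine) biphasic wavelet, scaled so the trough
depth equals the requested amplitude and aligned so its minimum falls on
the event timestamp. Two wavelet classes separate the detector's two bands:

* slow troughs: 80 ms wide, 150 µV deep — power concentrated near 12 Hz,
  inside the 4–30 Hz detection band and negligible above 30 Hz;
* fast troughs: 15 ms wide, 100 µV deep — power near 67 Hz, inside the
  30–100 Hz band and negligible below 30 Hz.

These widths were chosen by measuring single-wavelet band responses: an
80 ms wavelet leaves exactly one sub-threshold excursion in the 4–30 Hz
band and none in the 30–100 Hz band at the default noise level, and vice
versa for the 15 ms wavelet. Narrower slow wavelets (40–50 ms) put their
carrier too close to the 30 Hz band edge and are detected twice, once per
band, at offsets beyond the 8 ms deduplication window. Slice-discharge
presets use a single 120 ms wavelet class whose high-pass undershoot stays
below the detection threshold at the configured noise level.

Background noise is Gaussian white at the analysis rate (1 kHz), 10 µV SD
for the in vivo presets; a 1/f option exists but is off by default because
white noise keeps the threshold analytically checkable (the 8σ Gaussian
tail probability per sample is below 10⁻¹⁵, so a noise-only trace yields no
detections). The published study gives no in vivo trough amplitudes, only
slice-discharge amplitudes (106 µV for 4-AP, 358.5 µV for gabazine, which
the slice presets carry literally); in vivo amplitudes are set heuristically
to 10–15× the noise SD.

Presets are rendered directly at 1 kHz — the rate at which all analysis
happens after downsampling — rather than at the 20 kHz acquisition rate;
`downsample_recording()` is exercised separately on 20 kHz test signals.
The tests and the acceptance script use 600 s recordings, 20 replicate
seeds for rate/frequency recovery, 10 for replay and 50 cell maps, sizes at
which Monte-Carlo error sits comfortably inside the recovery tolerances.

## What the generator does and does not emulate

It emulates: condition-specific trough rates and median instantaneous
frequencies (anesthetized and awake S1/M1, the two slice regimes, and the
two replay exemplars), clustered event timing, band-separated spectral
content of slow and fast troughs, and Poisson cell maps with sector- and
layer-dependent intensity. It does not emulate: multi-channel geometry,
unit (spike) activity, amplitude variability across troughs, non-stationary
bout structure over minutes, movement artifacts, 1/f background (by
default), or curved cortical anatomy. Passing recovery tests therefore
demonstrate that the analysis chain is correct and unbiased under the
stated generative model — not that it is robust to every property of real
recordings.

# Spectral quantification

`segment_recording()` splits the first 180 s into non-overlapping 5 s
segments from $t = 0$ (36 segments), discarding any trailing remainder.
`mean_power_spectrum()` averages one-sided rectangular-taper periodograms
across segments; the bin width is $1/5\,\mathrm{s} = 0.2$ Hz. No taper is
applied because the original analysis names none; a `detrend` flag
(default off) subtracts segment means. The normalization makes the bin sum
equal the mean-square amplitude, so the discrete Parseval identity is a
unit test (relative tolerance $10^{-9}$). `band_power()` sums bins with
inclusive endpoints; the "delta to gamma" summary band is operationalized
as 1–100 Hz since no numeric limits are published.

# Trough detection

The pipeline follows the published procedure: downsample to 1 kHz
(anti-alias low-pass at 0.4× the target rate, then decimate), band-pass
into 4–30 Hz and 30–100 Hz, threshold at 8× a baseline deviation, take one
trough per contiguous sub-threshold excursion (at its minimum), pool the
two bands, and drop troughs within 8 ms of an accepted one (greedy,
earliest-accepted scan — deterministic given sorted input, and idempotent).
Troughs at exactly 8 ms separation are retained (the exclusion is strict).

Design decisions where the procedure is underspecified:

* **Baseline deviation.** The package defaults to the scaled median
  absolute deviation (1.4826·MAD) of the filtered trace rather than its
  plain SD. The SD reading is provably unusable at sustained event rates:
  with rate $\lambda$, wavelet width $W$, shape factor $\beta$ and
  amplitude $A$, the full-trace variance is approximately
  $\sigma_{band}^2 + \lambda \beta W A^2$, so the 8×SD threshold exceeds
  $A$ itself whenever $\lambda \beta W > 1/64$ — which the S1 rate of
  2.6 s⁻¹ guarantees for any wavelet wide enough to carry 4–30 Hz power,
  independent of amplitude. "Baseline" is therefore read as the quiet
  background between events, which the MAD estimates robustly (event duty
  cycles here are far below 50%). `baseline = "sd"` remains available, and
  a unit test documents that it detects fewer troughs on S1-like traces.
* **Zero-phase filtering.** An order-2 Butterworth high-pass cascaded with
  an order-2 low-pass (four poles), each applied forward-backward, so
  trough timestamps are not phase-shifted. The cascade is numerically
  stable where a direct transfer-function band-pass at 4–30 Hz/1 kHz is
  fragile. Contracts: ≥90% amplitude retention in-band, ≤10% one octave
  outside.
* **Polarity and multiplicity.** Troughs only (negative deflections); one
  event per excursion, at the excursion minimum; a constant (zero-SD)
  trace returns an empty train with a warning.
* **Median frequency.** All consecutive intervals enter the median; no
  maximum-interval exclusion is applied by default (the original treatment
  of long between-bout gaps is unstated).

Detection is verified against an exhaustive sample-by-sample scan (exact
equality on 10 s traces), and recovery tests require detected rates and
pooled median frequencies within 10% of the generator's ground truth.

# Replay protocols

The original study chose two 3 min stretches "representing typical
properties of activity" to build stimulation files; how they were chosen is
unstated. `select_representative_window()` operationalizes this
deterministically: candidate 180 s windows start at every whole second and
the window whose event rate is closest to the whole-recording rate wins,
ties to the earliest start. `build_protocol()` copies the event times in
the window (shifted to window-relative time), preserving the inter-event
interval multiset exactly; the pulse descriptor is opaque metadata since
the published pulse shape is hardware-defined.

The published protocol rates (24 ± 3.1 and 125 ± 15.2 stimuli/min) came
from two specific exemplar recordings whose rates differ from the
across-animal condition means (63 and 156 min⁻¹). The package therefore
ships dedicated `M1_replay_source` / `S1_replay_source` presets carrying
the exemplar rates as ground truth; the end-to-end replay checks run
detection → window selection → protocol construction on those presets.

# Sectorized density quantification

The analyzed strip of a P5-7 coronal section is modeled as a flat rectangle
("unrolled" cortex — the original sectors follow the curved cortical
surface; adequate for synthetic maps and a documented limitation): six
sectors a–f of 0.55 mm width starting 0.73 mm from the midline, with
laminar bands I–IV, V and VI as fractions of the cortical thickness.
The band fractions (0.45/0.30/0.25) are not published (layers were
identified from DAPI cytoarchitecture); the defaults reflect typical P6
cytoarchitecture and are fully configurable. All bins are half-open
$[lo, hi)$ (the deepest band closes at 1), coordinates are mm from the
midline and pia-normalized depth fractions — unambiguous boundary behavior
by construction. Only the P5-7 geometry is defaulted; other ages require an
explicit geometry.

`generate_cell_map()` draws a homogeneous Poisson process per bin at the
preset intensity (the published layer I–IV densities 57.76 and
14.86 cells/mm² for M1 and S1, layer V 13.79/29.97, layer VI 6.76);
`density_table()` divides per-bin counts by anatomical bin area (not imaged
area — the original normalization is unstated); `area_aggregate()` pools
counts and areas (never densities) into M1 = a/b and S1 = c–f. Counts are
conserved exactly, including out-of-grid points, and recovery tests check
the estimator is unbiased within Monte-Carlo error.

# Statistics

`compare_two_groups()` wraps the two-tailed Student's t-test and the
Mann-Whitney test (exact for combined $n \le 20$ without ties — verified
against full permutation enumeration — and normal approximation with tie
correction above). `two_way_anova()` fits `value ~ f1 * f2` with Type II
sums of squares (via `car::Anova`; the original software's SS type is
unstated and the designs are unbalanced across slices), dropping the
interaction when cells have no replication, and reducing to one-way when
`f2` is absent. Post-hoc pairwise comparisons use Bonferroni by default;
Newman–Keuls (step-down studentized range, implemented on
`stats::ptukey`) is provided because the original analysis used both, but
is flagged non-conservative. The replicate unit throughout is the
slice/hemisphere/animal-level summary value, matching the published $n$
definitions.

# Orchestration and reproducibility

`run_pipeline()` validates the full configuration before any side effect,
then writes a deterministic layout (`recordings/`, `events/`, `spectra/`,
`protocols/`, `densities/`, `report.json`, `manifest.json`). One base seed
fans out into named per-stage, per-replicate streams (a hash of seed and
stage name), so inserting a stage never reshuffles the randomness of
existing stages; every parameter is echoed into the manifest, and repeated
runs are byte-identical. All formats are plain CSV/JSON/YAML; recordings
use a two-column CSV with a JSON metadata sidecar (no binary container
dependency). The package's functions are the interface; `run_pipeline()`
plus the shipped preset registry cover scripted end-to-end use.

# Known limitations

* The generator's near-rhythmic S1 gap structure is forced by the published
  summary pair (see above); real inter-burst intervals are more variable,
  which would widen the recovered median's sampling distribution.
* Trough amplitudes are constant within a class; amplitude heterogeneity
  (and therefore near-threshold misses) is not modeled.
* The flat-strip geometry ignores cortical curvature; sector areas are
  exact rectangles.
* Newman–Keuls controls error rates only weakly; it is provided for
  completeness, with Bonferroni as the default.
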