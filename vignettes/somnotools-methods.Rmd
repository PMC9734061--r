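---
title: "Methods: sleep electrophysiology analysis in somnotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep electrophysiology analysis in somnotools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`somnotools` analyzes rodent polysomnography — EEG/LFP/EMG recordings
scored into 1-s vigilance-state epochs — and quantifies the NREM-sleep
oscillations that thalamocortical circuits generate: slow-wave activity
(SWA), sleep spindles, their mutual coupling, and the tonic/burst firing of
single units. This vignette documents the models and procedures, the
parameters that matter, the numerical choices, and what the accompanying
synthetic generator does and does not emulate.

## Time, states and containers

All event times are seconds from recording start; intervals are half-open
`[start_s, end_s)`. Zeitgeber time (hours after lights-on) is stored once,
on the recording. A `hypnogram` is a vector of labels over
{Wake, NREM, REM, Artifact} at a fixed epoch length (1 s by default, the
standard scoring resolution for mouse EEG/EMG). Artifact epochs always
break episode runs and are excluded from time-in-state denominators by
default. Signals travel as EDF (the polysomnography interchange standard;
16-bit, so write–read round trips are exact only to the per-channel
quantization step) or as float32 binary with a JSON sidecar when a lossless
container is wanted.

## Sleep architecture

Episodes are maximal runs of one state. Two thresholds parameterize the
classical analyses:

* `interruption_s` — brief interruptions by a different state, flanked by
  the same state on both sides, are absorbed (default 0, i.e. off; the
  literature's consolidation rules vary, so absorption is opt-in).
* `min_stable_s` — latency to a state is the time to its first run lasting
  at least this long; 20 s is the conventional threshold for "consolidated"
  NREM sleep, and the same rule is applied to REM (an explicit assumption;
  the convention for REM is less settled). An absent state yields `NA`,
  never 0.

Episodes are counted in the window containing their start, which makes
per-hour counts unambiguous. Percent time is always computed from epoch
labels, not from the (possibly filtered) episode list, so discarding short
episodes from counts never loses time.

## Spectral analysis

`welch_psd()` averages Hann-tapered, mean-detrended periodograms over 8-s
windows with 75% overlap (0.125 Hz resolution), the standard parameters for
rodent sleep EEG. When a state mask is given, only windows lying *fully
inside* contiguous masked runs contribute, so state-conditioned spectra
never mix states across a boundary. Band powers are trapezoidal integrals
with linear interpolation at the band edges, which makes adjacent bands
tile exactly (SWA 0.5–4 Hz = its sub-bands, to machine precision).

The delta sub-bands follow the fronto-thalamic literature: delta1
0.75–1.75 Hz (relatively insensitive to sleep pressure) and delta2
2.75–3.5 Hz (sleep-pressure sensitive). A 2.5–3.5 Hz variant of delta2
also circulates; both are provided (`default_bands()$delta2`,
`$delta2_alt`) and the choice is the caller's.

Normalization divides a PSD by its total power (trapezoidal integral over
the full computed range by default, restrictable via `range_hz`), the usual
between-animal normalization. Whether the total should be per-state or
per-recording is a genuinely open convention; the implementation takes
whatever mask the caller used for the estimate.

One deliberate deviation: the taper is Hann rather than the Hamming default
of some toolboxes. For band *integrals* the difference is far below the
estimator's own variance, and Hann's zero endpoints behave better with the
masked-window scheme.

## Spindle detection

Spindles are detected from continuous-wavelet-transform energy in the
spindle band (10–16 Hz; a 9–16 Hz convention also exists and the band is a
parameter). Two analytic wavelet families are available — complex Morlet
(Gaussian frequency window, `n_cycles` = 7) and an order-2 frequency
B-spline (triangular frequency window) — evaluated at 13 center
frequencies across the band, magnitude-squared, frequency-averaged,
smoothed (50 ms boxcar) and divided by the series mean over NREM epochs.
This NREM normalization makes detection amplitude-scale invariant:
rescaling the signal changes no event time.

Detection is two-threshold hysteresis on the normalized energy: a candidate
is a contiguous region above `mean + 1 SD` (NREM statistics) containing at
least one sample above `mean + 2.5 SD`; candidates closer than 100 ms are
merged. All four numbers are parameters.

Event *extent* is then refined, because threshold crossings systematically
truncate a waxing-and-waning event: for a Hann-enveloped burst, the region
above any fixed threshold is strictly shorter than the burst. The refined
boundary rule measures the width of the energy peak at one quarter of its
height above baseline (the NREM median) — for a Hann envelope this width is
exactly half the full duration — and corrects it in quadrature for the
detector's own temporal blur: a narrowband burst is smeared by the wavelet
envelope, a Gaussian of FWHM `2 sqrt(2 ln 2) n_cycles / (2 pi f_center)`
(~0.2 s at the defaults), plus the smoothing boxcar. Both corrections are
closed-form properties of the analysis kernel, not fitted constants. The
result is an approximately unbiased duration estimate across the 0.4–2 s
range of interest; durations outside that range are rejected (>0.4 s is
the conventional rodent spindle floor; the 2 s cap excludes fused
delta-band contamination). Events with at least half their extent in NREM
are kept; those not fully inside NREM (e.g. straddling a NREM-to-REM
transition) carry `transition = TRUE`.

Per event the detector reports peak-to-trough amplitude of the band-passed
signal, the center frequency of maximal wavelet energy, and mean normalized
energy. Rates are per minute of NREM within the analysis window.

## Phase, envelope and coupling

All phase outputs use one convention: filtered-signal trough = 0°, peak =
180°. Phase and envelope come from a zero-phase (forward–backward)
4th-order Butterworth band-pass followed by the analytic signal. For slow
or narrow bands relative to the sampling rate, the band-pass polynomial
becomes numerically singular; the extractor therefore decimates first
(anti-aliased) so the band sits well inside the decimated Nyquist range,
and interpolates unwrapped phase and envelope back to the original grid.
This changes nothing measurable for slow-band phase while keeping every
design well conditioned.

**Slow-wave/spindle cross-correlation.** Slow-wave peaks are local maxima
of the SW-band (0.5–4 Hz) signal within NREM above the 75th amplitude
percentile (percentile configurable; the threshold convention is not
standardized). The SW-band signal and the spindle envelope are averaged in
±2 s around each peak on a 50 Hz envelope grid, and the averaged envelope
is Pearson-normalized against the averaged SW template at every lag.
Positive peak lag means spindle activity follows the slow-wave peak; the
lag resolution is one envelope sample (20 ms). Note that against a strictly
periodic slow oscillation the lag is identified only modulo one cycle —
an inherent property of correlation, relevant to synthetic inputs but not
to the irregular slow waves of real NREM sleep.

**Modulation index.** Phase–amplitude coupling uses the binned-distribution
family: mean amplitude per phase bin (18 bins), normalized to a
distribution P, summarized as KL(P‖uniform)/log(n_bins) — the normalized
entropy deficit, 0 for phase-independent amplitude and 1 for a
single-bin concentration. Empty bins contribute zero (0·log 0 = 0). The
preferred phase is the amplitude-weighted circular mean.

**Comodulogram.** MI on a grid of (phase center, amplitude center) pairs.
The phase half-bandwidth default is ±0.25 Hz so that adjacent bands on the
default 0.5 Hz grid do not overlap: with overlapping phase bands a strong
slow rhythm leaks into neighboring cells and the matrix maximum no longer
localizes the driver. Amplitude half-bandwidth defaults to ±2 Hz, wide
enough to pass a spindle's envelope sidebands.

**Surrogate calibration.** The MI null circularly shifts the amplitude
series by uniform offsets of at least 10 s (configurable) — shifting, not
shuffling, preserves the amplitude autocorrelation so only the
phase–amplitude alignment is destroyed — and reports
`p = (1 + #{MI_surr ≥ MI}) / (1 + n_surrogates)`.

**Cross-region coupling.** The slow-oscillation phase of one region is
sampled at spindle envelope peaks detected in another region and
summarized by a circular histogram, circular mean and resultant length.

## Single-unit metrics

The spike-band contract is the published filter: 600–4000 Hz 4th-order
elliptic band-pass, 0.1 dB passband ripple, 40 dB stopband attenuation,
applied zero-phase. Spike sorting itself is out of scope — the module
consumes per-unit spike-time tables.

Bursts follow the thalamic T-type definition: at least 2 spikes with
inter-spike intervals ≤ 10 ms, preceded by ≥ 100 ms of silence (all three
parameters of `burst_criteria()`; the first spike of a train counts as
preceded by silence). Detection is a single left-to-right scan with a 1 ns
numerical grace so regularly spaced trains are not split by floating-point
representation. Burst density is per minute of a state, bursts assigned to
states by their onset epoch. Peri-transition histograms align spikes to
state boundaries whose flanking runs each last ≥ 20 s (mirroring the
consolidation threshold) and report spikes/s per bin averaged over
transitions.

## The synthetic generator

Real recordings of this kind are rarely public, so the package ships a
generator whose outputs have recoverable ground truth; every analysis
stage is tested against it.

* **States**: a semi-Markov chain (Wake → NREM; NREM → REM with
  probability 0.3, else Wake; REM → Wake) with exponential episode
  durations. Defaults — Wake 150 s, NREM 120 s, REM 60 s — give the
  few-minute episodes typical of mouse sleep. `fragmentation` divides all
  means, multiplying episode counts while preserving state totals, which is
  exactly the architecture phenotype of interest (more, shorter episodes;
  unchanged time in state).
* **Signals** (200 Hz default): per-channel 1/f background at 20 µV RMS; a
  shared 1 Hz, 150 µV slow oscillation during NREM (trough = 0°,
  peak = 180° by construction); 12 Hz spindles at 8 per NREM minute,
  0.5–1.5 s Hann envelopes, ~100 µV peak-to-trough, placed wholly inside
  NREM episodes with a configurable fraction (default 0.7) envelope-peak
  locked to a target slow-oscillation phase (default 180°) and the rest
  uniform; 7.5 Hz theta in REM; EMG loud in Wake. Amplitudes were chosen
  once as typical of mouse frontal EEG; all are parameters.
* **Spikes**: per state, Poisson tonic firing plus Poisson-placed bursts
  of 2–6 spikes at a fixed 5 ms interval, each preceded by an enforced
  silent gap. When bursts are generated, guard rules (no spike within the
  silence window of a burst boundary; tonic chains thinned below the
  intra-burst criterion) make detection under `sim_burst_criteria()`
  recover the ground truth exactly; with bursts disabled the tonic process
  is left strictly Poisson.

One global seed expands into named per-stream sub-seeds (hypnogram, each
channel, each unit), so components are independently reproducible and the
full pipeline is byte-identical across runs.

What the generator does **not** emulate: non-stationary sleep-pressure
dynamics, K-complexes and asymmetric slow-wave shapes, spindle frequency
chirps, volume conduction and inter-regional lags, movement and electrode
artifacts, and non-Poisson firing statistics. Tests passing on this
synthetic ground truth therefore demonstrate correctness of the
*computations* under the stated model, not detector performance on real
data.

## Numerical choices and degenerate inputs

* Welch windows shorter than the taper, masks admitting no window, bands
  outside the computed range, zero total power, hypnograms with no NREM,
  fewer than 10 slow-wave peaks, and empty event lists all raise immediate
  errors rather than returning silent zeros; binned time courses flag
  empty bins as `NA` and never interpolate.
* Band integrals interpolate at band edges so adjacent bands tile exactly.
* The EDF writer quantizes to the per-channel physical range read back
  from its own 8-character header field, making write–read scaling exact.
* Problem sizes in the test-suite simulations (10 × 30-min recordings for
  detector recovery, 25-min coupled recordings for PAC, 500 replicates for
  surrogate calibration, 1000 random trains for the burst oracle) were
  chosen to give stable statistics at interactive runtimes.

## Known limitations

Detection thresholds are standard-deviation based, so the false-positive
rate depends on how much genuine spindle activity inflates the NREM energy
statistics; in nearly event-free recordings the thresholds are effectively
lower. The duration correction assumes a roughly Hann-like (symmetric,
waxing-and-waning) envelope; strongly asymmetric events will be biased
accordingly. The comodulogram inherits the usual PAC caveats: sharp
non-sinusoidal slow waves create harmonic cells, and narrow phase bands
trade frequency resolution against phase-estimate variance.
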