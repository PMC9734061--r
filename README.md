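# somnotools

Analysis of rodent sleep electrophysiology: polysomnographic recordings
(EEG, depth LFP, EMG) scored into 1-second vigilance-state epochs, and the
NREM-sleep oscillations that thalamocortical circuits generate.

The package is written for sleep and systems neuroscientists who need a
reproducible, scriptable version of the standard analysis chain:

* **Sleep architecture** — episode segmentation, episodes/h, mean episode
  duration, percent time in state, latency to the first consolidated
  episode (the > 20 s stability rule), binned time-in-state series; the
  metrics that quantify sleep fragmentation.
* **Spectral analysis** — state-masked Welch PSD (8 s Hann windows, 75%
  overlap), total-power normalization for between-animal comparison, band
  integrals for slow-wave activity (SWA, 0.5–4 Hz) and the delta
  sub-bands δ1 (0.75–1.75 Hz) and δ2 (2.75–3.5 Hz), and binned SWA time
  courses.
* **Spindle detection** — continuous-wavelet-transform energy in the
  spindle band (10–16 Hz; complex Morlet or frequency B-spline wavelets),
  NREM-normalized with two-threshold hysteresis and a duration estimator
  corrected for the wavelet's own temporal blur; per-state spindle rate,
  amplitude and length.
* **Slow-wave/spindle coupling** — SW-peak-triggered normalized
  cross-correlation with the spindle envelope; phase–amplitude coupling as
  the normalized-entropy modulation index over phase bins,
  MI = KL(P‖U)/log N with P the mean-amplitude distribution over N = 18
  phase bins; comodulograms; circular-shift surrogate calibration; and
  cross-region slow-oscillation phase at spindle peaks. The phase
  convention throughout is trough = 0°, peak = 180°.
* **Single-unit activity** — the 600–4000 Hz fourth-order elliptic
  spike-band filter (0.1 dB ripple, 40 dB stopband), per-state firing
  rates, peri-transition rate histograms, and thalamic T-type burst
  detection (≥ 2 spikes at ≤ 10 ms intervals after ≥ 100 ms silence) with
  burst density and length statistics.
* **Synthetic polysomnography** — a generator with known ground truth
  (semi-Markov hypnograms with a fragmentation dial, 1/f background,
  NREM slow oscillation, phase-locked Hann-enveloped spindles, REM theta,
  state-dependent EMG, tonic + burst spike trains) against which every
  stage is validated.

File formats: EDF for signals (plus a lossless float32 + JSON sidecar
variant), CSV for hypnograms, event tables and spike times, JSON for
results. See the methods vignette
(`vignettes/somnotools-methods.Rmd`) for the full account of models,
parameters and numerical choices.

## Worked example

Simulate half an hour of baseline-like mouse sleep and push it through the
pipeline:

```r
library(somnotools)

params <- sim_params(duration_s = 1800, seed = 1,
                     channels = c("EEG_front", "ACC", "AD", "EMG"))
hyp <- simulate_hypnogram(params)
sim <- simulate_recording(hyp, params)
sim$recording
#> <recording> 4 channels x 360000 samples @ 200 Hz (1800.0 s), t0 = ZT0.00
#>   channels: EEG_front[EEG_front], ACC[ACC], AD[AD], EMG[EMG]

architecture_summary(segment_episodes(hyp), hyp)
#>   state episodes_per_h mean_episode_dur_s percent_time
#> 1  Wake             12              129.5        43.17
#> 2  NREM             12              162.2        54.06
#> 3   REM              6               16.7         2.78
latency_to_state(hyp, "NREM")   # first NREM run lasting > 20 s
#> [1] 19

eeg <- channel(sim$recording, "EEG_front")
psd <- normalize_psd(welch_psd(eeg, params$fs, hyp = hyp, state = "NREM"))
band_power(psd, default_bands()$swa)      # SWA fraction of total power
#> [1] 0.982

spindles <- detect_spindles(eeg, params$fs, hyp)
spindle_stats(spindles, hyp)
#>   n_events rate_per_min mean_amp_uv mean_dur_s
#> 1      148         9.13        98.2      0.974

cr <- cross_region_phase_coupling(channel(sim$recording, "ACC"),
                                  channel(sim$recording, "AD"),
                                  params$fs, hyp)
#> SO phase at spindle peaks: mean 179.3 deg, resultant 0.74 (n = 147)

unit <- simulate_spike_train(hyp, params, unit_id = "trn1", region = "TRN")
burst_stats(detect_bursts(unit$train, burst_criteria()), hyp, state = "NREM")
#>   n_bursts density_per_min mean_spikes mean_dur_ms
#> 1      329            20.3        3.56        13.4
```

Reading them: the hypnogram spends about half its time in NREM in episodes
of a couple of minutes; the NREM spectrum is dominated by slow-wave
activity; the detector finds ~9 spindles per NREM minute of ~100 µV and
~1 s (the generator injected 8/min, 100 µV, 0.5–1.5 s); spindle peaks in AD
cluster near 180° of the ACC slow oscillation — the slow-oscillation peak —
with a strong resultant, reflecting the 70% phase-locked fraction the
generator uses by default; and the TRN-like unit bursts at ~20/min of NREM
under the standard 10 ms / 100 ms criteria (the generator injects 15/min at
a 5 ms intra-burst interval; the remainder are tonic chains that satisfy
the broader standard criteria).

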