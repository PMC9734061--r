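# Synthetic polysomnography generator with known ground truth: semi-Markov
# vigilance-state sequences, state-specific signal recipes (1/f background,
# NREM slow oscillation + phase-locked spindles, REM theta, state-dependent
# EMG tone) and spike trains mixing tonic firing with T-type-like bursts.
# One global seed expands deterministically into per-stream sub-seeds so
# hypnogram, each channel and each unit are independently reproducible.

#' Simulation parameters
#'
#' Defaults describe a baseline mouse recording: episode means of a few
#' minutes, 1 Hz slow oscillation at 150 uV during NREM, 12 Hz spindles of
#' ~100 uV peak-to-trough at 8 per NREM minute, mostly locked near the slow
#' oscillation peak (180 degrees, trough = 0 convention), 1/f background at
#' 20 uV RMS, REM theta, and thalamic-like spiking (tonic Poisson firing
#' plus short fixed-ISI bursts preceded by an enforced silent gap).
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Simulated duration, seconds.
#' @param epoch_s Scoring epoch, seconds.
#' @param mean_episode_s Named mean episode durations (s) for Wake/NREM/REM.
#' @param fragmentation Divisor applied to all mean episode durations;
#'   larger values give more, shorter episodes with unchanged state totals.
#' @param rem_entry_prob Probability that an ending NREM episode enters REM.
#' @param spindle_rate_per_min Target spindle rate per minute of NREM.
#' @param spindle_dur_s Length-2 range (s) of uniform spindle durations.
#' @param spindle_amp_uv Spindle peak-to-trough amplitude at envelope peak (uV).
#' @param spindle_freq_hz Spindle carrier frequency (Hz).
#' @param so_freq_hz,so_amp_uv NREM slow-oscillation frequency (Hz) and
#'   amplitude (uV).
#' @param couple_prob Fraction of spindles whose envelope peak is placed at
#'   `couple_phase_deg` of the concurrent slow-oscillation cycle; the rest
#'   are placed uniformly in time.
#' @param couple_phase_deg Target slow-oscillation phase of coupled spindle
#'   peaks (trough = 0, peak = 180).
#' @param theta_freq_hz,theta_amp_uv REM theta frequency and amplitude.
#' @param noise_exponent Slope alpha of the 1/f^alpha background.
#' @param noise_rms_uv Background RMS (uV) on EEG/LFP channels.
#' @param emg_rms_uv Named per-state EMG RMS (uV).
#' @param tonic_rate_hz Named per-state tonic firing rate (Hz).
#' @param burst_rate_per_min Named per-state burst rate (per minute).
#' @param spikes_per_burst Length-2 integer range of spikes per burst.
#' @param intraburst_isi_ms Fixed intra-burst inter-spike interval (ms).
#' @param pre_burst_silence_ms Enforced silent gap before each burst (ms).
#' @param channels Channel roles to simulate.
#' @param seed Global seed (expands to per-stream sub-seeds).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(fs = 200,
                       duration_s = 4 * 3600,
                       epoch_s = 1,
                       mean_episode_s = c(Wake = 150, NREM = 120, REM = 60),
                       fragmentation = 1,
                       rem_entry_prob = 0.3,
                       spindle_rate_per_min = 8,
                       spindle_dur_s = c(0.5, 1.5),
                       spindle_amp_uv = 100,
                       spindle_freq_hz = 12,
                       so_freq_hz = 1,
                       so_amp_uv = 150,
                       couple_prob = 0.7,
                       couple_phase_deg = 180,
                       theta_freq_hz = 7.5,
                       theta_amp_uv = 50,
                       noise_exponent = 1,
                       noise_rms_uv = 20,
                       emg_rms_uv = c(Wake = 60, NREM = 8, REM = 5),
                       tonic_rate_hz = c(Wake = 10, NREM = 5, REM = 12),
                       burst_rate_per_min = c(Wake = 1, NREM = 15, REM = 0.5),
                       spikes_per_burst = c(2, 6),
                       intraburst_isi_ms = 5,
                       pre_burst_silence_ms = 100,
                       channels = c("EEG_front", "EEG_par", "ACC", "AD",
                                    "TRN", "Brr", "VPL", "EMG"),
                       seed = 1) {
  p <- as.list(environment())
  for (nm in c("fs", "duration_s", "epoch_s", "fragmentation",
               "spindle_amp_uv", "spindle_freq_hz", "so_freq_hz", "so_amp_uv",
               "theta_freq_hz", "theta_amp_uv", "noise_rms_uv",
               "intraburst_isi_ms", "pre_burst_silence_ms")) {
    if (!is.numeric(p[[nm]]) || any(p[[nm]] <= 0)) stop(nm, " must be positive")
  }
  for (nm in c("mean_episode_s", "emg_rms_uv", "tonic_rate_hz", "burst_rate_per_min")) {
    v <- p[[nm]]
    if (!all(c("Wake", "NREM", "REM") %in% names(v))) {
      stop(nm, " must be named with Wake, NREM, REM")
    }
    if (any(v < 0)) stop(nm, " must be non-negative")
  }
  if (p$couple_prob < 0 || p$couple_prob > 1) stop("couple_prob must be in [0, 1]")
  if (p$couple_phase_deg < 0 || p$couple_phase_deg >= 360) {
    stop("couple_phase_deg must be in [0, 360)")
  }
  if (p$rem_entry_prob < 0 || p$rem_entry_prob > 1) stop("rem_entry_prob must be in [0, 1]")
  if (length(p$spindle_dur_s) != 2 || any(p$spindle_dur_s <= 0) ||
      p$spindle_dur_s[1] > p$spindle_dur_s[2]) {
    stop("spindle_dur_s must be an increasing positive (min, max) pair")
  }
  if (length(p$spikes_per_burst) != 2 || any(p$spikes_per_burst < 2) ||
      p$spikes_per_burst[1] > p$spikes_per_burst[2]) {
    stop("spikes_per_burst must be a (min, max) pair with min >= 2")
  }
  if (p$intraburst_isi_ms >= p$pre_burst_silence_ms) {
    stop("intraburst_isi_ms must be smaller than pre_burst_silence_ms ",
         "(burst criteria degenerate otherwise)")
  }
  bad <- setdiff(p$channels, CHANNEL_ROLES)
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  structure(p, class = "sim_params")
}

#' Burst criteria matching a simulation's generative model
#'
#' Detection under these criteria recovers the simulator's ground-truth
#' bursts exactly (the generator enforces the corresponding silent guards
#' around every injected burst).
#'
#' @param params A [sim_params()].
#' @return A [burst_criteria()].
#' @export
sim_burst_criteria <- function(params) {
  burst_criteria(
    max_intraburst_isi_ms = params$intraburst_isi_ms,
    min_spikes = params$spikes_per_burst[1],
    min_preceding_silence_ms = params$pre_burst_silence_ms
  )
}

#' Simulate a vigilance-state sequence
#'
#' Semi-Markov chain with exponential episode durations (means
#' `mean_episode_s / fragmentation`) and transitions Wake -> NREM,
#' NREM -> REM with probability `rem_entry_prob` (else back to Wake),
#' REM -> Wake. Durations are discretized to scoring epochs (minimum one
#' epoch), so state totals are preserved while fragmentation multiplies
#' episode counts.
#'
#' @param params A [sim_params()].
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$duration_s < 3 * max(params$mean_episode_s)) {
    warning("duration_s < 3 x the longest mean episode; ",
            "architecture statistics will be unstable")
  }
  set.seed(sub_seed(params$seed, "hypnogram"))
  n_target <- ceiling(params$duration_s / params$epoch_s)
  chunks <- list()
  total <- 0L
  state <- "Wake"
  while (total < n_target) {
    mu <- params$mean_episode_s[[state]] / params$fragmentation
    dur <- stats::rexp(1, rate = 1 / mu)
    n_ep <- max(1L, as.integer(round(dur / params$epoch_s)))
    chunks[[length(chunks) + 1L]] <- rep(state, n_ep)
    total <- total + n_ep
    state <- switch(state,
      Wake = "NREM",
      NREM = if (stats::runif(1) < params$rem_entry_prob) "REM" else "Wake",
      REM = "Wake"
    )
  }
  hypnogram(unlist(chunks)[seq_len(n_target)], epoch_s = params$epoch_s)
}

## Usable placement intervals (peak-time bounds) inside NREM episodes for a
## spindle of duration `dur`: the whole event must fit in the episode.
placement_bounds <- function(nrem_runs, dur, epoch_s, margin = 0.25) {
  lo <- (nrem_runs$start - 1) * epoch_s + dur / 2 + margin
  hi <- (nrem_runs$start - 1 + nrem_runs$len) * epoch_s - dur / 2 - margin
  ok <- hi > lo
  data.frame(lo = lo[ok], hi = hi[ok])
}

#' Simulate a multichannel recording for a hypnogram
#'
#' Every EEG/LFP channel receives independent 1/f^alpha background noise
#' plus shared state-gated components: an NREM slow oscillation (trough at
#' phase 0, peak at 180), Hann-enveloped spindle events placed wholly
#' inside NREM episodes (a `couple_prob` fraction with envelope peak at
#' `couple_phase_deg` of the slow-oscillation cycle, the rest uniform in
#' time), and REM theta. The EMG channel is broadband noise, loud in Wake.
#'
#' @param hyp A [hypnogram()].
#' @param params A [sim_params()].
#' @return List with elements `recording` (a [recording()]) and `truth`
#'   (ground truth: `spindles` data frame with start/end/peak times,
#'   coupling flag and slow-oscillation phase at each envelope peak;
#'   `so_peaks_s`, slow-oscillation peak times within NREM; `params`).
#' @export
simulate_recording <- function(hyp, params) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(params, "sim_params"))
  env_bw <- 2 / min(params$spindle_dur_s) # spindle spectral half-width, Hz
  if (params$spindle_freq_hz - env_bw <= 2 * params$so_freq_hz) {
    stop("spindle band (", params$spindle_freq_hz, " +/- ", env_bw,
         " Hz) overlaps the slow-oscillation band; increase the separation")
  }
  if (params$fs < 4 * params$spindle_freq_hz) {
    stop("fs must be at least 4 x spindle_freq_hz")
  }
  fs <- params$fs
  n <- as.integer(round(hypnogram_duration_s(hyp) * fs))
  t <- (seq_len(n) - 1) / fs
  st <- sample_states(hyp, n, fs)
  nrem <- st == "NREM"
  rem <- st == "REM"

  ## shared slow oscillation: trough at phase 0, peak at 180 degrees
  so_phase_deg <- (360 * params$so_freq_hz * t) %% 360
  so_sig <- -params$so_amp_uv * cos(deg2rad(so_phase_deg)) * nrem
  theta_sig <- params$theta_amp_uv * sin(2 * pi * params$theta_freq_hz * t) * rem

  ## spindle events
  set.seed(sub_seed(params$seed, "events"))
  runs <- label_runs(hyp$labels)
  nrem_runs <- runs[runs$state == "NREM", , drop = FALSE]
  nrem_min <- sum(nrem) / fs / 60
  n_spin <- stats::rpois(1, params$spindle_rate_per_min * nrem_min)
  peaks <- numeric(0); durs <- numeric(0); coupled <- logical(0)
  if (n_spin > 0 && nrow(nrem_runs) > 0) {
    for (i in seq_len(n_spin)) {
      dur <- stats::runif(1, params$spindle_dur_s[1], params$spindle_dur_s[2])
      is_cpl <- stats::runif(1) < params$couple_prob
      bounds <- placement_bounds(nrem_runs, dur, hyp$epoch_s)
      if (!nrow(bounds)) next
      w <- (bounds$hi - bounds$lo) / sum(bounds$hi - bounds$lo)
      for (attempt in 1:100) {
        k <- sample.int(nrow(bounds), 1, prob = w)
        if (is_cpl) {
          ## slow-oscillation cycles whose target-phase time fits the episode
          f <- params$so_freq_hz
          k0 <- ceiling(bounds$lo[k] * f - params$couple_phase_deg / 360)
          k1 <- floor(bounds$hi[k] * f - params$couple_phase_deg / 360)
          if (k1 < k0) next
          cyc <- if (k1 > k0) sample(k0:k1, 1) else k0
          peak <- (cyc + params$couple_phase_deg / 360) / f
        } else {
          peak <- stats::runif(1, bounds$lo[k], bounds$hi[k])
        }
        sep_ok <- !length(peaks) ||
          all(abs(peaks - peak) >= (durs + dur) / 2 + 0.2)
        if (sep_ok) {
          peaks <- c(peaks, peak); durs <- c(durs, dur); coupled <- c(coupled, is_cpl)
          break
        }
      }
    }
  }
  ord <- order(peaks)
  peaks <- peaks[ord]; durs <- durs[ord]; coupled <- coupled[ord]
  spin_sig <- numeric(n)
  for (i in seq_along(peaks)) {
    i0 <- max(1L, as.integer(floor((peaks[i] - durs[i] / 2) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((peaks[i] + durs[i] / 2) * fs)))
    tt <- t[i0:i1] - (peaks[i] - durs[i] / 2)
    hann <- 0.5 * (1 - cos(2 * pi * pmin(pmax(tt / durs[i], 0), 1)))
    spin_sig[i0:i1] <- spin_sig[i0:i1] +
      (params$spindle_amp_uv / 2) * hann *
        sin(2 * pi * params$spindle_freq_hz * tt)
  }

  sig <- matrix(0, nrow = n, ncol = length(params$channels))
  emg_rms <- c(params$emg_rms_uv, Artifact = unname(params$emg_rms_uv["Wake"]))
  for (j in seq_along(params$channels)) {
    role <- params$channels[j]
    set.seed(sub_seed(params$seed, paste0("chan_", role)))
    if (role == "EMG") {
      sig[, j] <- stats::rnorm(n) * emg_rms[st]
    } else {
      sig[, j] <- noise_1f(n, params$noise_exponent, params$noise_rms_uv) +
        so_sig + spin_sig + theta_sig
    }
  }
  rec <- recording(sig, fs, labels = params$channels, roles = params$channels,
                   t0_zt = 0)

  so_peak_t <- (seq_len(floor(max(t) * params$so_freq_hz)) - 0.5) / params$so_freq_hz
  so_peak_t <- so_peak_t[nrem[pmin(n, floor(so_peak_t * fs) + 1L)]]
  truth <- list(
    spindles = data.frame(
      start_s = peaks - durs / 2, end_s = peaks + durs / 2, dur_s = durs,
      peak_s = peaks, amp_uv = rep(params$spindle_amp_uv, length(peaks)),
      freq_hz = rep(params$spindle_freq_hz, length(peaks)),
      coupled = coupled,
      phase_deg = (360 * params$so_freq_hz * peaks) %% 360
    ),
    so_peaks_s = so_peak_t,
    params = params
  )
  list(recording = rec, truth = truth)
}

#' Simulate a spike train with ground-truth bursts
#'
#' Per vigilance state, homogeneous Poisson tonic spikes plus
#' Poisson-placed bursts of `spikes_per_burst` spikes at the fixed
#' intra-burst interval. Whenever bursts are generated, silent guards are
#' enforced so that detection under [sim_burst_criteria()] recovers the
#' ground truth exactly: no spike falls within `pre_burst_silence_ms` of a
#' burst boundary, and tonic spikes closer than the intra-burst interval to
#' their predecessor are removed so no tonic chain qualifies as a burst.
#'
#' @param hyp A [hypnogram()].
#' @param params A [sim_params()].
#' @param unit_id,region Labels for the returned [spike_train()].
#' @return List with `train` (a [spike_train()]) and `bursts` (data frame
#'   `start_s`, `n_spikes`, `dur_ms` of injected bursts).
#' @export
simulate_spike_train <- function(hyp, params, unit_id = "u1", region = "TRN") {
  stopifnot(inherits(hyp, "hypnogram"), inherits(params, "sim_params"))
  set.seed(sub_seed(params$seed, paste0("unit_", unit_id)))
  runs <- label_runs(hyp$labels)
  runs <- runs[runs$state != "Artifact", , drop = FALSE]
  silence_s <- params$pre_burst_silence_ms / 1000
  isi_s <- params$intraburst_isi_ms / 1000
  max_span <- (params$spikes_per_burst[2] - 1) * isi_s

  ## 1) bursts, with mutual separation >= pre-burst silence on both sides
  b_start <- numeric(0); b_n <- integer(0)
  for (r in seq_len(nrow(runs))) {
    r0 <- (runs$start[r] - 1) * hyp$epoch_s
    len <- runs$len[r] * hyp$epoch_s
    rate <- params$burst_rate_per_min[[runs$state[r]]] / 60
    m <- stats::rpois(1, rate * len)
    if (m == 0 || len <= max_span + 2 * silence_s) next
    for (i in seq_len(m)) {
      for (attempt in 1:50) {
        s0 <- stats::runif(1, r0 + silence_s, r0 + len - max_span - silence_s)
        nb <- sample(params$spikes_per_burst[1]:params$spikes_per_burst[2], 1)
        e0 <- s0 + (nb - 1) * isi_s
        ok <- !length(b_start) ||
          all(s0 - (b_start + (b_n - 1) * isi_s) > 2 * silence_s |
              b_start - e0 > 2 * silence_s)
        if (ok) { b_start <- c(b_start, s0); b_n <- c(b_n, nb); break }
      }
    }
  }
  ord <- order(b_start)
  b_start <- b_start[ord]; b_n <- b_n[ord]
  burst_spikes <- unlist(lapply(seq_along(b_start), function(i) {
    b_start[i] + (seq_len(b_n[i]) - 1) * isi_s
  })) %||% numeric(0)

  ## 2) tonic spikes, excluded from guard zones around bursts
  tonic <- unlist(lapply(seq_len(nrow(runs)), function(r) {
    r0 <- (runs$start[r] - 1) * hyp$epoch_s
    len <- runs$len[r] * hyp$epoch_s
    rate <- params$tonic_rate_hz[[runs$state[r]]]
    k <- stats::rpois(1, rate * len)
    sort(stats::runif(k, r0, r0 + len))
  })) %||% numeric(0)
  if (length(b_start)) {
    b_end <- b_start + (b_n - 1) * isi_s
    keep <- vapply(tonic, function(x) {
      all(x < b_start - silence_s | x > b_end + silence_s)
    }, logical(1))
    tonic <- tonic[keep]
  }

  ## 3) merge; when bursts exist, thin tonic chains so none can qualify as
  ## a burst under the generating criteria
  pool <- c(tonic, burst_spikes)
  ord <- order(pool)
  all_t <- pool[ord]
  is_burst <- (seq_along(pool) > length(tonic))[ord]
  if (length(b_start) && length(all_t) > 1) {
    keep <- logical(length(all_t))
    last <- -Inf
    for (i in seq_along(all_t)) {
      if (is_burst[i] || all_t[i] - last > isi_s) {
        keep[i] <- TRUE
        last <- all_t[i]
      }
    }
    all_t <- all_t[keep]
  }
  all_t <- all_t[!duplicated(all_t)]
  bursts <- data.frame(start_s = b_start, n_spikes = b_n,
                       dur_ms = (b_n - 1) * params$intraburst_isi_ms)
  list(train = spike_train(all_t, unit_id = unit_id, region = region),
       bursts = bursts)
}
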