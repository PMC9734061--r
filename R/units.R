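# State-resolved single-unit metrics: the spike-band filtering contract
# (sorted spike times are consumed, not produced), per-state firing rates,
# peri-transition rate histograms and burst detection with the thalamic
# T-type burst definition (short intra-burst intervals after a silent
# period).

#' Spike-band filter (600-4000 Hz elliptic band-pass)
#'
#' Fourth-order elliptic band-pass, 0.1 dB passband ripple and 40 dB
#' stopband attenuation, 600-4000 Hz, applied zero-phase (forward and
#' backward).
#'
#' @param x Raw wideband signal.
#' @param fs Sampling rate (Hz); must exceed 8000 Hz.
#' @return Filtered signal, same length.
#' @export
spike_band_filter <- function(x, fs) {
  if (fs <= 2 * 4000) stop("Nyquist error: fs must exceed 8000 Hz")
  flt <- spike_band_design(fs)
  signal::filtfilt(flt, x)
}

## The filter design itself, exposed internally so its frequency response
## can be examined without applying it.
spike_band_design <- function(fs) {
  signal::ellip(4, 0.1, 40, c(600, 4000) / (fs / 2), type = "pass")
}

#' Burst criteria
#'
#' The thalamic T-type burst definition: at least `min_spikes` spikes with
#' inter-spike intervals of at most `max_intraburst_isi_ms`, preceded by a
#' silent period of at least `min_preceding_silence_ms`.
#'
#' @param max_intraburst_isi_ms Maximum intra-burst ISI (ms, default 10).
#' @param min_spikes Minimum spikes per burst (default 2).
#' @param min_preceding_silence_ms Minimum pre-burst silence (ms, default
#'   100); must exceed the intra-burst ISI.
#' @return Object of class `burst_criteria`.
#' @export
burst_criteria <- function(max_intraburst_isi_ms = 10, min_spikes = 2,
                           min_preceding_silence_ms = 100) {
  if (max_intraburst_isi_ms <= 0 || min_preceding_silence_ms <= 0 ||
      min_spikes < 2) {
    stop("criteria must be positive with min_spikes >= 2")
  }
  if (min_preceding_silence_ms <= max_intraburst_isi_ms) {
    stop("min_preceding_silence_ms must exceed max_intraburst_isi_ms")
  }
  structure(list(max_intraburst_isi_ms = max_intraburst_isi_ms,
                 min_spikes = min_spikes,
                 min_preceding_silence_ms = min_preceding_silence_ms),
            class = "burst_criteria")
}

#' Detect bursts in a spike train
#'
#' Single left-to-right scan: a burst starts at a spike preceded by
#' silence of at least the criterion (the first spike of a train counts
#' as preceded by silence) whose next inter-spike interval is within the
#' intra-burst maximum, extends while ISIs stay within that maximum, and
#' is kept when it contains at least `min_spikes` spikes. Returned bursts
#' are disjoint.
#'
#' @param train A [spike_train()] or numeric vector of spike times (s).
#' @param criteria A [burst_criteria()].
#' @return Burst event data frame: `start_s`, `n_spikes`, `dur_ms`
#'   (first-to-last spike).
#' @export
detect_bursts <- function(train, criteria = burst_criteria()) {
  t <- if (inherits(train, "spike_train")) train$times_s else as.numeric(train)
  n <- length(t)
  if (n < criteria$min_spikes) return(empty_events("burst"))
  ## 1 ns grace on the criteria so regularly spaced trains are not split
  ## by floating-point representation of their intervals
  max_isi <- criteria$max_intraburst_isi_ms / 1000 + 1e-9
  silence <- criteria$min_preceding_silence_ms / 1000 - 1e-9
  gaps <- c(Inf, diff(t))
  out_start <- numeric(0); out_n <- integer(0); out_dur <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (gaps[i] >= silence && i < n && gaps[i + 1L] <= max_isi) {
      j <- i
      while (j < n && gaps[j + 1L] <= max_isi) j <- j + 1L
      if (j - i + 1L >= criteria$min_spikes) {
        out_start <- c(out_start, t[i])
        out_n <- c(out_n, j - i + 1L)
        out_dur <- c(out_dur, (t[j] - t[i]) * 1000)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start_s = out_start, n_spikes = out_n, dur_ms = out_dur)
}

#' Per-state firing rates
#'
#' Spike count in each state's epochs divided by time in that state,
#' within a window. States with zero time get `NA`.
#'
#' @param train A [spike_train()] or numeric spike times (s).
#' @param hyp A [hypnogram()].
#' @param window Length-2 `(start_s, end_s)`; defaults to the whole
#'   hypnogram.
#' @return Named numeric vector of rates (spikes/s) for Wake, NREM, REM.
#' @export
state_firing_rate <- function(train, hyp,
                              window = c(0, hypnogram_duration_s(hyp))) {
  t <- if (inherits(train, "spike_train")) train$times_s else as.numeric(train)
  t <- t[t >= window[1] & t < window[2]]
  lab <- spike_state(t, hyp)
  ep_t <- (seq_along(hyp$labels) - 1) * hyp$epoch_s
  in_win <- ep_t >= window[1] & ep_t < window[2]
  vapply(c(Wake = "Wake", NREM = "NREM", REM = "REM"), function(s) {
    dur <- sum(hyp$labels[in_win] == s) * hyp$epoch_s
    if (dur == 0) NA_real_ else sum(lab == s) / dur
  }, numeric(1))
}

## vigilance label of the epoch containing each spike time
spike_state <- function(t, hyp) {
  idx <- floor(t / hyp$epoch_s) + 1L
  idx <- pmin(pmax(idx, 1L), length(hyp$labels))
  hyp$labels[idx]
}

#' Peri-transition time histogram of firing rate
#'
#' Aligns spikes to every qualifying state transition (a boundary whose
#' flanking runs of the from- and to-states each last at least
#' `min_flank_s`) and returns per-bin rates averaged over transitions.
#'
#' @param train A [spike_train()] or numeric spike times (s).
#' @param hyp A [hypnogram()].
#' @param transition Length-2 character `(from, to)`, default Wake->NREM.
#' @param window_s Length-2 `(pre, post)` seconds around the transition.
#' @param bin_s Bin width (s); bins must tile the window exactly.
#' @param min_flank_s Minimum duration of both flanking runs (s).
#' @return Object of class `transition_peth`: `bin_start_s` (left edges,
#'   transition at 0), `rate` (spikes/s), `n_transitions`, `transition`.
#' @export
transition_peth <- function(train, hyp, transition = c("Wake", "NREM"),
                            window_s = c(20, 20), bin_s = 1,
                            min_flank_s = 20) {
  t <- if (inherits(train, "spike_train")) train$times_s else as.numeric(train)
  k_pre <- window_s[1] / bin_s
  k_post <- window_s[2] / bin_s
  if (abs(k_pre - round(k_pre)) > 1e-9 || abs(k_post - round(k_post)) > 1e-9) {
    stop("bins must tile the window exactly")
  }
  runs <- label_runs(hyp$labels)
  trans_t <- numeric(0)
  if (nrow(runs) > 1) {
    for (i in seq_len(nrow(runs) - 1L)) {
      if (runs$state[i] == transition[1] && runs$state[i + 1L] == transition[2] &&
          runs$len[i] * hyp$epoch_s >= min_flank_s &&
          runs$len[i + 1L] * hyp$epoch_s >= min_flank_s) {
        trans_t <- c(trans_t, (runs$start[i + 1L] - 1L) * hyp$epoch_s)
      }
    }
  }
  if (!length(trans_t)) {
    stop("insufficient events: no qualifying ", transition[1], "->",
         transition[2], " transitions")
  }
  edges <- seq(-window_s[1], window_s[2], by = bin_s)
  counts <- numeric(length(edges) - 1L)
  for (tt in trans_t) {
    rel <- t[t >= tt - window_s[1] & t < tt + window_s[2]] - tt
    counts <- counts + tabulate(floor((rel + window_s[1]) / bin_s) + 1L,
                                nbins = length(counts))
  }
  structure(
    list(bin_start_s = edges[-length(edges)],
         rate = counts / (length(trans_t) * bin_s),
         n_transitions = length(trans_t),
         transition = transition, bin_s = bin_s),
    class = "transition_peth"
  )
}

#' Burst statistics over a window
#'
#' Burst density per minute of a state (bursts assigned to states by
#' their onset epoch) and mean burst length in spikes and milliseconds.
#'
#' @param bursts Burst table from [detect_bursts()].
#' @param hyp A [hypnogram()].
#' @param window Length-2 `(start_s, end_s)`; defaults to the whole
#'   hypnogram.
#' @param state Vigilance state (default NREM).
#' @return One-row data frame: `n_bursts`, `density_per_min`,
#'   `mean_spikes`, `mean_dur_ms`.
#' @export
burst_stats <- function(bursts, hyp,
                        window = c(0, hypnogram_duration_s(hyp)),
                        state = "NREM") {
  ep_t <- (seq_along(hyp$labels) - 1) * hyp$epoch_s
  in_win <- ep_t >= window[1] & ep_t < window[2]
  state_min <- sum(hyp$labels[in_win] == state) * hyp$epoch_s / 60
  if (state_min == 0) stop("undefined density: no ", state, " time in window")
  sel <- bursts$start_s >= window[1] & bursts$start_s < window[2] &
    spike_state(bursts$start_s, hyp) == state
  b <- bursts[sel, , drop = FALSE]
  data.frame(
    n_bursts = nrow(b),
    density_per_min = nrow(b) / state_min,
    mean_spikes = if (nrow(b)) mean(b$n_spikes) else NA_real_,
    mean_dur_ms = if (nrow(b)) mean(b$dur_ms) else NA_real_
  )
}
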