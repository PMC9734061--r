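# Shared domain containers: recordings, hypnograms, frequency bands,
# event tables and spike trains. All event times are seconds from recording
# start; intervals are half-open [start_s, end_s). Zeitgeber time is stored
# only on the recording (t0_zt, hours after lights-on).

CHANNEL_ROLES <- c("EEG_front", "EEG_par", "ACC", "AD", "TRN", "Brr", "VPL", "EMG")

#' Construct a multichannel recording
#'
#' A recording holds a sample matrix (microvolts) with one column per
#' channel, the sampling rate, per-channel role tags and the start time in
#' Zeitgeber hours (ZT, lights-on = ZT0).
#'
#' @param signals Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of channel labels (one per column).
#' @param roles Character vector of channel roles, from
#'   `c("EEG_front","EEG_par","ACC","AD","TRN","Brr","VPL","EMG")`. Each role
#'   must be unique within a recording.
#' @param t0_zt Recording start in Zeitgeber hours.
#' @return An object of class `recording`.
#' @export
recording <- function(signals, fs, labels, roles, t0_zt = 0) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("signals must be numeric")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a single positive number")
  if (length(labels) != ncol(signals)) stop("one label per channel required")
  if (length(roles) != ncol(signals)) stop("one role per channel required")
  bad <- setdiff(roles, CHANNEL_ROLES)
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(roles)) stop("duplicate channel roles: ", paste(roles[duplicated(roles)], collapse = ", "))
  colnames(signals) <- labels
  structure(
    list(signals = signals, fs = fs, labels = as.character(labels),
         roles = as.character(roles), t0_zt = t0_zt),
    class = "recording"
  )
}

#' Recording duration in seconds
#' @param rec A `recording`.
#' @return Duration in seconds (`n_samples / fs`).
#' @export
duration_s <- function(rec) nrow(rec$signals) / rec$fs

#' Extract one channel of a recording by role
#' @param rec A `recording`.
#' @param role A channel role tag (e.g. `"EEG_front"`).
#' @return Numeric vector of samples (microvolts).
#' @export
channel <- function(rec, role) {
  i <- match(role, rec$roles)
  if (is.na(i)) stop("recording has no channel with role '", role, "'")
  rec$signals[, i]
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), t0 = ZT%.2f\n",
              ncol(x$signals), nrow(x$signals), x$fs, duration_s(x), x$t0_zt))
  cat("  channels:", paste(sprintf("%s[%s]", x$labels, x$roles), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a hypnogram
#'
#' Per-epoch vigilance-state labels over the four-symbol alphabet
#' Wake / NREM / REM / Artifact, with a fixed epoch length (1 s scoring
#' epochs by default).
#'
#' @param labels Character vector of state labels.
#' @param epoch_s Epoch length in seconds (> 0, default 1).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_s = 1) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), VIGILANCE_STATES)
  if (length(bad)) {
    stop("unknown vigilance label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(VIGILANCE_STATES, collapse = ", "))
  }
  if (!is.numeric(epoch_s) || length(epoch_s) != 1 || epoch_s <= 0) {
    stop("epoch_s must be a single positive number")
  }
  structure(list(labels = labels, epoch_s = epoch_s), class = "hypnogram")
}

#' Hypnogram duration in seconds
#' @param hyp A `hypnogram`.
#' @return `length(labels) * epoch_s`.
#' @export
hypnogram_duration_s <- function(hyp) length(hyp$labels) * hyp$epoch_s

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = VIGILANCE_STATES))
  cat(sprintf("<hypnogram> %d epochs x %g s (%.1f min)\n",
              length(x$labels), x$epoch_s, hypnogram_duration_s(x) / 60))
  print(tab)
  invisible(x)
}

#' Check that a hypnogram and a recording cover the same span
#'
#' Fails loudly when the two durations disagree by more than one scoring
#' epoch, which almost always indicates mismatched files.
#'
#' @param hyp A `hypnogram`.
#' @param rec A `recording`.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_pairing <- function(hyp, rec) {
  dh <- hypnogram_duration_s(hyp)
  dr <- duration_s(rec)
  if (abs(dh - dr) > hyp$epoch_s) {
    stop(sprintf("hypnogram (%.1f s) and recording (%.1f s) differ by more than one epoch", dh, dr))
  }
  invisible(TRUE)
}

## Per-sample state label vector for a recording paired with `hyp`.
sample_states <- function(hyp, n_samples, fs) {
  idx <- pmin(floor((seq_len(n_samples) - 1) / fs / hyp$epoch_s) + 1L, length(hyp$labels))
  hyp$labels[idx]
}

#' Define a frequency band
#'
#' @param name Band name (e.g. `"swa"`).
#' @param lo_hz,hi_hz Band edges in Hz, `0 <= lo_hz < hi_hz`.
#' @return An object of class `band`.
#' @export
band <- function(name, lo_hz, hi_hz) {
  if (!(lo_hz >= 0 && lo_hz < hi_hz)) stop("band edges must satisfy 0 <= lo_hz < hi_hz")
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz), class = "band")
}

#' Canonical analysis bands
#'
#' Slow-wave activity (0.5-4 Hz), its sub-bands delta1 (0.75-1.75 Hz) and
#' delta2 (2.75-3.5 Hz; a 2.5 Hz lower-edge variant is used in parts of the
#' literature and is available as `delta2_alt`), the spindle band
#' (10-16 Hz) and REM theta (6-9 Hz).
#'
#' @return Named list of `band` objects.
#' @export
default_bands <- function() {
  list(
    swa = band("swa", 0.5, 4),
    delta1 = band("delta1", 0.75, 1.75),
    delta2 = band("delta2", 2.75, 3.5),
    delta2_alt = band("delta2_alt", 2.5, 3.5),
    spindle = band("spindle", 10, 16),
    theta = band("theta", 6, 9)
  )
}

#' Construct a spike train
#'
#' @param times_s Strictly increasing spike times in seconds.
#' @param unit_id Unit identifier.
#' @param region Recording-site label (e.g. `"TRN"`).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, unit_id = "u1", region = "TRN") {
  times_s <- as.numeric(times_s)
  if (length(times_s) > 1 && any(diff(times_s) <= 0)) {
    stop("spike times must be strictly increasing")
  }
  structure(list(unit_id = unit_id, region = region, times_s = times_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s (%s): %d spikes", x$unit_id, x$region, length(x$times_s)))
  if (length(x$times_s)) cat(sprintf(" over %.1f s", diff(range(x$times_s))))
  cat("\n")
  invisible(x)
}

## Event-table schemas (stable column order for on-disk CSVs).
EVENT_SCHEMAS <- list(
  spindle = c("channel", "start_s", "end_s", "dur_s", "peak_s",
              "peak_amp_uv", "peak_freq_hz", "energy", "transition"),
  burst = c("start_s", "n_spikes", "dur_ms"),
  episode = c("state", "start_s", "dur_s")
)

empty_events <- function(kind) {
  cols <- EVENT_SCHEMAS[[kind]]
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  if ("channel" %in% cols) df$channel <- character(0)
  if ("state" %in% cols) df$state <- character(0)
  if ("transition" %in% cols) df$transition <- logical(0)
  df
}

event_kind <- function(events) {
  for (k in names(EVENT_SCHEMAS)) {
    if (setequal(names(events), EVENT_SCHEMAS[[k]])) return(k)
  }
  stop("unrecognized or mixed event table: columns [",
       paste(names(events), collapse = ", "), "] match no known event kind")
}
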