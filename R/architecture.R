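# Sleep-architecture metrics from a hypnogram: episode segmentation with
# optional absorption of brief interruptions, per-state episode counts and
# durations, latencies to the first consolidated episode of a state, and
# binned time-in-state series. Artifact epochs always break runs and are
# excluded from percent-time denominators unless requested.

#' Segment a hypnogram into vigilance-state episodes
#'
#' Maximal runs of identical labels become episodes. Runs of a different
#' state shorter than `interruption_s` that are flanked by the same state
#' on both sides are absorbed into the surrounding episode (applied
#' repeatedly until stable); Artifact runs are never absorbed and always
#' break episodes. Surviving episodes shorter than `min_dur_s` are dropped
#' from the returned list (their time still counts toward time-in-state
#' percentages, which are computed from epoch labels).
#'
#' @param hyp A [hypnogram()].
#' @param min_dur_s Minimum episode duration retained (s); 0 keeps all.
#' @param interruption_s Interruptions shorter than this are absorbed (s);
#'   0 disables absorption.
#' @return Data frame with columns `state`, `start_s`, `dur_s`.
#' @export
segment_episodes <- function(hyp, min_dur_s = 0, interruption_s = 0) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (min_dur_s > 0 && min_dur_s < hyp$epoch_s) {
    stop("min_dur_s must be 0 or >= the epoch length")
  }
  labels <- hyp$labels
  if (interruption_s > 0) {
    repeat {
      runs <- label_runs(labels)
      changed <- FALSE
      if (nrow(runs) >= 3) {
        for (i in 2:(nrow(runs) - 1)) {
          if (runs$state[i] != "Artifact" &&
              runs$len[i] * hyp$epoch_s < interruption_s &&
              runs$state[i - 1] == runs$state[i + 1] &&
              runs$state[i - 1] != runs$state[i] &&
              runs$state[i - 1] != "Artifact") {
            sel <- runs$start[i]:(runs$start[i] + runs$len[i] - 1L)
            labels[sel] <- runs$state[i - 1]
            changed <- TRUE
            break
          }
        }
      }
      if (!changed) break
    }
  }
  runs <- label_runs(labels)
  ep <- data.frame(
    state = runs$state,
    start_s = (runs$start - 1) * hyp$epoch_s,
    dur_s = runs$len * hyp$epoch_s,
    stringsAsFactors = FALSE
  )
  ep[ep$dur_s >= max(min_dur_s, 0), , drop = FALSE]
}

#' Summarize sleep architecture over a time window
#'
#' Episodes per hour (episodes are counted in the window containing their
#' start), mean episode duration, and percent time in each vigilance state
#' computed from epoch labels. Artifact epochs are excluded from the
#' percent-time denominator unless `include_artifact` is set, so
#' Wake + NREM + REM percentages sum to 100 in artifact-free data.
#'
#' @param episodes Episode table from [segment_episodes()].
#' @param hyp The [hypnogram()] the episodes were derived from.
#' @param window Length-2 numeric `(start_s, end_s)`; defaults to the whole
#'   hypnogram.
#' @param include_artifact Count Artifact time in the denominator?
#' @return Data frame with one row per state (Wake, NREM, REM):
#'   `episodes_per_h`, `mean_episode_dur_s`, `percent_time`; the window is
#'   attached as attribute `"window"`.
#' @export
architecture_summary <- function(episodes, hyp,
                                 window = c(0, hypnogram_duration_s(hyp)),
                                 include_artifact = FALSE) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be (start_s, end_s) with end > start")
  }
  hours <- (window[2] - window[1]) / 3600
  ep_t <- (seq_along(hyp$labels) - 1) * hyp$epoch_s
  in_win <- ep_t >= window[1] & ep_t < window[2]
  lab_w <- hyp$labels[in_win]
  denom <- if (include_artifact) length(lab_w) else sum(lab_w != "Artifact")
  states <- c("Wake", "NREM", "REM")
  out <- do.call(rbind, lapply(states, function(s) {
    e <- episodes[episodes$state == s &
                    episodes$start_s >= window[1] &
                    episodes$start_s < window[2], , drop = FALSE]
    data.frame(
      state = s,
      episodes_per_h = nrow(e) / hours,
      mean_episode_dur_s = if (nrow(e)) mean(e$dur_s) else NA_real_,
      percent_time = if (denom > 0) 100 * sum(lab_w == s) / denom else NA_real_
    )
  }))
  attr(out, "window") <- window
  out
}

#' Latency to the first consolidated episode of a state
#'
#' Time from `ref_s` to the start of the first run of `state` lasting at
#' least `min_stable_s` (the >20 s stability rule used for consolidated
#' NREM sleep; the same rule is applied to REM by default). Runs already in
#' progress at `ref_s` count from `ref_s` with their remaining duration.
#'
#' @param hyp A [hypnogram()].
#' @param state Target state.
#' @param ref_s Reference time (s from recording start).
#' @param min_stable_s Minimum run duration to count as consolidated (s).
#' @return Latency in seconds, or `NA_real_` if no such episode is
#'   observed (never 0 for an absent state).
#' @export
latency_to_state <- function(hyp, state = "NREM", ref_s = 0, min_stable_s = 20) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (min_stable_s < hyp$epoch_s) stop("min_stable_s must be >= the epoch length")
  if (ref_s < 0 || ref_s >= hypnogram_duration_s(hyp)) {
    stop("ref_s must lie within the hypnogram")
  }
  ref_ep <- floor(ref_s / hyp$epoch_s) + 1L
  runs <- label_runs(hyp$labels)
  for (i in seq_len(nrow(runs))) {
    r_end <- runs$start[i] + runs$len[i] - 1L
    if (r_end < ref_ep || runs$state[i] != state) next
    eff_start <- max(runs$start[i], ref_ep)
    eff_len_s <- (r_end - eff_start + 1L) * hyp$epoch_s
    if (eff_len_s >= min_stable_s) {
      return((eff_start - 1L) * hyp$epoch_s - ref_s)
    }
  }
  NA_real_
}

#' Binned time course of percent time in a state
#'
#' @param hyp A [hypnogram()].
#' @param state Target state.
#' @param bin_s Bin width (s), a multiple of the epoch length.
#' @return Data frame with `bin_start_s` and `percent` (share of scored,
#'   i.e. non-Artifact, epochs in the bin spent in `state`; `NA` for bins
#'   that are entirely Artifact).
#' @export
timecourse_percent_state <- function(hyp, state = "NREM", bin_s = 3600) {
  stopifnot(inherits(hyp, "hypnogram"))
  k <- bin_s / hyp$epoch_s
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("bin_s must be a positive multiple of the epoch length")
  }
  k <- as.integer(round(k))
  n <- length(hyp$labels)
  n_bins <- ceiling(n / k)
  bin_idx <- factor((seq_len(n) - 1L) %/% k, levels = 0:(n_bins - 1L))
  num <- as.numeric(tapply(hyp$labels == state, bin_idx, sum))
  den <- as.numeric(tapply(hyp$labels != "Artifact", bin_idx, sum))
  data.frame(
    bin_start_s = (0:(n_bins - 1L)) * k * hyp$epoch_s,
    percent = ifelse(den > 0, 100 * num / den, NA_real_),
    row.names = NULL
  )
}
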