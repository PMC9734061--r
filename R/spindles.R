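# Automated spindle detection from band-restricted wavelet energy, plus
# per-state spindle statistics. Detection is amplitude-scale invariant:
# thresholds act on NREM-normalized energy, so rescaling the signal leaves
# event times unchanged and scales amplitude statistics linearly.

## contiguous TRUE runs of a logical vector as (start, end) sample indices
true_runs <- function(z) {
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect sleep spindles
#'
#' Candidate events are contiguous runs of smoothed normalized wavelet
#' energy above the low threshold that contain at least one sample above
#' the high threshold (hysteresis); candidates closer than `merge_gap_s`
#' are merged. Event boundaries are then refined from the width of the
#' energy peak at one quarter of its height above baseline (the NREM
#' median), which for a waxing-and-waning envelope estimates the full
#' event duration independently of amplitude. Events are kept when their
#' refined duration lies within the configured bounds and at least half of
#' the event overlaps NREM epochs; events not fully inside NREM (e.g. at
#' NREM-to-REM transitions) are retained with `transition = TRUE`.
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate (Hz).
#' @param hyp A [hypnogram()] paired with `x` (NREM epochs required).
#' @param params A [spindle_params()].
#' @param channel Channel label written into the event table.
#' @return Spindle event data frame: `channel`, `start_s`, `end_s`,
#'   `dur_s`, `peak_s` (energy peak), `peak_amp_uv` (peak-to-trough of the
#'   band-filtered signal), `peak_freq_hz` (center frequency of maximal
#'   wavelet energy), `energy` (mean normalized energy), `transition`.
#' @export
detect_spindles <- function(x, fs, hyp, params = spindle_params(),
                            channel = "EEG_front") {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(x)
  st <- sample_states(hyp, n, fs)
  nrem <- st == "NREM"
  if (!any(nrem)) stop("insufficient data: hypnogram contains no NREM epochs")

  en <- spindle_energy(x, fs, params, hyp)
  e <- en$energy
  mu <- mean(e[nrem])
  sdv <- stats::sd(e[nrem])
  hi <- mu + params$thresh_hi_sd * sdv
  lo <- mu + params$thresh_lo_sd * sdv
  baseline <- stats::median(e[nrem])

  cand <- true_runs(e > lo)
  if (nrow(cand)) {
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      any(e[cand[i, 1]:cand[i, 2]] > hi)
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  ## merge candidates separated by less than merge_gap_s
  if (nrow(cand) > 1) {
    gap <- (cand[-1, 1] - cand[-nrow(cand), 2]) / fs
    grp <- cumsum(c(0, gap >= params$merge_gap_s))
    cand <- do.call(rbind, lapply(split(seq_len(nrow(cand)), grp), function(ii) {
      c(start = cand[ii[1], 1], end = cand[ii[length(ii)], 2])
    }))
  }
  if (!nrow(cand)) return(empty_events("spindle"))

  ## quarter-maximum boundary refinement. The measured width is corrected
  ## (in quadrature) for the wavelet's own temporal smearing: a narrowband
  ## burst is blurred by the wavelet envelope, a Gaussian of
  ## sigma_t = n_cycles / (2 pi f_center), and by the boxcar smoothing.
  max_walk <- as.integer(params$max_dur_s * fs)
  f_ctr <- (params$bnd$lo_hz + params$bnd$hi_hz) / 2
  w_psf <- 2 * sqrt(2 * log(2)) * params$n_cycles / (2 * pi * f_ctr)
  w_sm <- 2.355 * params$smooth_s / sqrt(12)
  ref <- matrix(NA_real_, nrow = nrow(cand), ncol = 3) # start_s, end_s, peak idx
  for (i in seq_len(nrow(cand))) {
    seg <- cand[i, 1]:cand[i, 2]
    ip <- seg[which.max(e[seg])]
    level <- baseline + 0.25 * (e[ip] - baseline)
    l <- ip
    while (l > 1 && ip - l < max_walk && e[l - 1] >= level) l <- l - 1
    r <- ip
    while (r < n && r - ip < max_walk && e[r + 1] >= level) r <- r + 1
    w_meas <- (r - l) / fs # quarter-max-energy width = half the duration
    w_corr <- sqrt(max(w_meas^2 - w_psf^2 - w_sm^2, (1 / fs)^2))
    ctr <- (l + r - 2) / 2 / fs
    ref[i, ] <- c(ctr - w_corr, ctr + w_corr, ip)
  }
  ## merge any refined events that overlap, keeping events disjoint
  ord <- order(ref[, 1])
  ref <- ref[ord, , drop = FALSE]
  merged <- list()
  cur <- ref[1, ]
  for (i in seq_len(nrow(ref))[-1]) {
    if (ref[i, 1] <= cur[2]) {
      cur[2] <- max(cur[2], ref[i, 2])
      if (e[ref[i, 3]] > e[cur[3]]) cur[3] <- ref[i, 3]
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- ref[i, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  ref <- do.call(rbind, merged)

  start_s <- pmax(ref[, 1], 0)
  end_s <- pmin(ref[, 2], n / fs)
  dur <- end_s - start_s
  keep <- dur >= params$min_dur_s & dur <= params$max_dur_s
  ## state assignment: >= 50% of the event in NREM
  nrem_frac <- vapply(seq_along(start_s), function(i) {
    i0 <- max(1L, floor(start_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(end_s[i] * fs))
    mean(nrem[i0:i1])
  }, numeric(1))
  keep <- keep & nrem_frac >= 0.5
  if (!any(keep)) return(empty_events("spindle"))
  start_s <- start_s[keep]; end_s <- end_s[keep]; dur <- dur[keep]
  ipk <- as.integer(ref[keep, 3]); nrem_frac <- nrem_frac[keep]

  bp <- signal::butter(4, c(params$bnd$lo_hz, params$bnd$hi_hz) / (fs / 2),
                       type = "pass")
  xf <- signal::filtfilt(bp, x)
  peak_amp <- numeric(length(start_s))
  peak_freq <- numeric(length(start_s))
  mean_en <- numeric(length(start_s))
  for (i in seq_along(start_s)) {
    i0 <- max(1L, floor(start_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(end_s[i] * fs))
    peak_amp[i] <- max(xf[i0:i1]) - min(xf[i0:i1])
    prof <- rowMeans(en$energy_mat[, i0:i1, drop = FALSE])
    peak_freq[i] <- en$freqs_hz[which.max(prof)]
    mean_en[i] <- mean(e[i0:i1])
  }
  data.frame(
    channel = channel, start_s = start_s, end_s = end_s, dur_s = dur,
    peak_s = (ipk - 1) / fs, peak_amp_uv = peak_amp,
    peak_freq_hz = peak_freq, energy = mean_en,
    transition = nrem_frac < 1,
    row.names = NULL
  )
}

#' Spindle statistics over a window
#'
#' Rate per minute of NREM (denominator: NREM epochs within the window),
#' mean peak-to-trough amplitude and mean length over events starting in
#' the window.
#'
#' @param events Spindle event table from [detect_spindles()].
#' @param hyp The paired [hypnogram()].
#' @param window Length-2 `(start_s, end_s)`; defaults to the whole
#'   hypnogram.
#' @return One-row data frame: `n_events`, `rate_per_min`,
#'   `mean_amp_uv`, `mean_dur_s` (means are `NA` when no events).
#' @export
spindle_stats <- function(events, hyp,
                          window = c(0, hypnogram_duration_s(hyp))) {
  stopifnot(inherits(hyp, "hypnogram"))
  ep_t <- (seq_along(hyp$labels) - 1) * hyp$epoch_s
  in_win <- ep_t >= window[1] & ep_t < window[2]
  nrem_min <- sum(hyp$labels[in_win] == "NREM") * hyp$epoch_s / 60
  if (nrem_min == 0) stop("undefined rate: no NREM time in the window")
  ev <- events[events$start_s >= window[1] & events$start_s < window[2], ,
               drop = FALSE]
  data.frame(
    n_events = nrow(ev),
    rate_per_min = nrow(ev) / nrem_min,
    mean_amp_uv = if (nrow(ev)) mean(ev$peak_amp_uv) else NA_real_,
    mean_dur_s = if (nrow(ev)) mean(ev$dur_s) else NA_real_
  )
}
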