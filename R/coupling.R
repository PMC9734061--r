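# Slow-wave / spindle coupling. Within a region: normalized
# cross-correlation between slow-wave peaks and the spindle envelope.
# Across regions: phase-amplitude coupling (PAC) summarized by the
# Tort-style normalized-entropy modulation index over phase bins, with
# comodulograms over (phase frequency, amplitude frequency) grids,
# circular-shift surrogate calibration, and slow-oscillation phase
# sampled at spindle peaks of a second region.
#
# Phase convention everywhere: filtered-signal trough = 0 degrees, peak =
# 180 degrees, phase increasing through the cycle.

#' Instantaneous phase and envelope in a band
#'
#' Zero-phase Butterworth band-pass (order 4) followed by the analytic
#' signal. For low or narrow bands relative to the sampling rate the
#' signal is first decimated (anti-aliased) so the filter stays well
#' conditioned, and phase/envelope are interpolated back to the original
#' grid; this leaves slow-band phase estimates unchanged while avoiding
#' numerically singular filter designs.
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate (Hz); must be at least 4 x the band's upper edge.
#' @param bnd A [band()].
#' @param order Butterworth order (default 4).
#' @return List: `phase_deg` (trough = 0, peak = 180), `envelope` (uV),
#'   `filtered` (band-passed signal, uV), `fs`.
#' @export
extract_phase_envelope <- function(x, fs, bnd, order = 4) {
  stopifnot(inherits(bnd, "band"))
  if (fs < 4 * bnd$hi_hz) {
    stop("band degenerate for this sampling rate: need fs >= 4 x hi_hz")
  }
  if (bnd$lo_hz <= 0) stop("band lower edge must be > 0 for phase extraction")
  n <- length(x)
  fac <- max(1L, as.integer(floor(fs / max(20, 10 * bnd$hi_hz))))
  if (fac > 1L) {
    aa <- signal::butter(4, 0.8 / fac, type = "low")
    xd <- signal::filtfilt(aa, x)[seq(1L, n, by = fac)]
    fsd <- fs / fac
  } else {
    xd <- x
    fsd <- fs
  }
  bp <- signal::butter(order, c(bnd$lo_hz, bnd$hi_hz) / (fsd / 2), type = "pass")
  xf <- signal::filtfilt(bp, xd)
  a <- analytic_signal(xf)
  ph <- Arg(a) # 0 at filtered-signal peak
  env <- Mod(a)
  if (fac > 1L) {
    td <- (seq_along(xd) - 1) / fsd
    t_full <- (seq_len(n) - 1) / fs
    phu <- signal::unwrap(ph)
    ph <- stats::approx(td, phu, xout = t_full, rule = 2)$y
    env <- stats::approx(td, env, xout = t_full, rule = 2)$y
    xf <- stats::approx(td, xf, xout = t_full, rule = 2)$y
  }
  list(phase_deg = (rad2deg(ph) + 180) %% 360, envelope = env,
       filtered = xf, fs = fs)
}

## Normalized (Pearson) cross-correlation between two equal-length series
## on the same grid, evaluated at integer lags -L..L of `b` relative to
## `a` (positive lag: features of b occur later than in a).
xcorr_lagged <- function(a, b, L) {
  n <- length(a)
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- 1:(n - l); ib <- (1 + l):n
    } else {
      ia <- (1 - l):n; ib <- 1:(n + l)
    }
    sa <- a[ia]; sb <- b[ib]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(NA_real_)
    stats::cor(sa, sb)
  }, numeric(1))
  list(lags = lags, cc = cc)
}

#' Slow-wave-peak-triggered spindle-envelope cross-correlation
#'
#' Detects slow-wave peaks (local maxima of the SW-band signal within NREM
#' exceeding an amplitude percentile), averages the SW-band signal and the
#' spindle envelope in a +/- `max_lag_s` window around each peak (on a
#' decimated envelope grid), and Pearson-normalizes the averaged envelope
#' against the averaged SW template at every lag. A positive peak lag
#' means spindle activity follows the slow-wave peak.
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate (Hz).
#' @param hyp A [hypnogram()] (NREM required).
#' @param sw_band,spindle_band [band()] definitions (defaults 0.5-4 and
#'   10-16 Hz).
#' @param max_lag_s Maximum lag (s, default 2).
#' @param peak_pctl Slow-wave peak amplitude percentile (default 0.75).
#' @param env_fs Envelope grid rate for the correlation (Hz, default 50);
#'   one envelope sample = `1/env_fs` s of lag resolution.
#' @return Object of class `sw_spindle_xcorr`: `lags_s`, `cc`,
#'   `peak_lag_s`, `peak_cc`, `n_peaks`, `template`, `envelope`.
#' @export
sw_spindle_crosscorr <- function(x, fs, hyp,
                                 sw_band = default_bands()$swa,
                                 spindle_band = default_bands()$spindle,
                                 max_lag_s = 2, peak_pctl = 0.75,
                                 env_fs = 50) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(x)
  nrem <- sample_states(hyp, n, fs) == "NREM"
  if (!any(nrem)) stop("insufficient data: no NREM epochs")
  sw <- extract_phase_envelope(x, fs, sw_band)$filtered
  env <- extract_phase_envelope(x, fs, spindle_band)$envelope

  ## local maxima of the SW-band signal, within NREM, above percentile
  d <- diff(sw)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  pk <- pk[nrem[pk] & sw[pk] > 0]
  if (length(pk)) pk <- pk[sw[pk] >= stats::quantile(sw[pk], peak_pctl)]
  step <- max(1L, as.integer(round(fs / env_fs)))
  fs_e <- fs / step
  L <- as.integer(round(max_lag_s * fs_e))
  sw_d <- moving_average(sw, step)[seq(1L, n, by = step)]
  env_d <- moving_average(env, step)[seq(1L, n, by = step)]
  pk_d <- as.integer(round((pk - 1) / step)) + 1L
  pk_d <- pk_d[pk_d - L >= 1 & pk_d + L <= length(sw_d)]
  if (length(pk_d) < 10) {
    stop("insufficient events: fewer than 10 slow-wave peaks")
  }
  seg <- function(v) {
    rowMeans(vapply(pk_d, function(p) v[(p - L):(p + L)], numeric(2L * L + 1L)))
  }
  Tpl <- seg(sw_d)
  Env <- seg(env_d)
  xc <- xcorr_lagged(Tpl, Env, L)
  i <- which.max(xc$cc)
  structure(
    list(lags_s = xc$lags / fs_e, cc = xc$cc,
         peak_lag_s = xc$lags[i] / fs_e, peak_cc = xc$cc[i],
         n_peaks = length(pk_d), template = Tpl, envelope = Env,
         env_fs = fs_e),
    class = "sw_spindle_xcorr"
  )
}

## MI core on precomputed phase-bin indices (1..n_bins); empty bins
## contribute zero probability (0 * log 0 = 0 convention).
mi_from_bins <- function(idx, amp, n_bins) {
  s <- numeric(n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  rs <- rowsum(amp, idx)
  s[as.integer(rownames(rs))] <- rs
  m <- ifelse(cnt > 0, s / pmax(cnt, 1L), 0)
  if (all(m == 0)) return(list(mi = 0, P = rep(1 / n_bins, n_bins)))
  P <- m / sum(m)
  nz <- P > 0
  H <- -sum(P[nz] * log(P[nz]))
  list(mi = (log(n_bins) - H) / log(n_bins), P = P)
}

#' Phase-amplitude modulation index
#'
#' Bins the amplitude series by the phase series (18 bins of 20 degrees by
#' default), normalizes the mean amplitude per bin to a distribution P,
#' and reports the Kullback-Leibler divergence of P from uniform divided
#' by log(n_bins) (normalized entropy deficit): 0 for phase-independent
#' amplitude, 1 when all amplitude concentrates in one bin. The preferred
#' phase is the amplitude-weighted circular mean.
#'
#' @param phase_deg Phase series in degrees (trough = 0, peak = 180).
#' @param amp Amplitude series (same length, non-negative).
#' @param n_bins Number of phase bins (>= 4, default 18).
#' @param phase_band,amp_band Optional [band()] metadata carried in the
#'   result.
#' @return Object of class `pac`: `n_bins`, `bin_centers_deg`, `bin_amp`
#'   (P, sums to 1), `mi`, `preferred_phase_deg`, `surrogate_p` (`NA`
#'   until [surrogate_null()] is used).
#' @export
modulation_index <- function(phase_deg, amp, n_bins = 18,
                             phase_band = NULL, amp_band = NULL) {
  if (length(phase_deg) != length(amp)) stop("series must have equal length")
  if (n_bins < 4) stop("n_bins must be >= 4")
  idx <- pmin(floor((phase_deg %% 360) / (360 / n_bins)) + 1L, n_bins)
  r <- mi_from_bins(idx, amp, n_bins)
  structure(
    list(phase_band = phase_band, amp_band = amp_band, n_bins = n_bins,
         bin_centers_deg = (seq_len(n_bins) - 0.5) * 360 / n_bins,
         bin_amp = r$P, mi = r$mi,
         preferred_phase_deg = circ_mean_deg(phase_deg, w = amp)$mean_deg,
         surrogate_p = NA_real_),
    class = "pac"
  )
}

#' @export
print.pac <- function(x, ...) {
  cat(sprintf("<pac> MI = %.4f, preferred phase = %.1f deg (%d bins)",
              x$mi, x$preferred_phase_deg, x$n_bins))
  if (!is.na(x$surrogate_p)) cat(sprintf(", surrogate p = %.4f", x$surrogate_p))
  cat("\n")
  invisible(x)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index for every (phase center, amplitude center) pair:
#' phase from `phase_signal` filtered at center +/- `phase_bw_hz`,
#' amplitude envelope from `amp_signal` filtered at center +/-
#' `amp_bw_hz`. Grids whose bands would collide (phase band reaching into
#' an amplitude band) are rejected.
#'
#' @param phase_signal,amp_signal Numeric signals (uV), equal length.
#' @param fs Sampling rate (Hz).
#' @param phase_freqs,amp_freqs Center-frequency grids (Hz).
#' @param phase_bw_hz,amp_bw_hz Half-bandwidths (Hz). The phase default
#'   (0.25) makes adjacent phase bands on the default 0.5 Hz grid
#'   non-overlapping, so a strong slow rhythm cannot dominate neighboring
#'   cells through passband leakage.
#' @param n_bins Phase bins for the MI.
#' @return Object of class `comodulogram`: `mi` matrix (phase x amp),
#'   `phase_freqs`, `amp_freqs`.
#' @export
comodulogram <- function(phase_signal, amp_signal, fs,
                         phase_freqs = seq(0.5, 4, by = 0.5),
                         amp_freqs = seq(9, 16, by = 1),
                         phase_bw_hz = 0.25, amp_bw_hz = 2, n_bins = 18) {
  if (length(phase_signal) != length(amp_signal)) {
    stop("signals must have equal length")
  }
  if (max(phase_freqs) + phase_bw_hz >= min(amp_freqs) - amp_bw_hz) {
    stop("band collision: phase bands overlap amplitude bands")
  }
  envs <- lapply(amp_freqs, function(af) {
    extract_phase_envelope(amp_signal, fs,
                           band("amp", af - amp_bw_hz, af + amp_bw_hz))$envelope
  })
  mi <- matrix(NA_real_, nrow = length(phase_freqs), ncol = length(amp_freqs),
               dimnames = list(phase = phase_freqs, amp = amp_freqs))
  for (i in seq_along(phase_freqs)) {
    pf <- phase_freqs[i]
    ph <- extract_phase_envelope(phase_signal, fs,
                                 band("phase", max(pf - phase_bw_hz, 0.05),
                                      pf + phase_bw_hz))$phase_deg
    idx <- pmin(floor((ph %% 360) / (360 / n_bins)) + 1L, n_bins)
    for (j in seq_along(amp_freqs)) {
      mi[i, j] <- mi_from_bins(idx, envs[[j]], n_bins)$mi
    }
  }
  structure(list(mi = mi, phase_freqs = phase_freqs, amp_freqs = amp_freqs),
            class = "comodulogram")
}

#' Surrogate calibration of a modulation index
#'
#' Circularly time-shifts the amplitude series by `n_surrogates` uniform
#' random offsets of at least `min_shift_s`, recomputes the MI for each,
#' and reports `p = (1 + #{MI_surr >= MI_obs}) / (1 + n_surrogates)`.
#' Circular shifting (rather than shuffling) preserves the amplitude
#' autocorrelation, so the null only destroys the phase-amplitude
#' alignment.
#'
#' @param phase_deg,amp Phase (degrees) and amplitude series.
#' @param fs Sampling rate of the series (Hz).
#' @param n_surrogates Number of surrogates (>= 19, default 200).
#' @param min_shift_s Minimum shift (s, default 10); the series must be
#'   longer than twice this.
#' @param n_bins Phase bins.
#' @param seed Optional seed for the shift draw.
#' @return A `pac` object (as [modulation_index()]) with `surrogate_p`
#'   set, plus `mi_surrogates`.
#' @export
surrogate_null <- function(phase_deg, amp, fs, n_surrogates = 200,
                           min_shift_s = 10, n_bins = 18, seed = NULL) {
  if (n_surrogates < 19) stop("n_surrogates must be >= 19")
  n <- length(amp)
  ms <- as.integer(round(min_shift_s * fs))
  if (n <= 2 * ms) stop("series must be longer than 2 x min_shift_s")
  if (!is.null(seed)) set.seed(seed)
  obs <- modulation_index(phase_deg, amp, n_bins)
  idx <- pmin(floor((phase_deg %% 360) / (360 / n_bins)) + 1L, n_bins)
  shifts <- sample(ms:(n - ms), n_surrogates, replace = TRUE)
  mi_s <- vapply(shifts, function(s) {
    a <- amp[((seq_len(n) - 1 + s) %% n) + 1]
    mi_from_bins(idx, a, n_bins)$mi
  }, numeric(1))
  obs$surrogate_p <- (1 + sum(mi_s >= obs$mi)) / (1 + n_surrogates)
  obs$mi_surrogates <- mi_s
  obs
}

#' Cross-region slow-oscillation phase at spindle peaks
#'
#' Samples the slow-oscillation phase of one region at the spindle
#' envelope peaks detected in another region and summarizes the circular
#' distribution (histogram, circular mean, resultant length). With the
#' trough = 0 convention, spindles nested in the slow-oscillation peak
#' give a mean near 180 degrees.
#'
#' @param sw_signal Phase-providing region signal (uV).
#' @param amp_signal Spindle-providing region signal (uV).
#' @param fs Sampling rate (Hz).
#' @param hyp A [hypnogram()] (used for spindle detection).
#' @param sw_band,spindle_band [band()] definitions.
#' @param n_bins Circular histogram bins (default 18).
#' @param events Optional precomputed spindle events for `amp_signal`
#'   (skips detection).
#' @param det_params [spindle_params()] for detection.
#' @return List: `preferred_phase_deg`, `resultant`, `n_events`,
#'   `phases_deg`, `counts`, `bin_centers_deg`.
#' @export
cross_region_phase_coupling <- function(sw_signal, amp_signal, fs, hyp = NULL,
                                        sw_band = default_bands()$swa,
                                        spindle_band = default_bands()$spindle,
                                        n_bins = 18, events = NULL,
                                        det_params = spindle_params()) {
  if (length(sw_signal) != length(amp_signal)) {
    stop("signals must have equal length")
  }
  if (is.null(events)) {
    if (is.null(hyp)) stop("either events or a hypnogram must be supplied")
    events <- detect_spindles(amp_signal, fs, hyp, det_params)
  }
  if (!nrow(events)) stop("insufficient events: no spindles detected")
  ph <- extract_phase_envelope(sw_signal, fs, sw_band)$phase_deg
  env <- extract_phase_envelope(amp_signal, fs, spindle_band)$envelope
  n <- length(ph)
  pk_idx <- vapply(seq_len(nrow(events)), function(i) {
    i0 <- max(1L, as.integer(floor(events$start_s[i] * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(events$end_s[i] * fs)))
    i0 + which.max(env[i0:i1]) - 1L
  }, integer(1))
  phases <- ph[pk_idx]
  cm <- circ_mean_deg(phases)
  idx <- pmin(floor((phases %% 360) / (360 / n_bins)) + 1L, n_bins)
  list(
    preferred_phase_deg = cm$mean_deg,
    resultant = cm$resultant,
    n_events = length(phases),
    phases_deg = phases,
    counts = tabulate(idx, nbins = n_bins),
    bin_centers_deg = (seq_len(n_bins) - 0.5) * 360 / n_bins
  )
}
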