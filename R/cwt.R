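# Continuous wavelet transform restricted to an analysis band, used for
# spindle energy. Implemented in the frequency domain with analytic
# (negative-frequency-suppressed) wavelets so |W|^2 estimates the squared
# envelope amplitude of in-band activity. Two wavelet families are
# available: complex Morlet (Gaussian frequency window) and a frequency
# B-spline of order 2 (triangular frequency window).

## Frequency response of one wavelet centered at fc, evaluated on the FFT
## grid of an n-sample signal at rate fs. Peak gain 2 on the positive
## branch: for x = a cos(2 pi fc t), |W| ~ a.
wavelet_freq_response <- function(n, fs, fc, wavelet, n_cycles) {
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs # signed two-sided grid
  H <- numeric(n)
  pos <- f > 0
  if (wavelet == "complex_morlet") {
    sigma_f <- fc / n_cycles
    H[pos] <- 2 * exp(-(f[pos] - fc)^2 / (2 * sigma_f^2))
  } else if (wavelet == "freq_bspline") {
    fb <- 4 * fc / n_cycles # total frequency support
    H[pos] <- 2 * pmax(0, 1 - abs(f[pos] - fc) / (fb / 2))
  } else {
    stop("unknown wavelet: ", wavelet)
  }
  H
}

## Complex CWT coefficients for a set of center frequencies.
## Returns an n_freqs x n matrix of |W|^2.
cwt_energy_matrix <- function(x, fs, freqs_hz, wavelet, n_cycles) {
  n <- length(x)
  X <- stats::fft(x)
  out <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(freqs_hz)) {
    H <- wavelet_freq_response(n, fs, freqs_hz[i], wavelet, n_cycles)
    W <- stats::fft(X * H, inverse = TRUE) / n
    out[i, ] <- Mod(W)^2
  }
  out
}

#' Spindle detector parameters
#'
#' The detector thresholds the smoothed, NREM-normalized wavelet energy in
#' the spindle band with a two-threshold hysteresis (detection at
#' `thresh_hi_sd`, extent at `thresh_lo_sd`, both in standard deviations
#' above the NREM mean of the energy series), then refines event
#' boundaries from the width of the energy peak at quarter maximum above
#' baseline, which estimates the full duration of a waxing-and-waning
#' (Hann-like) event independently of its amplitude.
#'
#' @param bnd Spindle [band()] (default 10-16 Hz).
#' @param wavelet `"complex_morlet"` or `"freq_bspline"`.
#' @param n_freqs Number of wavelet center frequencies across the band.
#' @param n_cycles Wavelet cycles (frequency resolution fc / n_cycles).
#' @param thresh_hi_sd,thresh_lo_sd Detection / extent thresholds, in SDs
#'   above the NREM mean of smoothed normalized energy;
#'   `thresh_hi_sd >= thresh_lo_sd > 0`.
#' @param smooth_s Energy smoothing window (s).
#' @param min_dur_s,max_dur_s Event duration bounds (s); the >0.4 s floor
#'   is the conventional rodent spindle minimum and the 2 s cap excludes
#'   fused delta-band contamination.
#' @param merge_gap_s Candidates closer than this are merged (s).
#' @return An object of class `spindle_params`.
#' @export
spindle_params <- function(bnd = default_bands()$spindle,
                           wavelet = c("complex_morlet", "freq_bspline"),
                           n_freqs = 13,
                           n_cycles = 7,
                           thresh_hi_sd = 2.5,
                           thresh_lo_sd = 1,
                           smooth_s = 0.05,
                           min_dur_s = 0.4,
                           max_dur_s = 2.0,
                           merge_gap_s = 0.1) {
  wavelet <- match.arg(wavelet)
  if (!(thresh_hi_sd >= thresh_lo_sd && thresh_lo_sd > 0)) {
    stop("need thresh_hi_sd >= thresh_lo_sd > 0")
  }
  if (!(min_dur_s > 0 && min_dur_s < max_dur_s)) {
    stop("need 0 < min_dur_s < max_dur_s")
  }
  structure(list(bnd = bnd, wavelet = wavelet, n_freqs = n_freqs,
                 n_cycles = n_cycles, thresh_hi_sd = thresh_hi_sd,
                 thresh_lo_sd = thresh_lo_sd, smooth_s = smooth_s,
                 min_dur_s = min_dur_s, max_dur_s = max_dur_s,
                 merge_gap_s = merge_gap_s),
            class = "spindle_params")
}

#' Normalized wavelet energy in the spindle band
#'
#' Magnitude-squared CWT coefficients at `n_freqs` centers spanning the
#' band, averaged over frequency, smoothed with a `smooth_s` moving
#' average, and divided by the series mean over NREM epochs (over the
#' whole signal when no hypnogram is given).
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate (Hz); must be at least 4 x the band's upper
#'   edge (downsample first if not).
#' @param params A [spindle_params()].
#' @param hyp Optional [hypnogram()] used for the NREM normalization.
#' @return List: `energy` (normalized smoothed series), `energy_mat`
#'   (raw per-frequency energy, n_freqs x n), `freqs_hz`, `norm` (the
#'   normalization constant, uV^2).
#' @export
spindle_energy <- function(x, fs, params = spindle_params(), hyp = NULL) {
  stopifnot(inherits(params, "spindle_params"))
  if (fs < 4 * params$bnd$hi_hz) {
    stop("fs must be >= 4 x the spindle band upper edge; downsample first")
  }
  if (length(x) < 10 * params$smooth_s * fs) {
    stop("insufficient data: signal shorter than 10 x smooth_s")
  }
  freqs <- seq(params$bnd$lo_hz, params$bnd$hi_hz, length.out = params$n_freqs)
  E <- cwt_energy_matrix(x, fs, freqs, params$wavelet, params$n_cycles)
  raw <- colMeans(E)
  sm <- moving_average(raw, params$smooth_s * fs)
  if (!is.null(hyp)) {
    mask <- sample_states(hyp, length(x), fs) == "NREM"
    norm <- if (any(mask)) mean(sm[mask]) else mean(sm)
  } else {
    norm <- mean(sm)
  }
  energy <- if (norm > 0) sm / norm else numeric(length(sm))
  list(energy = energy, energy_mat = E, freqs_hz = freqs, norm = norm)
}
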