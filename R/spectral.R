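# Welch power spectral density with state masking, total-power
# normalization, band integrals (slow-wave activity and the delta
# sub-bands) and binned SWA time courses.

hann_periodic <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

## Admissible window start indices: windows of `nwin` samples advancing by
## `hop` that lie fully inside contiguous TRUE runs of `mask`.
masked_window_starts <- function(mask, nwin, hop) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in which(r$values)) {
    if (r$lengths[i] >= nwin) {
      out <- c(out, seq.int(starts[i], ends[i] - nwin + 1L, by = hop))
    }
  }
  out
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered, mean-detrended periodograms over all windows of
#' `window_s` seconds advancing by `window_s * (1 - overlap_frac)`,
#' restricted (when a hypnogram state or an epoch mask is given) to
#' windows lying fully inside contiguous masked runs. One-sided density
#' scaling in uV^2/Hz; frequency resolution `1 / window_s`.
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 8).
#' @param overlap_frac Fractional overlap between windows (default 0.75).
#' @param hyp Optional [hypnogram()] paired with `x`.
#' @param state With `hyp`: restrict to epochs of this vigilance state.
#' @param epoch_mask Optional logical per-epoch mask (alternative to
#'   `hyp`/`state`); epoch length taken from `hyp` or `epoch_s`.
#' @param epoch_s Epoch length for `epoch_mask` without `hyp`.
#' @return An object of class `psd`: `freqs_hz`, `power`, `normalized`,
#'   `window_s`, `overlap_frac`, `n_windows`, `fs`.
#' @export
welch_psd <- function(x, fs, window_s = 8, overlap_frac = 0.75,
                      hyp = NULL, state = NULL, epoch_mask = NULL,
                      epoch_s = 1) {
  n <- length(x)
  nwin <- as.integer(round(window_s * fs))
  if (nwin < 4) stop("window too short for the sampling rate")
  if (n < nwin) stop("insufficient data: signal shorter than one window")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  hop <- max(1L, as.integer(round(nwin * (1 - overlap_frac))))

  mask <- rep(TRUE, n)
  if (!is.null(hyp) && !is.null(state)) {
    mask <- sample_states(hyp, n, fs) %in% state
  } else if (!is.null(epoch_mask)) {
    es <- if (!is.null(hyp)) hyp$epoch_s else epoch_s
    idx <- pmin(floor((seq_len(n) - 1) / fs / es) + 1L, length(epoch_mask))
    mask <- epoch_mask[idx]
  }
  starts <- masked_window_starts(mask, nwin, hop)
  if (!length(starts)) {
    stop("insufficient data: no admissible ", window_s,
         " s window inside the mask")
  }
  w <- hann_periodic(nwin)
  U <- sum(w^2)
  segs <- vapply(starts, function(s0) {
    seg <- x[s0:(s0 + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    Mod(stats::fft(seg))^2
  }, numeric(nwin))
  pxx <- rowMeans(as.matrix(segs))[1:(nwin %/% 2 + 1)] / (fs * U)
  if (nwin %% 2 == 0) {
    pxx[2:(nwin %/% 2)] <- 2 * pxx[2:(nwin %/% 2)]
  } else {
    pxx[2:length(pxx)] <- 2 * pxx[2:length(pxx)]
  }
  structure(
    list(freqs_hz = (0:(nwin %/% 2)) * fs / nwin, power = pxx,
         normalized = FALSE, window_s = window_s,
         overlap_frac = overlap_frac, n_windows = length(starts), fs = fs),
    class = "psd"
  )
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, 0-%g Hz (df = %g Hz), %d windows of %g s%s\n",
              length(x$freqs_hz), max(x$freqs_hz),
              x$freqs_hz[2] - x$freqs_hz[1], x$n_windows, x$window_s,
              if (x$normalized) ", total-power normalized" else ""))
  invisible(x)
}

#' Normalize a PSD by its total power
#'
#' Divides the density by its trapezoidal integral over `range_hz`
#' (default: the full computed range), the per-recording normalization
#' used to compare spectra between animals. After the call the integral of
#' the density over that range is 1.
#'
#' @param psd A `psd` from [welch_psd()].
#' @param range_hz Optional `(lo, hi)` integration range for the
#'   normalization constant.
#' @return A normalized `psd`.
#' @export
normalize_psd <- function(psd, range_hz = NULL) {
  stopifnot(inherits(psd, "psd"))
  if (psd$normalized) stop("psd is already normalized")
  if (is.null(range_hz)) {
    total <- trapz(psd$freqs_hz, psd$power)
  } else {
    total <- band_power(psd, band("norm", range_hz[1], range_hz[2]))
  }
  if (total <= 0) stop("degenerate input: total power is zero")
  psd$power <- psd$power / total
  psd$normalized <- TRUE
  psd
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the density over `[lo_hz, hi_hz)`, with linear
#' interpolation at the band edges so that adjacent bands tile exactly.
#'
#' @param psd A `psd`.
#' @param bnd A [band()].
#' @return Band power: uV^2 for a raw PSD, a dimensionless fraction for a
#'   normalized one.
#' @export
band_power <- function(psd, bnd) {
  stopifnot(inherits(psd, "psd"), inherits(bnd, "band"))
  f <- psd$freqs_hz
  if (bnd$lo_hz < f[1] || bnd$hi_hz > f[length(f)]) {
    stop("band [", bnd$lo_hz, ", ", bnd$hi_hz,
         ") outside the PSD frequency range")
  }
  sel <- f > bnd$lo_hz & f < bnd$hi_hz
  xs <- c(bnd$lo_hz, f[sel], bnd$hi_hz)
  ys <- c(stats::approx(f, psd$power, xout = bnd$lo_hz)$y,
          psd$power[sel],
          stats::approx(f, psd$power, xout = bnd$hi_hz)$y)
  trapz(xs, ys)
}

#' Binned time course of band power (SWA progression)
#'
#' Splits the recording into `bin_s` bins, estimates a state-masked,
#' total-power-normalized PSD per bin, integrates `bnd` and scales the
#' series by the chosen reference. Bins without a single admissible Welch
#' window are returned as `NA`, never interpolated.
#'
#' @param x Numeric signal (uV).
#' @param fs Sampling rate (Hz).
#' @param hyp A [hypnogram()] paired with `x`.
#' @param bnd Band to integrate (default slow-wave activity 0.5-4 Hz).
#' @param bin_s Bin width (s), must be at least `window_s`.
#' @param state Vigilance state defining the mask (default NREM).
#' @param normalize_to `"first_bin"` (first non-missing value becomes 1)
#'   or `"mean"` (series mean becomes 1).
#' @param window_s,overlap_frac Welch parameters, see [welch_psd()].
#' @return Data frame: `bin_start_s`, `band_power` (normalized-PSD band
#'   fraction), `rel_power` (scaled by the reference).
#' @export
swa_timecourse <- function(x, fs, hyp, bnd = default_bands()$swa,
                           bin_s = 3600, state = "NREM",
                           normalize_to = c("first_bin", "mean"),
                           window_s = 8, overlap_frac = 0.75) {
  normalize_to <- match.arg(normalize_to)
  if (bin_s < window_s) stop("bin_s must be >= window_s")
  n <- length(x)
  st <- sample_states(hyp, n, fs)
  bin_len <- as.integer(round(bin_s * fs))
  n_bins <- ceiling(n / bin_len)
  bp <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    sel <- ((b - 1) * bin_len + 1):min(b * bin_len, n)
    mask_epochs <- rep(FALSE, length(hyp$labels))
    ep_sel <- unique(pmin(floor((sel - 1) / fs / hyp$epoch_s) + 1L,
                          length(hyp$labels)))
    mask_epochs[ep_sel] <- hyp$labels[ep_sel] == state
    p <- tryCatch(
      welch_psd(x, fs, window_s, overlap_frac, hyp = hyp,
                epoch_mask = mask_epochs),
      error = function(e) NULL
    )
    if (!is.null(p)) bp[b] <- band_power(normalize_psd(p), bnd)
  }
  ref <- if (normalize_to == "first_bin") bp[which(!is.na(bp))[1]]
         else mean(bp, na.rm = TRUE)
  data.frame(
    bin_start_s = (seq_len(n_bins) - 1) * bin_s,
    band_power = bp,
    rel_power = bp / ref
  )
}
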