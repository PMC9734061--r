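# Internal numerical helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif rexp rpois quantile sd median approx
#' @importFrom utils read.csv write.csv
NULL

VIGILANCE_STATES <- c("Wake", "NREM", "REM", "Artifact")

## Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Gaussian 1/f^alpha noise scaled to a target RMS, generated by spectral
## shaping of white noise. alpha = 0 gives white noise.
noise_1f <- function(n, alpha, rms) {
  if (n < 2) return(stats::rnorm(n, sd = rms))
  ## complex spectrum with Hermitian symmetry via real white noise
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # two-sided frequency index
  gain <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * gain, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

## Centered moving average with a boxcar of `width` samples (width >= 1).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(round(width)))
  if (width == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## Trapezoidal integral of y over x (both ascending grids).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## Circular mean (degrees in [0, 360)) and resultant length, optionally
## amplitude-weighted.
circ_mean_deg <- function(phase_deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(phase_deg))
  th <- deg2rad(phase_deg)
  C <- sum(w * cos(th))
  S <- sum(w * sin(th))
  mu <- rad2deg(atan2(S, C)) %% 360
  R <- sqrt(C^2 + S^2) / sum(w)
  list(mean_deg = mu, resultant = R)
}

## Signed circular difference a - b in (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## Derive a reproducible 31-bit sub-seed for a named random stream.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483647L)
}

## Run-length encoding of a label vector as a data.frame of runs.
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  data.frame(
    state = r$values,
    start = ends - r$lengths + 1L, # first epoch index (1-based)
    len = r$lengths,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
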