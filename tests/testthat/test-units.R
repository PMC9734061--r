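# Single-unit metrics: the 600-4000 Hz elliptic filter contract, state
# firing rates, peri-transition histograms and burst detection against a
# brute-force enumeration oracle.

test_that("spike-band filter meets the cited elliptic design", {
  fs <- 20000
  flt <- somnotools:::spike_band_design(fs)
  fr <- signal::freqz(flt$b, flt$a, n = 8192, Fs = fs)
  gain_db <- function(f) 20 * log10(abs(fr$h[which.min(abs(fr$f - f))]))
  ## passband gain within the 0.1 dB ripple at 1 kHz
  expect_lt(abs(gain_db(1000)), 0.1)
  ## stopband attenuation at least 40 dB at 100 Hz and 8 kHz
  expect_lt(gain_db(100), -40)
  expect_lt(gain_db(8000), -40)
  ## frequency response from the filter's own impulse response (direct
  ## time-domain evaluation, independent of freqz) matches at spot checks
  ## (impulse FFT grid chosen to coincide exactly with the freqz grid)
  imp <- c(1, numeric(2 * 8192 - 1))
  h_t <- signal::filter(flt, imp)
  H <- fft(h_t)[seq_len(8192)]
  for (f0 in c(1000, 2000, 100)) {
    k <- which.min(abs(fr$f - f0))
    expect_equal(abs(H[k]), abs(fr$h[k]), tolerance = 1e-3)
  }
  ## zero-phase application: a passband tone comes back unshifted
  t <- seq(0, 0.5, by = 1 / fs)
  x <- sin(2 * pi * 1000 * t)
  y <- spike_band_filter(x, fs)
  mid <- seq(2000, length(x) - 2000)
  expect_gt(stats::cor(x[mid], y[mid]), 0.999)
  expect_error(spike_band_filter(x, 8000), "Nyquist")
})

test_that("burst detection matches the hand-enumerated example", {
  b <- detect_bursts(c(0.500, 0.503, 0.506, 1.000, 1.800, 1.804))
  expect_equal(b$start_s, c(0.500, 1.800))
  expect_equal(b$n_spikes, c(3L, 2L))
  expect_equal(b$dur_ms, c(6, 4), tolerance = 1e-9)
  ## all ISIs above the intra-burst maximum: no bursts
  expect_equal(nrow(detect_bursts(seq(0, 10, by = 0.5))), 0)
  expect_error(burst_criteria(min_preceding_silence_ms = 5), "exceed")
})

test_that("burst detection equals brute-force enumeration on random trains", {
  set.seed(33)
  crit <- burst_criteria()
  for (rep in 1:300) {
    n <- sample(5:1000, 1)
    ## mixture of slow and fast ISIs to exercise chains and silences
    isi <- ifelse(runif(n) < 0.35, runif(n, 0.001, 0.012),
                  runif(n, 0.02, 0.4))
    times <- cumsum(isi)
    got <- detect_bursts(times, crit)
    want <- brute_force_bursts(times, crit)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$n_spikes, want$n_spikes)
    expect_equal(got$dur_ms, want$dur_ms, tolerance = 1e-9)
  }
})

test_that("simulated ground-truth bursts are recovered exactly", {
  p <- quick_params(seed = 25, duration_s = 1200)
  hyp <- simulate_hypnogram(p)
  u <- simulate_spike_train(hyp, p)
  got <- detect_bursts(u$train, sim_burst_criteria(p))
  expect_equal(got$start_s, u$bursts$start_s, tolerance = 1e-9)
  expect_equal(got$n_spikes, u$bursts$n_spikes)
  expect_equal(got$dur_ms, u$bursts$dur_ms, tolerance = 1e-6)
})

test_that("burst output is invariant to distant tonic spikes, partitions spikes", {
  crit <- burst_criteria()
  burst_t <- c(1, 1.005, 1.010, 3, 3.004)
  tonic_t <- c(0.2, 0.5, 1.5, 2.2, 4)
  b0 <- detect_bursts(burst_t, crit)
  b1 <- detect_bursts(sort(c(burst_t, tonic_t)), crit)
  expect_equal(b0, b1)
  ## partition: burst spikes + tonic spikes = all spikes
  all_t <- sort(c(burst_t, tonic_t))
  in_burst <- rowSums(vapply(seq_len(nrow(b1)), function(i) {
    all_t >= b1$start_s[i] - 1e-12 &
      all_t <= b1$start_s[i] + b1$dur_ms[i] / 1000 + 1e-12
  }, logical(length(all_t)))) > 0
  expect_equal(sum(in_burst) + sum(!in_burst), length(all_t))
  expect_equal(sum(in_burst), sum(b1$n_spikes))
})

test_that("state firing rates follow the Poisson oracle and recompose", {
  p <- quick_params(seed = 26, duration_s = 3600)
  hyp <- simulate_hypnogram(p)
  set.seed(27)
  n_exp <- 5 * 3600
  spk <- sort(runif(rpois(1, n_exp), 0, 3600)) # uniform 5 Hz Poisson
  r <- state_firing_rate(spk, hyp)
  for (s in c("Wake", "NREM", "REM")) {
    dur <- sum(hyp$labels == s)
    if (dur > 100) {
      se <- sqrt(5 / dur)
      expect_lt(abs(r[[s]] - 5), 3 * se + 0.05)
    }
  }
  ## rates weighted by state time recompose the overall rate
  durs <- vapply(c("Wake", "NREM", "REM"), function(s) sum(hyp$labels == s),
                 numeric(1))
  overall <- sum(r * durs, na.rm = TRUE) / sum(durs[!is.na(r)])
  expect_equal(overall, length(spk) / 3600, tolerance = 1e-9)
  ## no spikes: all rates zero
  r0 <- state_firing_rate(numeric(0), hyp)
  expect_true(all(r0[!is.na(r0)] == 0))
})

test_that("transition PETH recovers a constructed rate step", {
  h <- hypnogram(rep(c(rep("Wake", 60), rep("NREM", 60)), 20))
  ## deterministic spikes: 10 Hz in Wake, 2 Hz in NREM
  wake_sp <- unlist(lapply(0:19, function(k) 120 * k + seq(0.05, 59.95, by = 0.1)))
  nrem_sp <- unlist(lapply(0:19, function(k) 120 * k + 60 + seq(0.25, 59.75, by = 0.5)))
  spk <- sort(c(wake_sp, nrem_sp))
  pe <- transition_peth(spk, h, c("Wake", "NREM"), window_s = c(20, 20))
  expect_equal(pe$n_transitions, 20)
  expect_equal(unname(pe$rate[pe$bin_start_s < 0]), rep(10, 20))
  expect_equal(unname(pe$rate[pe$bin_start_s >= 0]), rep(2, 20))
  ## conservation: total rate x bins x transitions = spikes in windows
  tot <- sum(pe$rate) * pe$bin_s * pe$n_transitions
  in_win <- sum(vapply(which(diff(h$labels == "Wake") == -1), function(i) {
    sum(spk >= i - 20 & spk < i + 20)
  }, numeric(1)))
  expect_equal(tot, in_win)
  expect_error(transition_peth(spk, h, c("REM", "Wake")), "insufficient")
  ## short flanks disqualify transitions
  h2 <- hypnogram(c(rep("Wake", 10), rep("NREM", 10)))
  expect_error(transition_peth(spk, h2, c("Wake", "NREM")), "insufficient")
})

test_that("burst statistics use per-state minutes", {
  hyp <- hypnogram(c(rep("NREM", 900), rep("Wake", 900)))
  b <- data.frame(start_s = seq(10, 890, length.out = 30), n_spikes = 4L,
                  dur_ms = 15)
  s <- burst_stats(b, hyp, state = "NREM")
  expect_equal(s$density_per_min, 30 / 15) # 30 bursts / 15 NREM minutes
  expect_equal(s$mean_spikes, 4)
  s0 <- burst_stats(b[0, ], hyp, state = "NREM")
  expect_equal(s0$density_per_min, 0)
  expect_error(burst_stats(b, hyp, state = "REM"), "undefined")
})

test_that("simulated per-burst spike counts are recovered in statistics", {
  p <- quick_params(seed = 29, duration_s = 1200, spikes_per_burst = c(4, 4))
  hyp <- simulate_hypnogram(p)
  u <- simulate_spike_train(hyp, p)
  got <- detect_bursts(u$train, sim_burst_criteria(p))
  st <- burst_stats(got, hyp, state = "NREM")
  expect_equal(st$mean_spikes, 4)
})
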