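# Phase/envelope extraction, slow-wave/spindle cross-correlation,
# modulation index (with a numerical-integration oracle), comodulogram
# localization, surrogate calibration and cross-region phase coupling.

test_that("phase convention puts the peak at 180 and trough at 0", {
  fs <- 200
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1.5 * t)
  pe <- extract_phase_envelope(x, fs, band("swa", 0.5, 4))
  interior <- seq(10 * fs, 110 * fs)
  ## envelope of a unit sine is 1 (interior, away from filter edges)
  expect_lt(max(abs(pe$envelope[interior] - 1)), 0.01)
  ## maxima at 180, minima at 0/360
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pk <- pk[pk > 10 * fs & pk < 110 * fs]
  expect_lt(max(abs(somnotools:::circ_diff_deg(pe$phase_deg[pk], 180))), 2)
  tr <- which(diff(sign(diff(x))) == 2) + 1
  tr <- tr[tr > 10 * fs & tr < 110 * fs]
  expect_lt(max(abs(somnotools:::circ_diff_deg(pe$phase_deg[tr], 0))), 2)
  expect_error(extract_phase_envelope(x, 10, band("sp", 10, 16)), "degenerate")
})

test_that("a slowly amplitude-modulated tone yields its envelope", {
  fs <- 200
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  a <- 1 + 0.5 * sin(2 * pi * 0.2 * t)
  x <- a * sin(2 * pi * 12 * t)
  pe <- extract_phase_envelope(x, fs, band("sp", 10, 16))
  interior <- seq(10 * fs, 110 * fs)
  expect_lt(max(abs(pe$envelope[interior] - a[interior]) / a[interior]), 0.02)
})

test_that("cross-correlation recovers injected slow-wave to spindle delays", {
  for (d in c(-0.5, 0, 0.3, 0.5)) {
    sig <- make_sw_delay_signal(d, seed = 3)
    r <- sw_spindle_crosscorr(sig$x, 200, sig$hyp)
    expect_lte(abs(r$peak_lag_s - d), 1 / r$env_fs) # one envelope sample
    expect_gt(r$peak_cc, 0.5)
  }
})

test_that("cross-correlation identity and independence nulls behave", {
  ## identical series: peak correlation 1 at lag 0
  set.seed(15)
  a <- somnotools:::moving_average(rnorm(2000), 9)
  xc <- somnotools:::xcorr_lagged(a, a, 50)
  expect_equal(xc$cc[xc$lags == 0], 1, tolerance = 1e-12)
  expect_equal(which.max(xc$cc), which(xc$lags == 0))

  ## spindles statistically independent of slow waves: the coupling drops
  ## below a shuffled-peak null built from delay-randomized constructions
  fs <- 200; dur <- 600
  set.seed(16)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- somnotools:::noise_1f(length(t), 1, 10)
  sw_pk <- cumsum(runif(220, 2.5, 5)); sw_pk <- sw_pk[sw_pk > 10 & sw_pk < dur - 10]
  for (p0 in sw_pk) {
    tt <- seq(-0.5, 0.5, by = 1 / fs)
    idx <- round((p0 - 0.5) * fs) + seq_along(tt)
    x[idx] <- x[idx] + 200 * cos(2 * pi * tt) * 0.5 * (1 + cos(2 * pi * tt))
  }
  sp_t <- runif(length(sw_pk), 10, dur - 10) # unrelated spindle times
  for (p0 in sp_t) {
    ts <- seq(0, 0.6, by = 1 / fs)
    jdx <- round((p0 - 0.3) * fs) + seq_along(ts)
    x[jdx] <- x[jdx] + 50 * 0.5 * (1 - cos(2 * pi * ts / 0.6)) * sin(2 * pi * 13 * ts)
  }
  hyp <- hypnogram(rep("NREM", dur))
  r_ind <- sw_spindle_crosscorr(x, fs, hyp)
  r_ali <- sw_spindle_crosscorr(make_sw_delay_signal(0.3, seed = 16)$x, fs, hyp)
  expect_lt(r_ind$peak_cc, r_ali$peak_cc)
})

test_that("insufficient slow-wave peaks raise an error", {
  set.seed(17)
  x <- rnorm(200 * 30)
  expect_error(sw_spindle_crosscorr(x, 200, hypnogram(rep("Wake", 30))),
               "NREM")
})

test_that("modulation index matches a numerical-integration oracle", {
  ## amp(phi) = 1 + cos(phi - 180): bin means by exact integration
  n_bins <- 18
  edges <- seq(0, 360, length.out = n_bins + 1)
  exact_mean <- function(lo, hi) {
    ## (1/w) integral of 1 + cos(phi - 180) dphi over [lo, hi], degrees
    w <- (hi - lo) * pi / 180
    1 + (sin((hi - 180) * pi / 180) - sin((lo - 180) * pi / 180)) / w
  }
  m <- mapply(exact_mean, edges[-length(edges)], edges[-1])
  P <- m / sum(m)
  mi_oracle <- (log(n_bins) + sum(P * log(P))) / log(n_bins)

  ph <- seq(0, 360 - 0.001, length.out = 2e5)
  amp <- 1 + cos((ph - 180) * pi / 180)
  r <- modulation_index(ph, amp, n_bins)
  expect_equal(r$mi, mi_oracle, tolerance = 1e-3)
  expect_lt(abs(somnotools:::circ_diff_deg(r$preferred_phase_deg, 180)), 2)

  ## phase-independent amplitude: uniform distribution, MI = 0
  r0 <- modulation_index(ph, rep(2, length(ph)), n_bins)
  expect_equal(r0$mi, 0, tolerance = 1e-12)
  expect_equal(r0$bin_amp, rep(1 / n_bins, n_bins), tolerance = 1e-12)

  ## scale invariance
  r5 <- modulation_index(ph, 5 * amp, n_bins)
  expect_equal(r5$mi, r$mi, tolerance = 1e-12)
  expect_true(r$mi >= 0 && r$mi <= 1)
})

test_that("MI is monotone in the fraction of coupled spindles", {
  hyp <- hypnogram(rep("NREM", 900))
  mis <- vapply(c(0, 0.5, 1), function(cp) {
    p <- quick_params(seed = 30, couple_prob = cp, channels = "ACC")
    sim <- simulate_recording(hyp, p)
    x <- channel(sim$recording, "ACC")
    ph <- extract_phase_envelope(x, p$fs, default_bands()$swa)$phase_deg
    env <- extract_phase_envelope(x, p$fs, default_bands()$spindle)$envelope
    modulation_index(ph, env)$mi
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("comodulogram peaks at the injected (SO, spindle) cell", {
  p <- sim_params(duration_s = 1200, seed = 5, couple_prob = 1,
                  channels = c("ACC", "AD"))
  hyp <- simulate_hypnogram(p)
  sim <- simulate_recording(hyp, p)
  nrem <- somnotools:::sample_states(hyp, nrow(sim$recording$signals), p$fs) == "NREM"
  cm <- comodulogram(channel(sim$recording, "ACC")[nrem],
                     channel(sim$recording, "AD")[nrem], p$fs)
  mx <- which(cm$mi == max(cm$mi), arr.ind = TRUE)
  expect_equal(cm$phase_freqs[mx[1]], 1)
  expect_equal(cm$amp_freqs[mx[2]], 12)
  expect_error(comodulogram(rnorm(100), rnorm(100), 200,
                            phase_freqs = c(2, 8), amp_freqs = c(9, 12)),
               "collision")
})

test_that("surrogate calibration: determinism, extremes, uniform null", {
  set.seed(20)
  n <- 3000
  ph <- runif(n, 0, 360)
  amp <- abs(rnorm(n))
  s1 <- surrogate_null(ph, amp, fs = 100, min_shift_s = 2, seed = 99)
  s2 <- surrogate_null(ph, amp, fs = 100, min_shift_s = 2, seed = 99)
  expect_identical(s1$surrogate_p, s2$surrogate_p)
  expect_error(surrogate_null(ph, amp, fs = 100, n_surrogates = 5), "19")
  expect_error(surrogate_null(ph[1:100], amp[1:100], fs = 100), "longer")

  ## strongly coupled: p at the minimum attainable value
  amp_c <- 1 + cos((ph - 180) * pi / 180)
  sc <- surrogate_null(ph, amp_c, fs = 100, min_shift_s = 2, seed = 1)
  expect_equal(sc$surrogate_p, 1 / 201)

  ## independent inputs: p approximately uniform over repeated runs
  set.seed(21)
  ps <- replicate(200, {
    ph0 <- runif(1500, 0, 360)
    a0 <- abs(rnorm(1500))
    surrogate_null(ph0, a0, fs = 100, min_shift_s = 2,
                   n_surrogates = 99)$surrogate_p
  })
  ## (surrogate p lives on a discrete lattice, so exact ties are expected)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cross-region coupling recovers the injected phase preference", {
  p <- sim_params(duration_s = 1500, seed = 8, couple_prob = 1,
                  channels = c("ACC", "AD"))
  hyp <- simulate_hypnogram(p)
  sim <- simulate_recording(hyp, p)
  cr <- cross_region_phase_coupling(channel(sim$recording, "ACC"),
                                    channel(sim$recording, "AD"), p$fs, hyp)
  expect_gt(cr$n_events, 30)
  expect_lt(abs(somnotools:::circ_diff_deg(cr$preferred_phase_deg, 180)), 5)
  expect_gt(cr$resultant, 0.8)

  ## degenerate case: a single event reproduces its own phase exactly
  ev1 <- data.frame(channel = "AD", start_s = 100.2, end_s = 101,
                    dur_s = 0.8, peak_s = 100.6, peak_amp_uv = 90,
                    peak_freq_hz = 12, energy = 4, transition = FALSE)
  cr1 <- cross_region_phase_coupling(channel(sim$recording, "ACC"),
                                     channel(sim$recording, "AD"), p$fs,
                                     events = ev1)
  expect_equal(cr1$n_events, 1)
  expect_equal(cr1$resultant, 1, tolerance = 1e-9)
  expect_equal(cr1$preferred_phase_deg, cr1$phases_deg[1] %% 360,
               tolerance = 1e-9)
  expect_error(cross_region_phase_coupling(
    channel(sim$recording, "ACC"), channel(sim$recording, "AD"), p$fs,
    events = somnotools:::empty_events("spindle")), "insufficient")
})

test_that("uniformly placed events have vanishing resultant length", {
  ## uniform circular law: E[R] ~ sqrt(pi)/(2 sqrt(n)); bound 2/sqrt(n)
  set.seed(22)
  n <- 400
  ph <- runif(n, 0, 360)
  r <- somnotools:::circ_mean_deg(ph)$resultant
  expect_lt(r, 2 / sqrt(n))
})
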