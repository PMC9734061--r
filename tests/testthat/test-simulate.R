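# Synthetic polysomnography generator: reproducibility, distributional
# oracles (Poisson counts, law of large numbers), ground-truth guarantees
# and the amplitude-scaling property.

test_that("identical parameters give bit-identical outputs", {
  p <- quick_params(seed = 42)
  h1 <- simulate_hypnogram(p); h2 <- simulate_hypnogram(p)
  expect_identical(h1, h2)
  s1 <- simulate_recording(h1, p); s2 <- simulate_recording(h2, p)
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(s1$truth$spindles, s2$truth$spindles)
  u1 <- simulate_spike_train(h1, p); u2 <- simulate_spike_train(h1, p)
  expect_identical(u1$train$times_s, u2$train$times_s)
})

test_that("semi-Markov architecture follows the transition rules", {
  p <- quick_params(seed = 7, duration_s = 3600, rem_entry_prob = 0)
  hyp <- simulate_hypnogram(p)
  expect_false(any(hyp$labels == "REM"))

  p2 <- quick_params(seed = 7, duration_s = 3600, rem_entry_prob = 1)
  runs <- somnotools:::label_runs(simulate_hypnogram(p2)$labels)
  ## every NREM run is followed by REM, every REM by Wake
  after <- function(s) runs$state[which(runs$state == s) + 1L]
  expect_true(all(after("NREM") == "REM", na.rm = TRUE))
  expect_true(all(after("REM") == "Wake", na.rm = TRUE))
  ## adjacent episodes always differ
  expect_false(any(runs$state[-1] == runs$state[-nrow(runs)]))
})

test_that("episode durations obey the law of large numbers", {
  ## ~10,000 NREM episodes; empirical mean within 3 SE of mean/fragmentation
  frag <- 4
  p <- sim_params(duration_s = 640000, seed = 11,
                  mean_episode_s = c(Wake = 150, NREM = 100, REM = 60),
                  fragmentation = frag, channels = "EEG_front")
  hyp <- simulate_hypnogram(p)
  runs <- somnotools:::label_runs(hyp$labels)
  nrem <- runs$len[runs$state == "NREM"]
  expect_gt(length(nrem), 5000)
  target <- 100 / frag
  se <- stats::sd(nrem) / sqrt(length(nrem))
  expect_lt(abs(mean(nrem) - target), 3 * se + 0.5) # 0.5: 1 s discretization
})

test_that("fragmentation multiplies episode counts, preserves state totals", {
  p1 <- sim_params(duration_s = 14400, seed = 5, fragmentation = 1,
                   channels = "EEG_front")
  p4 <- sim_params(duration_s = 14400, seed = 5, fragmentation = 4,
                   channels = "EEG_front")
  h1 <- simulate_hypnogram(p1); h4 <- simulate_hypnogram(p4)
  n1 <- sum(somnotools:::label_runs(h1$labels)$state == "NREM")
  n4 <- sum(somnotools:::label_runs(h4$labels)$state == "NREM")
  expect_gt(n4, n1) # construction guarantee
  expect_gt(n4 / n1, 2.5)
  pct <- function(h) mean(h$labels == "NREM")
  expect_lt(abs(pct(h4) - pct(h1)), 0.12)
})

test_that("spindle counts follow the Poisson oracle and rate zero is empty", {
  ## all-NREM hypnogram: 30 min at 8/min -> 240 expected, within 3 sqrt(240)
  hyp <- hypnogram(rep("NREM", 1800))
  p <- quick_params(seed = 13)
  sim <- simulate_recording(hyp, p)
  expect_lt(abs(nrow(sim$truth$spindles) - 240), 3 * sqrt(240))

  p0 <- quick_params(seed = 13, spindle_rate_per_min = 1e-9)
  sim0 <- simulate_recording(hyp, p0)
  expect_equal(nrow(sim0$truth$spindles), 0)
  ## no 10-16 Hz peak above background: spindle-band power comparable to
  ## its 1/f neighborhood
  ps <- normalize_psd(welch_psd(channel(sim0$recording, "EEG_front"), p0$fs))
  bp_sp <- band_power(ps, band("sp", 10, 16))
  bp_nb <- band_power(ps, band("nb", 16, 22))
  expect_lt(bp_sp / bp_nb, 2)
})

test_that("every true spindle lies wholly inside a NREM episode", {
  p <- quick_params(seed = 21, duration_s = 1200)
  hyp <- simulate_hypnogram(p)
  sim <- simulate_recording(hyp, p)
  tr <- sim$truth$spindles
  expect_gt(nrow(tr), 0)
  st <- somnotools:::sample_states(hyp, nrow(sim$recording$signals), p$fs)
  for (i in seq_len(nrow(tr))) {
    i0 <- floor(tr$start_s[i] * p$fs) + 1
    i1 <- ceiling(tr$end_s[i] * p$fs)
    expect_true(all(st[i0:i1] == "NREM"))
  }
})

test_that("coupled spindle peaks sit at the requested slow-oscillation phase", {
  hyp <- hypnogram(rep("NREM", 1200))
  p <- quick_params(seed = 17, couple_prob = 1, couple_phase_deg = 180)
  sim <- simulate_recording(hyp, p)
  ph <- sim$truth$spindles$phase_deg
  expect_gt(length(ph), 50)
  ## analytic phase at injected peak times is exactly the target
  expect_lt(max(abs(somnotools:::circ_diff_deg(ph, 180))), 1e-6)
  ## uncoupled: phases spread out (resultant below uniform-law bound)
  p0 <- quick_params(seed = 17, couple_prob = 0)
  sim0 <- simulate_recording(hyp, p0)
  r <- somnotools:::circ_mean_deg(sim0$truth$spindles$phase_deg)$resultant
  expect_lt(r, 2 / sqrt(nrow(sim0$truth$spindles)) + 0.1)
})

test_that("amplitude parameters scale the signal exactly linearly", {
  hyp <- hypnogram(rep(c("Wake", "NREM", "REM"), each = 60))
  base <- list(seed = 31, duration_s = 180)
  p1 <- do.call(quick_params, base)
  p3 <- do.call(quick_params, c(base, list(
    spindle_amp_uv = 3 * p1$spindle_amp_uv, so_amp_uv = 3 * p1$so_amp_uv,
    theta_amp_uv = 3 * p1$theta_amp_uv, noise_rms_uv = 3 * p1$noise_rms_uv,
    emg_rms_uv = 3 * p1$emg_rms_uv)))
  s1 <- simulate_recording(hyp, p1)$recording$signals
  s3 <- simulate_recording(hyp, p3)$recording$signals
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
})

test_that("tonic spike counts follow the Poisson oracle", {
  hyp <- hypnogram(rep("NREM", 600))
  p <- quick_params(seed = 19,
                    tonic_rate_hz = c(Wake = 10, NREM = 5, REM = 12),
                    burst_rate_per_min = c(Wake = 0, NREM = 0, REM = 0))
  u <- simulate_spike_train(hyp, p)
  expect_equal(nrow(u$bursts), 0)
  expect_lt(abs(length(u$train$times_s) - 3000), 3 * sqrt(3000))
})

test_that("ground-truth bursts satisfy their generative guarantees", {
  p <- quick_params(seed = 23, duration_s = 1200)
  hyp <- simulate_hypnogram(p)
  u <- simulate_spike_train(hyp, p)
  expect_gt(nrow(u$bursts), 10)
  t <- u$train$times_s
  isi_s <- p$intraburst_isi_ms / 1000
  for (i in seq_len(nrow(u$bursts))) {
    b0 <- u$bursts$start_s[i]
    nb <- u$bursts$n_spikes[i]
    idx <- which(abs(t - b0) < 1e-9)
    expect_length(idx, 1)
    ## all intra-burst ISIs equal the configured interval
    expect_equal(diff(t[idx:(idx + nb - 1)]), rep(isi_s, nb - 1),
                 tolerance = 1e-9)
    ## preceding gap at least the silence criterion
    if (idx > 1) expect_gte(b0 - t[idx - 1], p$pre_burst_silence_ms / 1000 - 1e-9)
  }
})

test_that("degenerate parameters are rejected", {
  expect_error(quick_params(intraburst_isi_ms = 120), "degenerate")
  expect_error(quick_params(couple_prob = 1.2), "couple_prob")
  expect_error(quick_params(spindle_dur_s = c(2, 1)), "spindle_dur_s")
  expect_warning(simulate_hypnogram(quick_params(duration_s = 100)), "unstable")
  ## spindle carrier too close to the slow-oscillation band
  p <- quick_params(so_freq_hz = 3.5, spindle_freq_hz = 10)
  hyp <- hypnogram(rep("NREM", 600))
  expect_error(simulate_recording(hyp, p), "overlaps")
})
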