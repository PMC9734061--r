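# Shared fixtures and independent oracles used across test files.

## Small, fast simulation defaults for unit tests.
quick_params <- function(...) {
  args <- utils::modifyList(list(duration_s = 600,
                                 channels = c("EEG_front", "EMG")),
                            list(...))
  do.call(sim_params, args)
}

## Greedy event matching at >= 50% overlap of the ground-truth duration.
## Returns recall, precision, and matched index pairs.
match_events <- function(truth, detected, min_frac = 0.5) {
  if (!nrow(truth) || !nrow(detected)) {
    return(list(recall = 0, precision = 0, pairs = cbind(integer(0), integer(0))))
  }
  hit_t <- logical(nrow(truth))
  hit_d <- logical(nrow(detected))
  pairs <- NULL
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(truth$end_s[i], detected$end_s) - pmax(truth$start_s[i], detected$start_s)
    ov[hit_d] <- -Inf
    j <- which.max(ov)
    if (ov[j] >= min_frac * truth$dur_s[i]) {
      hit_t[i] <- TRUE
      hit_d[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  ## unmatched detections may still overlap a truth event (duplicates count
  ## against precision only if they overlap nothing)
  fp <- vapply(which(!hit_d), function(j) {
    ov <- pmin(detected$end_s[j], truth$end_s) - pmax(detected$start_s[j], truth$start_s)
    !any(ov >= min_frac * pmin(detected$dur_s[j], truth$dur_s))
  }, logical(1))
  list(recall = mean(hit_t),
       precision = 1 - sum(fp) / nrow(detected),
       pairs = pairs)
}

## Independent brute-force burst oracle: split the train into maximal
## chains linked by ISI <= max_isi, then apply the silence and size rules.
## Deliberately a different algorithm from the package's scan.
brute_force_bursts <- function(times, criteria) {
  n <- length(times)
  if (n == 0) return(data.frame(start_s = numeric(0), n_spikes = integer(0),
                                dur_ms = numeric(0)))
  max_isi <- criteria$max_intraburst_isi_ms / 1000 + 1e-9
  silence <- criteria$min_preceding_silence_ms / 1000 - 1e-9
  grp <- cumsum(c(TRUE, diff(times) > max_isi))
  out <- NULL
  for (g in unique(grp)) {
    idx <- which(grp == g)
    first <- idx[1]
    pre_gap <- if (first == 1) Inf else times[first] - times[first - 1]
    if (length(idx) >= criteria$min_spikes && pre_gap >= silence) {
      out <- rbind(out, data.frame(
        start_s = times[first], n_spikes = length(idx),
        dur_ms = (times[idx[length(idx)]] - times[first]) * 1000
      ))
    }
  }
  if (is.null(out)) data.frame(start_s = numeric(0), n_spikes = integer(0),
                               dur_ms = numeric(0)) else out
}

## Constructed NREM signal with isolated (aperiodic) slow waves, each
## followed by a spindle burst at a fixed delay. Used for the
## cross-correlation delay-recovery oracle.
make_sw_delay_signal <- function(delay_s, fs = 200, dur_s = 600, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- somnotools:::noise_1f(length(t), 1, 10)
  pk <- cumsum(runif(ceiling(dur_s / 2.5), 2.5, 5))
  pk <- pk[pk > 10 & pk < dur_s - 10]
  for (p0 in pk) {
    tt <- seq(-0.5, 0.5, by = 1 / fs)
    idx <- round((p0 - 0.5) * fs) + seq_along(tt)
    x[idx] <- x[idx] + 200 * cos(2 * pi * tt) * 0.5 * (1 + cos(2 * pi * tt))
    ts <- seq(0, 0.6, by = 1 / fs)
    jdx <- round((p0 + delay_s - 0.3) * fs) + seq_along(ts)
    x[jdx] <- x[jdx] + 50 * 0.5 * (1 - cos(2 * pi * ts / 0.6)) * sin(2 * pi * 13 * ts)
  }
  list(x = x, hyp = hypnogram(rep("NREM", dur_s)), peaks = pk)
}
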