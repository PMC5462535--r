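# Shared fixtures: small designs and signal constructions used across
# test files. Everything is generated in code at test time.

fs_test <- 150

# Band-limited white noise, unit variance.
bl_noise <- function(n, band = c(0.25, 8), fs = fs_test) {
  v <- bandpass(stats::rnorm(n), band, rate_hz = fs)$values
  v / stats::sd(v)
}

# A tiny factorial design used by pipeline-level tests.
tiny_design <- function(n_participants = 4L, n_segments = 6L, duration_s = 12) {
  condition_design(n_participants = n_participants,
                   n_segments_per_condition = n_segments,
                   segment_duration_s = duration_s)
}

# Truth with one SNR-driven and one visual-context-driven node.
two_node_truth <- function(design, rng_seed = 1L, base_gain = 0.9, slope = 0.4) {
  cond <- conditions(design)
  snr_c <- (cond$snr_db - mean(design$snr_levels)) / stats::sd(design$snr_levels)
  gains <- rbind(NodeA = pmax(base_gain + slope * snr_c, 0.05),
                 NodeB = ifelse(cond$visual == "VI", base_gain, 0.1))
  colnames(gains) <- cond$condition
  synth_truth(node_gain = gains,
              node_lag_ms = c(NodeA = 60, NodeB = 100),
              rng_seed = rng_seed)
}

# Per-segment signal family with a known envelope->neural lag.
lagged_cell <- function(gain, lag, nseg = 6, n = 1800, seed0 = 1, band = c(1, 4)) {
  env <- lapply(seq_len(nseg), function(s) {
    gen_envelope(n / fs_test, fs_test, seed = seed0 * 1000 + s)$values
  })
  neural <- lapply(seq_len(nseg), function(s) {
    nz <- bl_noise(n, c(0.25, 48))
    shifted <- avspeechinfo:::shift_samples(env[[s]], lag)
    gain * shifted / stats::sd(shifted) + nz
  })
  list(
    env = lapply(env, function(v) bandpass(v, band, rate_hz = fs_test)$values),
    neural = lapply(neural, function(v) bandpass(v, band, rate_hz = fs_test)$values)
  )
}
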