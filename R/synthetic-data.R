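# Synthetic audio-visual speech datasets with known ground truth.
#
# The generator emulates the statistical structure of a factorial
# listening study: a low-frequency-dominated speech envelope, a lip
# trajectory coherent with the envelope in the delta/theta range,
# multi-node neural signals carrying lagged envelope information with
# condition-dependent gain plus directed inter-node coupling at fixed
# lags, and behavioral accuracies rising with acoustic SNR with a
# visual-context bonus.

#' Factorial condition design
#'
#' @param snr_levels Ordered acoustic SNR levels in dB (default 2, 4, 6, 8).
#' @param visual_levels Two-level visual-context factor; `VI` (informative,
#'   coded +1) and `VN` (not informative, coded -1).
#' @param n_segments_per_condition Segments per condition (default 6).
#' @param segment_duration_s Segment duration in seconds (default 60).
#' @param n_participants Number of simulated participants (default 19).
#' @param sample_rate_hz Sampling rate (default 150 Hz).
#' @return A `condition_design` list; `conditions(design)` enumerates the
#'   `length(snr_levels) * 2` condition cells.
#' @export
condition_design <- function(snr_levels = c(2, 4, 6, 8),
                             visual_levels = c("VI", "VN"),
                             n_segments_per_condition = 6L,
                             segment_duration_s = 60,
                             n_participants = 19L,
                             sample_rate_hz = 150) {
  stopifnot(length(snr_levels) >= 1, length(visual_levels) == 2L,
            n_segments_per_condition >= 1, segment_duration_s > 0,
            n_participants >= 1, sample_rate_hz > 0)
  structure(list(snr_levels = as.numeric(snr_levels),
                 visual_levels = visual_levels,
                 n_segments_per_condition = as.integer(n_segments_per_condition),
                 segment_duration_s = segment_duration_s,
                 n_participants = as.integer(n_participants),
                 sample_rate_hz = sample_rate_hz),
            class = "condition_design")
}

#' Enumerate the condition cells of a design
#'
#' @param design A [condition_design()].
#' @return A data.frame with columns `condition` (label), `snr_db`,
#'   `visual` ("VI"/"VN") and `visual_code` (+1/-1).
#' @export
conditions <- function(design) {
  grid <- expand.grid(visual = design$visual_levels, snr_db = design$snr_levels,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$snr_db, grid$visual), , drop = FALSE]
  data.frame(condition = sprintf("snr%g_%s", grid$snr_db, grid$visual),
             snr_db = grid$snr_db, visual = grid$visual,
             visual_code = ifelse(grid$visual == "VI", 1, -1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ground-truth parameters for the synthetic generator
#'
#' @param node_gain Envelope-coupling gain per node and condition: a named
#'   numeric vector (one gain per node, constant over conditions) or a
#'   matrix with node rows and condition-label columns. Gains must be >= 0.
#' @param node_lag_ms Named vector of stimulus-to-node lags in ms (>= 0,
#'   whole samples at the design rate).
#' @param node_lip_gain Optional lip-coupling gain per node (named vector
#'   or node x condition matrix); defaults to 0.
#' @param edge_coupling Optional list of directed edges, each a list with
#'   `seed`, `target`, `gain`, `lag_ms`, and `speech_mediated` (logical:
#'   `TRUE` transfers the seed's envelope-driven component, `FALSE` its
#'   full signal).
#' @param behavior_params List with `intercept`, `snr_slope` (per dB, on
#'   the logit scale), `vi_bonus` (accuracy-scale VI-VN difference, one
#'   value per SNR level), `noise_sd` (accuracy scale).
#' @param lip_coherence Envelope-lip coherence level in \\[0, 1\\] (default 0.7).
#' @param lip_lag_ms Envelope-to-lip lag in ms (default 0).
#' @param noise_sd Standard deviation of the additive band-limited
#'   (0.25-48 Hz) Gaussian noise on each node (default 1).
#' @param participant_gain_sd Log-normal spread of per-participant gain
#'   multipliers (default 0.15); 0 disables between-participant variation.
#' @param rng_seed Master seed for dataset generation.
#' @return A `synth_truth` list.
#' @export
synth_truth <- function(node_gain,
                        node_lag_ms,
                        node_lip_gain = NULL,
                        edge_coupling = list(),
                        behavior_params = list(intercept = 1.0, snr_slope = 0.15,
                                               vi_bonus = c(0.02, 0.06, 0.03, 0.06),
                                               noise_sd = 0.06),
                        lip_coherence = 0.7,
                        lip_lag_ms = 0,
                        noise_sd = 1,
                        participant_gain_sd = 0.15,
                        rng_seed = 1L) {
  if (is.null(dim(node_gain))) {
    if (is.null(names(node_gain))) stop_invalid("node_gain must be named by node")
    node_gain <- matrix(node_gain, nrow = length(node_gain), ncol = 1,
                        dimnames = list(names(node_gain), NULL))
  }
  if (any(node_gain < 0)) stop_invalid("gains must be >= 0")
  nodes <- rownames(node_gain)
  if (!all(nodes %in% names(node_lag_ms))) stop_invalid("node_lag_ms must name every node")
  if (any(node_lag_ms < 0)) stop_invalid("lags must be >= 0")
  for (e in edge_coupling) {
    if (!all(c(e$seed, e$target) %in% nodes)) {
      stop_invalid("edge references unknown node: %s -> %s", e$seed, e$target)
    }
    if (e$gain < 0 || e$lag_ms < 0) stop_invalid("edge gains and lags must be >= 0")
  }
  structure(list(node_gain = node_gain, node_lag_ms = node_lag_ms,
                 node_lip_gain = node_lip_gain, edge_coupling = edge_coupling,
                 behavior_params = behavior_params, lip_coherence = lip_coherence,
                 lip_lag_ms = lip_lag_ms, noise_sd = noise_sd,
                 participant_gain_sd = participant_gain_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_truth")
}

#' Default ground truth emulating the study-like network structure
#'
#' Four nodes: `pSTG` (envelope gain rising with SNR), `PMC` (envelope
#' gain present in VI only, strongest at low SNR), `IFG` (driven by a
#' speech-mediated edge from `pSTG` at a fixed lag), and `VC` (lip-driven).
#'
#' @param design A [condition_design()].
#' @param gain_scale Overall coupling strength multiplier (default 1).
#' @param rng_seed Master seed.
#' @return A [synth_truth()].
#' @export
default_synth_truth <- function(design = condition_design(), gain_scale = 1,
                                rng_seed = 1L) {
  cond <- conditions(design)
  snr_c <- (cond$snr_db - mean(design$snr_levels)) / stats::sd(design$snr_levels)
  gains <- rbind(
    pSTG = pmax(0.8 + 0.35 * snr_c, 0.05),
    PMC  = ifelse(cond$visual == "VI", pmax(0.8 - 0.25 * snr_c, 0.05), 0.15),
    IFG  = rep(0.25, nrow(cond)),
    VC   = rep(0.15, nrow(cond))
  ) * gain_scale
  colnames(gains) <- cond$condition
  lip_gain <- rbind(pSTG = 0, PMC = 0, IFG = 0, VC = 0.8 * gain_scale)
  synth_truth(
    node_gain = gains,
    node_lag_ms = c(pSTG = 60, PMC = 120, IFG = 100, VC = 80),
    node_lip_gain = lip_gain,
    edge_coupling = list(
      list(seed = "pSTG", target = "IFG", gain = 0.7 * gain_scale,
           lag_ms = 80, speech_mediated = TRUE)
    ),
    rng_seed = rng_seed
  )
}

#' Generate a synthetic speech envelope
#'
#' Low-pass-filtered rectified 1/f-shaped noise: Gaussian noise is
#' spectrally shaped toward low frequencies, half-wave rectified, low-pass
#' filtered, and clipped to be non-negative. The resulting spectrum is
#' dominated by components below 8 Hz, mimicking the syllabic/prosodic
#' dominance of natural speech envelopes.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param rate_hz Sampling rate (> 0).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param cutoff_hz Low-pass cutoff (default 6 Hz).
#' @return A non-negative [sampled_signal()] of length
#'   `round(duration_s * rate_hz)`.
#' @export
gen_envelope <- function(duration_s, rate_hz, seed, cutoff_hz = 6) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop_invalid("duration_s must be > 0")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop_invalid("rate_hz must be > 0")
  n <- round(duration_s * rate_hz)
  x <- with_seed(seed, stats::rnorm(n))
  x <- shape_one_over_f(x, rate_hz)
  x <- pmax(x, 0)                        # half-wave rectification
  x <- lowpass(x, cutoff_hz, rate_hz)
  sampled_signal(pmax(x, 0), rate_hz, label = "synthetic envelope")
}

# 1/f amplitude shaping in the frequency domain (floor at 0.5 Hz keeps
# the DC/near-DC region bounded).
shape_one_over_f <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                   # two-sided frequency axis
  amp <- 1 / pmax(f, 0.5)
  Re(stats::fft(X * amp, inverse = TRUE) / n)
}

# Circular delay by an integer number of samples.
shift_samples <- function(x, d) {
  n <- length(x)
  d <- ((as.integer(round(d))) %% n + n) %% n
  if (d == 0) return(x)
  c(x[(n - d + 1L):n], x[1L:(n - d)])
}

ms_to_samples <- function(lag_ms, rate_hz, what = "lag") {
  s <- lag_ms / 1000 * rate_hz
  if (abs(s - round(s)) > 1e-6) {
    stop_invalid("%s of %g ms is not a whole number of samples at %g Hz", what, lag_ms, rate_hz)
  }
  as.integer(round(s))
}

#' Generate a lip trajectory coherent with an envelope
#'
#' Mixes a delayed, standardized copy of the envelope with an
#' independent, spectrally matched noise signal so that the 1-8 Hz
#' magnitude-squared coherence with the envelope increases monotonically
#' with `coherence_level` (approximately equal to it); `coherence_level = 0`
#' yields an independent signal.
#'
#' @param envelope A [sampled_signal()] envelope.
#' @param coherence_level Target coherence in \\[0, 1\\].
#' @param lag_ms Envelope-to-lip delay in ms.
#' @param seed Integer seed for the independent component.
#' @return A [sampled_signal()] of identical length and rate.
#' @export
gen_lip <- function(envelope, coherence_level, lag_ms = 0, seed = 1L) {
  if (!inherits(envelope, "sampled_signal")) stop_invalid("envelope must be a sampled_signal")
  if (coherence_level < 0 || coherence_level > 1) stop_invalid("coherence_level must be in [0, 1]")
  fs <- envelope$rate_hz
  n <- length(envelope$values)
  d <- ms_to_samples(lag_ms, fs, "lip lag")
  env_part <- scale(shift_samples(envelope$values, d))[, 1]
  noise <- gen_envelope(n / fs, fs, seed = child_seed(seed, 811L))
  noise_part <- scale(noise$values)[, 1]
  w <- sqrt(coherence_level)
  lip <- w * env_part + sqrt(1 - w^2) * noise_part
  sampled_signal(lip, fs, label = "synthetic lip trajectory")
}

#' Generate a full synthetic dataset
#'
#' For every participant, condition and segment, generates an envelope, a
#' coherent lip trajectory and node signals
#' `gain(node, condition) * envelope(t - lag) + lip term + edge terms + noise`,
#' where edge terms transfer a delayed component of the seed node per
#' `edge_coupling`, and the noise is Gaussian band-limited to 0.25-48 Hz.
#' Deterministic given `truth$rng_seed`.
#'
#' @param design A [condition_design()].
#' @param truth A [synth_truth()]; its condition-indexed gain matrices
#'   must use the design's condition labels (or a single column applied
#'   to all conditions).
#' @return An `av_dataset`: list with `design`, `truth`, `conditions`,
#'   `nodes` and `data[[participant]][[condition]]$segments`, each segment
#'   holding `envelope`, `lip` and a samples x nodes matrix `nodes`.
#' @export
gen_dataset <- function(design, truth) {
  cond <- conditions(design)
  fs <- design$sample_rate_hz
  nodes <- rownames(truth$node_gain)
  gain_m <- expand_condition_matrix(truth$node_gain, cond$condition, "node_gain")
  lip_m <- if (is.null(truth$node_lip_gain)) {
    matrix(0, length(nodes), nrow(cond), dimnames = list(nodes, cond$condition))
  } else {
    expand_condition_matrix(truth$node_lip_gain, cond$condition, "node_lip_gain")
  }
  node_lag <- vapply(nodes, function(nd) {
    ms_to_samples(truth$node_lag_ms[[nd]], fs, sprintf("lag for node %s", nd))
  }, integer(1))
  edge_lag <- vapply(truth$edge_coupling, function(e) {
    ms_to_samples(e$lag_ms, fs, sprintf("edge lag %s->%s", e$seed, e$target))
  }, integer(1))

  pfac <- with_seed(child_seed(truth$rng_seed, 7001L), {
    matrix(stats::rlnorm(design$n_participants * length(nodes),
                         meanlog = -truth$participant_gain_sd^2 / 2,
                         sdlog = truth$participant_gain_sd),
           design$n_participants, length(nodes), dimnames = list(NULL, nodes))
  })

  noise_band <- c(0.25, min(48, fs / 2 * 0.9))
  data <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    pc <- vector("list", nrow(cond))
    names(pc) <- cond$condition
    for (ci in seq_len(nrow(cond))) {
      segs <- vector("list", design$n_segments_per_condition)
      for (s in seq_len(design$n_segments_per_condition)) {
        base_seed <- child_seed(truth$rng_seed, p, ci, s)
        env <- gen_envelope(design$segment_duration_s, fs, seed = child_seed(base_seed, 1L))
        lip <- gen_lip(env, truth$lip_coherence, truth$lip_lag_ms,
                       seed = child_seed(base_seed, 2L))
        env_sd <- stats::sd(env$values)
        lip_sd <- stats::sd(lip$values)
        speech_comp <- noise_comp <- matrix(0, length(env$values), length(nodes),
                                            dimnames = list(NULL, nodes))
        for (ni in seq_along(nodes)) {
          nd <- nodes[ni]
          g <- gain_m[nd, ci] * pfac[p, nd]
          gl <- lip_m[nd, ci] * pfac[p, nd]
          speech_comp[, ni] <- g * shift_samples(env$values, node_lag[ni]) / env_sd +
            gl * shift_samples(lip$values, node_lag[ni]) / lip_sd
          nz <- with_seed(child_seed(base_seed, 100L + ni),
                          stats::rnorm(length(env$values), sd = 1))
          nzb <- bandpass(nz, noise_band, rate_hz = fs)$values
          noise_comp[, ni] <- truth$noise_sd * nzb / stats::sd(nzb)
        }
        sig <- speech_comp + noise_comp
        if (length(truth$edge_coupling) > 0) {
          for (ei in seq_along(truth$edge_coupling)) {
            e <- truth$edge_coupling[[ei]]
            src <- if (isTRUE(e$speech_mediated)) speech_comp[, e$seed] else sig[, e$seed]
            sig[, e$target] <- sig[, e$target] +
              e$gain * pfac[p, e$target] * shift_samples(src, edge_lag[ei])
          }
        }
        segs[[s]] <- list(envelope = env$values, lip = lip$values, nodes = sig)
      }
      pc[[ci]] <- list(segments = segs)
    }
    data[[p]] <- pc
  }
  structure(list(design = design, truth = truth, conditions = cond,
                 nodes = nodes, sample_rate_hz = fs, data = data),
            class = "av_dataset")
}

expand_condition_matrix <- function(m, cond_labels, what) {
  if (ncol(m) == 1L) {
    m <- matrix(m[, 1], nrow(m), length(cond_labels),
                dimnames = list(rownames(m), cond_labels))
  }
  if (!all(cond_labels %in% colnames(m))) {
    stop_invalid("%s must have a column for every condition label", what)
  }
  m[, cond_labels, drop = FALSE]
}

#' Generate behavioral accuracies
#'
#' Word-recognition accuracy per participant and condition from a
#' logistic base curve in SNR plus an accuracy-scale visual-context
#' bonus: the expected VI-VN difference at each SNR level equals the
#' corresponding `vi_bonus` entry. Gaussian participant noise is added
#' and values are clipped to \\[0, 1\\].
#'
#' @param design A [condition_design()].
#' @param truth A [synth_truth()] with `behavior_params` set.
#' @return A data.frame: `participant`, `condition`, `snr_db`, `visual`,
#'   `accuracy`.
#' @export
gen_behavior <- function(design, truth) {
  bp <- truth$behavior_params
  cond <- conditions(design)
  vi_bonus <- rep_len(bp$vi_bonus, length(design$snr_levels))
  base <- stats::plogis(bp$intercept + bp$snr_slope * (cond$snr_db - mean(design$snr_levels)))
  bonus <- vi_bonus[match(cond$snr_db, design$snr_levels)] * cond$visual_code / 2
  acc <- with_seed(child_seed(truth$rng_seed, 9001L), {
    mu <- rep(base + bonus, each = design$n_participants)
    mu + stats::rnorm(length(mu), sd = bp$noise_sd)
  })
  out <- data.frame(
    participant = rep(seq_len(design$n_participants), times = nrow(cond)),
    condition = rep(cond$condition, each = design$n_participants),
    snr_db = rep(cond$snr_db, each = design$n_participants),
    visual = rep(cond$visual, each = design$n_participants),
    accuracy = pmin(pmax(acc, 0), 1),
    stringsAsFactors = FALSE
  )
  out[order(out$participant, out$snr_db, out$visual), , drop = FALSE]
}
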