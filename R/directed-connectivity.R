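# Speech-conditioned directed information between node pairs over
# brain-lag x speech-lag grids, Z-scored against segment-shuffled nulls.
#
# Signals are filtered to 0.25-8 Hz before embedding. Neural responses
# enter as a bivariate embedding (signal, first difference); the
# conditioning speech envelope is scalar. Brain lag 0 is excluded from
# estimation (the seed/target past must be strictly past); it is kept
# in output tables as a padding row of NA.

#' Lag grid for directed-information analysis
#'
#' @param brain_max_ms Maximum brain lag (default 250 ms).
#' @param speech_max_ms Maximum speech lag (default 500 ms).
#' @param rate_hz Sampling rate (default 150 Hz).
#' @return A list with integer sample grids `brain_lags` (from 1) and
#'   `speech_lags` (from 0), both at 1-sample steps, plus `rate_hz`.
#' @export
lag_grid <- function(brain_max_ms = 250, speech_max_ms = 500, rate_hz = 150) {
  list(brain_lags = seq_len(floor(brain_max_ms / 1000 * rate_hz)),
       speech_lags = 0:floor(speech_max_ms / 1000 * rate_hz),
       rate_hz = rate_hz)
}

#' Bivariate response embedding
#'
#' Pairs each sample with its first-order difference:
#' `(x_t, x_t - x_{t-1})` for `t = 2..n`. The first sample is dropped;
#' all variables entering one estimate must be aligned on this embedded
#' time base.
#'
#' @param signal Numeric vector or [sampled_signal()], length >= 2.
#' @return An `(n-1) x 2` matrix.
#' @export
embed_bivariate <- function(signal) {
  x <- as_signal_values(signal)
  if (length(x) < 2L) stop_invalid("need at least 2 samples to embed")
  cbind(x[-1L], diff(x))
}

#' Directed information (transfer entropy) at a brain lag
#'
#' `I(target_t ; seed_{t-tau} | target_{t-tau})` in bits — the
#' information the seed's past adds about the target's present beyond
#' the target's own past. Both signals enter through the bivariate
#' embedding.
#'
#' @param target,seed Numeric vectors (one segment) or lists of
#'   per-segment vectors; no estimate spans a segment boundary.
#' @param tau_brain Brain lag in samples (>= 1).
#' @return DI* in bits (>= 0).
#' @export
di_star <- function(target, seed, tau_brain) {
  tau_brain <- as.integer(tau_brain)
  if (tau_brain < 1L) stop_invalid("tau_brain must be >= 1 sample")
  segs <- di_prepare(target, seed, speech = NULL)
  # seed identical to target: the conditioning removes all shared past,
  # I(X_t; X_{t-tau} | X_{t-tau}) = 0 (the joint covariance is singular)
  if (isTRUE(all.equal(segs$target, segs$seed, tolerance = 1e-12))) return(0)
  idx <- di_indices(segs$lens, tau_brain, tau_speech = NULL)
  gcmi_cmi(segs$target[idx$t, , drop = FALSE],
           segs$seed[idx$t - tau_brain, , drop = FALSE],
           segs$target[idx$t - tau_brain, , drop = FALSE])
}

#' Speech-conditioned directed information
#'
#' `DI(tau_brain, tau_speech) = DI* - DI*|speech`: the transfer entropy
#' minus the same quantity additionally conditioned on the speech
#' envelope value at `t - tau_speech`. The subtraction removes terms
#' (including sampling bias and common-drive contributions) that cannot
#' carry speech information. Both terms are evaluated on the common
#' sample set so the difference is well defined. A constant speech
#' signal degenerates to conditioning on nothing and yields 0.
#'
#' @inheritParams di_star
#' @param speech Speech envelope, same segmentation as the node signals.
#' @param tau_speech Speech lag in samples (>= 0).
#' @return DI in bits (can be slightly negative through estimation noise).
#' @export
di_feature <- function(target, seed, speech, tau_brain, tau_speech) {
  tau_brain <- as.integer(tau_brain); tau_speech <- as.integer(tau_speech)
  if (tau_brain < 1L) stop_invalid("tau_brain must be >= 1 sample")
  if (tau_speech < 0L) stop_invalid("tau_speech must be >= 0")
  segs <- di_prepare(target, seed, speech)
  idx <- di_indices(segs$lens, tau_brain, tau_speech)
  x <- segs$target[idx$t, , drop = FALSE]
  y <- segs$seed[idx$t - tau_brain, , drop = FALSE]
  z <- segs$target[idx$t - tau_brain, , drop = FALSE]
  sp <- segs$speech[idx$t - tau_speech]
  base <- gcmi_cmi(x, y, z)
  cond <- tryCatch(gcmi_cmi(x, y, cbind(z, sp)), error = function(e) base)
  base - cond
}

# Embed and stack segments; returns concatenated embedded matrices and
# per-segment embedded lengths.
di_prepare <- function(target, seed, speech = NULL) {
  tl <- if (is.list(target)) target else list(target)
  sl <- if (is.list(seed)) seed else list(seed)
  if (length(tl) != length(sl)) stop_invalid("target and seed must have matching segments")
  pl <- if (!is.null(speech)) { if (is.list(speech)) speech else list(speech) } else NULL
  te <- lapply(tl, embed_bivariate)
  se <- lapply(sl, embed_bivariate)
  pe <- if (!is.null(pl)) lapply(pl, function(v) as_signal_values(v)[-1L]) else NULL
  list(target = do.call(rbind, te), seed = do.call(rbind, se),
       speech = if (!is.null(pe)) unlist(pe) else NULL,
       lens = vapply(te, nrow, integer(1)))
}

# Global row indices t (on the concatenated embedded time base) such
# that t and its lagged partners stay inside one segment.
di_indices <- function(lens, tau_brain, tau_speech = NULL) {
  tau_min <- max(tau_brain, tau_speech %||% 0L)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  t <- unlist(lapply(seq_along(lens), function(i) {
    if (lens[i] <= tau_min) return(integer(0))
    offs[i] + (tau_min + 1L):lens[i]
  }))
  if (length(t) < 16L) stop_invalid("segments too short for these lags")
  list(t = t)
}

#' Z-score a value against shuffle-null values
#'
#' @param value Observed statistic.
#' @param null_values Numeric vector of null statistics (>= 20 values,
#'   non-zero spread).
#' @return `(value - mean(null)) / sd(null)`.
#' @export
zscore_against_shuffles <- function(value, null_values) {
  if (length(null_values) < 20L) stop_invalid("need at least 20 null values")
  s <- stats::sd(null_values)
  if (!is.finite(s) || s <= 0) stop_invalid("degenerate input: zero null variance")
  (value - mean(null_values)) / s
}

#' Directed-information grid for one seed/target/speech triple
#'
#' Evaluates DI* for every brain lag and DI for every brain x speech lag
#' combination. For grid evaluation each embedded column is
#' rank-normalized once over the full (concatenated) series and lagged
#' copies are then read off by indexing, which makes the dense grid
#' tractable; the standalone [di_star()]/[di_feature()] estimates, which
#' re-rank per lagged subset, agree closely and serve as the reference
#' semantics.
#'
#' @param target,seed,speech Per-segment lists of numeric vectors
#'   (already band-limited).
#' @param grid A [lag_grid()].
#' @return List with `di_star` (named vector over brain lags) and `di`
#'   (matrix brain lags x speech lags, dimnames in samples).
#' @export
di_grid <- function(target, seed, speech, grid = lag_grid()) {
  segs <- di_prepare(target, seed, speech)
  cols <- cbind(segs$target, segs$seed, segs$speech)
  cols <- apply(cols, 2L, function(v) copula_transform(v)[, 1])
  Tm <- cols[, 1:2, drop = FALSE]; Sm <- cols[, 3:4, drop = FALSE]
  sp <- cols[, 5]
  lens <- segs$lens
  nb <- length(grid$brain_lags); ns <- length(grid$speech_lags)
  di_s <- stats::setNames(numeric(nb), grid$brain_lags)
  di <- matrix(NA_real_, nb, ns, dimnames = list(grid$brain_lags, grid$speech_lags))
  for (bi in seq_len(nb)) {
    tb <- grid$brain_lags[bi]
    for (si in seq_len(ns)) {
      ts <- grid$speech_lags[si]
      idx <- tryCatch(di_indices(lens, tb, ts), error = function(e) NULL)
      if (is.null(idx)) next
      t <- idx$t
      X <- cbind(Tm[t, , drop = FALSE], Sm[t - tb, , drop = FALSE],
                 Tm[t - tb, , drop = FALSE], sp[t - ts])
      base <- cmi_cols(X, 1:2, 3:4, 5:6)
      cond <- cmi_cols(X, 1:2, 3:4, 5:7)
      di[bi, si] <- base - cond
      if (si == 1L) di_s[bi] <- base
    }
  }
  list(di_star = di_s, di = di)
}

# Gaussian CMI from pre-transformed columns of X (indices give the x, y
# and conditioning blocks).
cmi_cols <- function(X, ix, iy, iz) {
  Xc <- sweep(X, 2L, colMeans(X))
  cc <- crossprod(Xc) / (nrow(X) - 1)
  cmi <- 0.5 * (logdet2(cc[c(ix, iz), c(ix, iz), drop = FALSE]) +
                logdet2(cc[c(iy, iz), c(iy, iz), drop = FALSE]) -
                logdet2(cc[iz, iz, drop = FALSE]) - logdet2(cc))
  max(cmi, 0)
}

#' Z-scored directed information over the grid, against segment shuffles
#'
#' Recomputes the DI grid with the seed and speech segments permuted
#' relative to the target (the same randomization scheme as the MI bias
#' correction) and Z-scores every grid point against its shuffle
#' distribution.
#'
#' @inheritParams di_grid
#' @param n_shuffles Number of seeded shuffles (default 100, min 20).
#' @param seed_rng Seed for the shuffle set.
#' @return List with `di` (raw grid), `z` (Z-scored grid) and
#'   `n_shuffles`.
#' @export
di_grid_z <- function(target, seed, speech, grid = lag_grid(), n_shuffles = 100L,
                      seed_rng = 1L) {
  if (n_shuffles < 20L) stop_invalid("need at least 20 shuffles")
  S <- length(target)
  if (S < 2L) stop_invalid("need at least 2 segments to shuffle")
  obs <- di_grid(target, seed, speech, grid)
  # identity assignments are excluded: they would leak the observed
  # statistic into its own null
  perms <- with_seed(seed_rng, {
    out <- matrix(0L, n_shuffles, S)
    for (k in seq_len(n_shuffles)) {
      p <- sample.int(S)
      while (all(p == seq_len(S))) p <- sample.int(S)
      out[k, ] <- p
    }
    out
  })
  nulls <- array(NA_real_, dim = c(dim(obs$di), n_shuffles))
  nulls_star <- matrix(NA_real_, length(obs$di_star), n_shuffles)
  for (k in seq_len(n_shuffles)) {
    p <- perms[k, ]
    nk <- di_grid(target, seed[p], speech[p], grid)
    nulls[, , k] <- nk$di
    nulls_star[, k] <- nk$di_star
  }
  mu <- apply(nulls, c(1, 2), mean)
  sdv <- apply(nulls, c(1, 2), stats::sd)
  z <- (obs$di - mu) / ifelse(sdv > 0, sdv, NA_real_)
  mu_s <- rowMeans(nulls_star)
  sd_s <- apply(nulls_star, 1L, stats::sd)
  z_star <- (obs$di_star - mu_s) / ifelse(sd_s > 0, sd_s, NA_real_)
  list(di = obs$di, di_star = obs$di_star, z = z, z_star = z_star,
       n_shuffles = n_shuffles)
}

#' Recover the coupling lags of a directed edge from a DI grid
#'
#' Two-step readout mirroring the quadratic-vertex rule of the
#' entrainment lag search: the brain lag is the rounded vertex of a
#' least-squares parabola fitted around the peak of the DI* profile,
#' and the speech lag is the rounded vertex around the peak of the DI
#' slice at that brain lag. The joint 2-D grid maximum is not used
#' because for smooth band-limited signals it drifts along the flat
#' `tau_speech - tau_brain` ridge; the profile peaks localize.
#'
#' @param res A [di_grid()] result (or list with `di_star` and `di`).
#' @param grid The [lag_grid()] the result was computed on.
#' @param halfwidth Samples on each side of the peak entering the
#'   parabola fit (default 5).
#' @return List with `tau_brain` and `tau_speech` in samples.
#' @export
di_recover_lags <- function(res, grid, halfwidth = 5L) {
  vertex <- function(lags, values) {
    pk <- which.max(values)
    idx <- max(1L, pk - halfwidth):min(length(values), pk + halfwidth)
    if (length(idx) < 3L) return(lags[pk])
    co <- stats::lm.fit(cbind(1, lags[idx], lags[idx]^2), values[idx])$coefficients
    if (!is.finite(co[3]) || co[3] >= 0) return(lags[pk])
    v <- -co[2] / (2 * co[3])
    round(min(max(v, min(lags)), max(lags)))
  }
  tb <- vertex(grid$brain_lags, as.numeric(res$di_star))
  slice <- res$di[as.character(tb), ]
  ts <- vertex(grid$speech_lags, as.numeric(slice))
  list(tau_brain = as.integer(tb), tau_speech = as.integer(ts))
}

#' Condition-specific DI table for node pairs of a synthetic dataset
#'
#' Band-limits node signals and envelope to `di_band`, evaluates the
#' Z-scored DI grid per participant, directed pair and condition, and
#' returns a tidy table.
#'
#' @param dataset An `av_dataset`.
#' @param pairs Data.frame with columns `seed`, `target` (node names).
#' @param grid A [lag_grid()].
#' @param n_shuffles Shuffles for Z-scoring.
#' @param di_band Analysis band (default 0.25-8 Hz).
#' @param seed Seed for shuffles.
#' @return Tidy data.frame: `participant`, `seed`, `target`,
#'   `tau_brain_ms`, `tau_speech_ms`, `condition`, `snr_db`, `visual`,
#'   `di_bits`, `z`.
#' @export
di_table <- function(dataset, pairs, grid = lag_grid(rate_hz = dataset$sample_rate_hz),
                     n_shuffles = 20L, di_band = c(0.25, 8), seed = 1L) {
  fs <- dataset$sample_rate_hz
  rows <- list(); r <- 1L
  for (pi in seq_len(nrow(pairs))) {
    sd_node <- pairs$seed[pi]; tg_node <- pairs$target[pi]
    if (!all(c(sd_node, tg_node) %in% dataset$nodes)) {
      stop_invalid("unknown node in pair %s -> %s", sd_node, tg_node)
    }
    for (p in seq_along(dataset$data)) {
      for (ci in seq_len(nrow(dataset$conditions))) {
        cnd <- dataset$conditions$condition[ci]
        segs <- dataset$data[[p]][[cnd]]$segments
        tgt <- lapply(segs, function(s) bandpass(s$nodes[, tg_node], di_band, rate_hz = fs)$values)
        sed <- lapply(segs, function(s) bandpass(s$nodes[, sd_node], di_band, rate_hz = fs)$values)
        spc <- lapply(segs, function(s) bandpass(s$envelope, di_band, rate_hz = fs)$values)
        res <- di_grid_z(tgt, sed, spc, grid, n_shuffles = max(20L, n_shuffles),
                         seed_rng = child_seed(seed, pi, p, ci))
        gr <- expand.grid(tau_brain = grid$brain_lags, tau_speech = grid$speech_lags)
        rows[[r]] <- data.frame(
          participant = p, seed = sd_node, target = tg_node,
          tau_brain_ms = gr$tau_brain / fs * 1000,
          tau_speech_ms = gr$tau_speech / fs * 1000,
          condition = cnd, snr_db = dataset$conditions$snr_db[ci],
          visual = dataset$conditions$visual[ci],
          di_bits = as.vector(res$di), z = as.vector(res$z),
          stringsAsFactors = FALSE, row.names = NULL)
        r <- r + 1L
      }
    }
  }
  do.call(rbind, rows)
}
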