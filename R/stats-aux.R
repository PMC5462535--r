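# Lateralization contrasts, neuro-behavioral correlations, behavioral
# repeated-measures ANOVA and amplitude condition effects.

#' Sign-permutation lateralization contrast
#'
#' Paired contrast of per-participant GLM betas between each ROI and its
#' contralateral counterpart. The paired-difference T statistic is
#' tested two-sided against a sign-flip null (each participant's
#' difference multiplied by a random sign, the same signs across ROIs),
#' with max-|T| correction across ROIs. When the sign-flip space
#' `2^P` does not exceed `n_perm` the enumeration is exhaustive and the
#' p-values exact.
#'
#' @param betas_roi,betas_contra Participant vectors, or participants x
#'   ROIs matrices.
#' @param n_perm Number of sign permutations (default 10,000).
#' @param seed RNG seed (unused on the exhaustive path).
#' @return Data.frame per ROI: `t`, `p_uncorrected`, `p_fwe`,
#'   `significant` (at FWE 0.05); attribute `exhaustive`.
#' @export
lateralization_contrast <- function(betas_roi, betas_contra, n_perm = 10000L,
                                    seed = 1L) {
  d <- as.matrix(betas_roi) - as.matrix(betas_contra)
  P <- nrow(d); R <- ncol(d)
  sdv <- apply(d, 2L, stats::sd)
  if (any(sdv <= 0)) stop_invalid("degenerate input: zero-variance difference")
  t_obs <- colMeans(d) / (sdv / sqrt(P))
  exhaustive <- 2^P <= n_perm
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), P)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * P, replace = TRUE), n_perm, P))
  }
  t_null <- apply(signs, 1L, function(s) {
    ds <- d * s
    colMeans(ds) / (apply(ds, 2L, stats::sd) / sqrt(P))
  })
  t_null <- matrix(t_null, nrow = R)
  max_null <- apply(abs(t_null), 2L, max)
  B <- ncol(t_null)
  p_unc <- vapply(seq_len(R), function(r) {
    if (exhaustive) mean(abs(t_null[r, ]) >= abs(t_obs[r]) - 1e-12)
    else (1 + sum(abs(t_null[r, ]) >= abs(t_obs[r]))) / (1 + B)
  }, numeric(1))
  p_fwe <- vapply(seq_len(R), function(r) {
    if (exhaustive) mean(max_null >= abs(t_obs[r]) - 1e-12)
    else (1 + sum(max_null >= abs(t_obs[r]))) / (1 + B)
  }, numeric(1))
  out <- data.frame(roi = colnames(d) %||% seq_len(R), t = t_obs,
                    p_uncorrected = p_unc, p_fwe = p_fwe,
                    significant = p_fwe <= 0.05, row.names = NULL)
  attr(out, "exhaustive") <- exhaustive
  out
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# Per-participant Fisher-Z correlation between performance and a neural
# table across conditions; neural may carry a lag dimension [P, C, L]
# whose Z values are averaged across lags.
participant_fisher_z <- function(performance, neural) {
  P <- nrow(performance)
  if (length(dim(neural)) == 2L) neural <- array(neural, dim = c(dim(neural), 1L))
  L <- dim(neural)[3]
  vapply(seq_len(P), function(p) {
    if (stats::sd(performance[p, ]) <= 0) {
      stop_invalid("degenerate input: constant performance across conditions")
    }
    mean(vapply(seq_len(L), function(l) {
      fisher_z(stats::cor(performance[p, ], neural[p, , l]))
    }, numeric(1)))
  }, numeric(1))
}

#' Neuro-behavioral correlation test
#'
#' For each region (or connection) computes the per-participant Pearson
#' correlation across conditions between behavioral performance and the
#' neural quantity, Fisher-Z transforms it (for lag-resolved input the
#' Z values are computed per lag and averaged across lags), and tests
#' the participant-average Z against zero: the null permutes the
#' condition labels of the neural table within participant (shared
#' across regions), p-values by the percentile method, FWE across
#' regions by the maximum statistic.
#'
#' @param performance Participants x conditions matrix (>= 3 conditions).
#' @param neural Named list, one entry per region: `[P, C]` matrix or
#'   `[P, C, L]` array (L lags).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed RNG seed.
#' @return Data.frame per region: `mean_r`, `r_sem`, `mean_z`, `t`,
#'   `p_uncorrected`, `p_fwe`, `significant`.
#' @export
neurobehav_correlation <- function(performance, neural, n_perm = 10000L, seed = 1L) {
  performance <- as.matrix(performance)
  P <- nrow(performance); C <- ncol(performance)
  if (C < 3) stop_invalid("need at least 3 conditions")
  if (!is.list(neural)) neural <- list(region = neural)
  R <- length(neural)
  z_obs <- vapply(neural, function(nv) mean(participant_fisher_z(performance, nv)),
                  numeric(1))
  r_part <- vapply(neural, function(nv) tanh(participant_fisher_z(performance, nv)),
                   numeric(P))
  r_part <- matrix(r_part, P, R)
  z_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perms <- replicate(P, sample.int(C))
      vapply(neural, function(nv) {
        if (length(dim(nv)) == 2L) nv <- array(nv, dim = c(dim(nv), 1L))
        shuffled <- nv
        for (p in seq_len(P)) shuffled[p, , ] <- nv[p, perms[, p], , drop = FALSE]
        mean(participant_fisher_z(performance, shuffled))
      }, numeric(1))
    }, numeric(R))
  })
  z_null <- matrix(z_null, nrow = R)
  max_null <- apply(z_null, 2L, max)
  p_unc <- vapply(seq_len(R), function(r) {
    (1 + sum(z_null[r, ] >= z_obs[r])) / (1 + n_perm)
  }, numeric(1))
  p_fwe <- vapply(seq_len(R), function(r) {
    (1 + sum(max_null >= z_obs[r])) / (1 + n_perm)
  }, numeric(1))
  tz <- apply(matrix(vapply(neural, function(nv) participant_fisher_z(performance, nv),
                            numeric(P)), P, R), 2L,
              function(v) mean(v) / (stats::sd(v) / sqrt(P)))
  data.frame(region = names(neural), mean_r = colMeans(r_part),
             r_sem = apply(r_part, 2L, stats::sd) / sqrt(P),
             mean_z = z_obs, t = tz, p_uncorrected = p_unc, p_fwe = p_fwe,
             significant = p_fwe <= 0.05, row.names = NULL)
}

#' Two-way repeated-measures ANOVA for behavioral accuracy
#'
#' Standard within-subject sums of squares for the SNR x visual
#' factorial with subject as the random factor; p-values use
#' Huynh-Feldt-corrected degrees of freedom (F itself unadjusted).
#' Partial eta squared is reported per effect.
#'
#' @param accuracy Either the data.frame from [gen_behavior()] (columns
#'   `participant`, `snr_db`, `visual`, `accuracy`) or a 3-d array
#'   `[participants, snr levels, visual levels]`.
#' @return Data.frame per effect (`SNR`, `VIVN`, `SNRxVIVN`): `df1`,
#'   `df2`, `F`, `eps_hf`, `p_hf`, `pes`.
#' @export
rm_anova_behavior <- function(accuracy) {
  Y <- if (is.data.frame(accuracy)) behavior_to_array(accuracy) else accuracy
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  if (any(!is.finite(Y))) stop_invalid("incomplete design: missing cells")
  g <- mean(Y)
  m_p <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_ab <- apply(Y, c(2, 3), mean); m_pa <- apply(Y, c(1, 2), mean)
  m_pb <- apply(Y, c(1, 3), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
  ss_as <- b * sum((sweep(sweep(m_pa, 1, m_p), 2, m_a) + g)^2)
  ss_bs <- a * sum((sweep(sweep(m_pb, 1, m_p), 2, m_b) + g)^2)
  ss_tot <- sum((Y - g)^2)
  ss_s <- a * b * sum((m_p - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  eff <- function(ss_e, ss_err, df1, df2, eps) {
    Fv <- (ss_e / df1) / (ss_err / df2)
    data.frame(df1 = df1, df2 = df2, F = Fv, eps_hf = eps,
               p_hf = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
               pes = ss_e / (ss_e + ss_err))
  }
  eps_a <- hf_epsilon(apply(Y, c(1, 2), mean))
  eps_ab <- hf_epsilon(interaction_scores(Y), contrasted = TRUE)
  out <- rbind(
    cbind(effect = "SNR", eff(ss_a, ss_as, a - 1, (a - 1) * (n - 1), eps_a)),
    cbind(effect = "VIVN", eff(ss_b, ss_bs, b - 1, (b - 1) * (n - 1), 1)),
    cbind(effect = "SNRxVIVN", eff(ss_ab, ss_abs, (a - 1) * (b - 1),
                                   (a - 1) * (b - 1) * (n - 1), eps_ab))
  )
  rownames(out) <- NULL
  out
}

behavior_to_array <- function(df) {
  snr <- sort(unique(df$snr_db)); vis <- sort(unique(df$visual))
  parts <- sort(unique(df$participant))
  Y <- array(NA_real_, dim = c(length(parts), length(snr), length(vis)))
  for (i in seq_len(nrow(df))) {
    Y[match(df$participant[i], parts), match(df$snr_db[i], snr),
      match(df$visual[i], vis)] <- df$accuracy[i]
  }
  if (any(is.na(Y))) stop_invalid("incomplete design: missing cells")
  Y
}

# Per-subject cell vectors (subjects x (a*b), cells ordered with the B
# index varying fastest) multiplied by the Kronecker product of the
# orthonormal effect contrasts — the transformed variables whose
# covariance drives the interaction sphericity estimate.
interaction_scores <- function(Y) {
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  cells <- matrix(0, n, a * b)
  for (p in seq_len(n)) cells[p, ] <- as.vector(t(Y[p, , ]))
  Cm <- kronecker(contr_orthonormal(a), contr_orthonormal(b))
  cells %*% Cm
}

# Huynh-Feldt epsilon from per-subject transformed scores (subjects x
# effect df columns, already in contrast space when `contrasted`):
# Greenhouse-Geisser epsilon, then the HF adjustment, capped at 1.
hf_epsilon <- function(scores, contrasted = FALSE) {
  n <- nrow(scores)
  if (!contrasted) {
    k <- ncol(scores)
    if (k < 3) return(1)
    scores <- scores %*% contr_orthonormal(k)
  }
  d <- ncol(scores)
  if (d < 2) return(1)
  S <- stats::cov(scores)
  gg <- sum(diag(S))^2 / (d * sum(S^2))
  hf <- (n * d * gg - 2) / (d * (n - 1 - d * gg))
  min(hf, 1)
}

contr_orthonormal <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

#' Condition effects on band-limited signal amplitude
#'
#' Averages the Hilbert amplitude of each band-passed node signal across
#' time and segments per condition, then applies the Freedman-Lane GLM
#' jointly over node x band indices (max-statistic FWE across them).
#'
#' @param dataset An `av_dataset`.
#' @param bands Band data.frame (rows of [band_bank()]).
#' @param effect GLM effect to test.
#' @param spec A [cluster_spec()].
#' @param seed RNG seed.
#' @return A `stat_result` with index labels `node|band` in
#'   `index_labels`.
#' @export
amplitude_condition_glm <- function(dataset, bands = band_bank(),
                                    effect = "VIVN", spec = cluster_spec(),
                                    seed = 1L) {
  amp <- amplitude_table(dataset, bands)
  res <- freedman_lane_glm(amp$values, dataset$conditions, effect, spec, seed)
  res$index_labels <- amp$labels
  res
}

#' Mean Hilbert amplitude per participant, node, band and condition
#'
#' @inheritParams amplitude_condition_glm
#' @return List with `values` (`[participants, conditions, node x band]`
#'   array) and `labels`.
#' @export
amplitude_table <- function(dataset, bands = band_bank()) {
  fs <- dataset$sample_rate_hz
  labels <- as.vector(outer(dataset$nodes, bands$band, paste, sep = "|"))
  P <- length(dataset$data); C <- nrow(dataset$conditions)
  vals <- array(0, dim = c(P, C, length(labels)))
  k <- 0L
  for (bi in seq_len(nrow(bands))) {
    band <- c(bands$low_hz[bi], bands$high_hz[bi])
    for (nd in dataset$nodes) {
      k <- match(paste(nd, bands$band[bi], sep = "|"), labels)
      for (p in seq_len(P)) {
        for (ci in seq_len(C)) {
          segs <- dataset$data[[p]][[dataset$conditions$condition[ci]]]$segments
          vals[p, ci, k] <- mean(vapply(segs, function(s) {
            mean(hilbert_analytic(bandpass(s$nodes[, nd], band, rate_hz = fs))$amplitude)
          }, numeric(1)))
        }
      }
    }
  }
  list(values = vals, labels = labels)
}
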