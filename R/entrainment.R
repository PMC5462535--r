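# Condition-specific speech/lip MI, CMI and redundancy with optimal-lag
# search and permutation-based bias correction.
#
# The null/bias scheme permutes the assignment of stimulus segments to
# neural segments: one permutation of the segment indices is applied
# identically within every condition (and across bands for a given
# draw). With 6 segments the exhaustive set has 6! = 720 permutations;
# at reduced scale a seeded random subset is used.

#' Lag-search specification
#'
#' @param lag_range_samples Inclusive integer lag range searched
#'   (default 0:37, i.e. 0-250 ms at 150 Hz).
#' @param fdr_q FDR level for lag significance (default 0.01).
#' @param n_null Number of segment permutations for lag significance and
#'   bias correction (default 120; use `NULL` for the exhaustive set).
#' @return A `lag_search_spec` list.
#' @export
lag_search_spec <- function(lag_range_samples = 0:37, fdr_q = 0.01, n_null = 120L) {
  if (length(lag_range_samples) < 1) stop_invalid("lag range must be non-empty")
  if (fdr_q <= 0 || fdr_q >= 1) stop_invalid("fdr_q must be in (0, 1)")
  structure(list(lag_range_samples = as.integer(lag_range_samples),
                 fdr_q = fdr_q, n_null = n_null),
            class = "lag_search_spec")
}

#' Segment-permutation set
#'
#' Exhaustive set of all `n!` permutations when `n_perm` is `NULL` or at
#' least `n!`; otherwise a seeded random subset that always includes the
#' identity (the identity belongs to the exhaustive set the subset
#' stands in for).
#'
#' @param n_segments Number of segments.
#' @param n_perm Requested number of permutations or `NULL`.
#' @param seed Seed for the random subset.
#' @return Integer matrix, one permutation per row.
#' @export
segment_permutations <- function(n_segments, n_perm = NULL, seed = 1L) {
  if (n_segments < 1) stop_invalid("need at least one segment")
  total <- factorial(n_segments)
  if (is.null(n_perm) || n_perm >= total) {
    return(all_permutations(n_segments))
  }
  if (n_perm < 1) stop_invalid("empty permutation set")
  with_seed(seed, {
    rows <- unique(rbind(seq_len(n_segments),
                         t(replicate(n_perm * 2L, sample.int(n_segments)))))
    rows[seq_len(min(n_perm, nrow(rows))), , drop = FALSE]
  })
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      row[row >= k] <- row[row >= k] + 1L
      out[r, ] <- c(k, row)
      r <- r + 1L
    }
  }
  out
}

# Align neural/feature segments at a lag: neural[t] is paired with
# feature[t - lag]. Returns per-segment blocks of equal length.
trim_at_lag <- function(neural_segs, feature_segs, lag) {
  lag <- as.integer(lag)
  if (lag < 0) stop_invalid("lag must be >= 0")
  xs <- lapply(neural_segs, function(v) v[(lag + 1L):length(v)])
  ys <- lapply(feature_segs, function(m) {
    m <- as.matrix(m)
    m[1L:(nrow(m) - lag), , drop = FALSE]
  })
  if (any(vapply(xs, length, integer(1)) < 8L)) stop_invalid("segments too short at this lag")
  list(x = xs, y = ys)
}

# MI family under a set of segment permutations. Copula transforms are
# computed once on the identity concatenation; because permuting the
# stimulus segments only reorders whole blocks of the transformed
# feature, every permuted covariance is assembled from precomputed
# block cross-products. Returns the vector of MI values (bits), one per
# permutation row (row of the identity permutation = the raw MI).
mi_family <- function(neural_segs, feature_segs, lag, perm_matrix) {
  tr <- trim_at_lag(neural_segs, feature_segs, lag)
  S <- length(tr$x)
  lens <- vapply(tr$x, length, integer(1))
  xall <- copula_transform(unlist(tr$x))[, 1]
  yall <- copula_transform(do.call(rbind, tr$y))
  K <- ncol(yall)
  N <- length(xall)
  idx <- split(seq_len(N), rep(seq_len(S), lens))
  xb <- lapply(idx, function(i) xall[i])
  yb <- lapply(idx, function(i) yall[i, , drop = FALSE])
  mx <- mean(xall); my <- colMeans(yall)
  vx <- sum((xall - mx)^2) / (N - 1)
  cyy <- stats::cov(yall)
  # G[[c]][i, j] = sum over t of x-block i times column c of y-block j
  G <- lapply(seq_len(K), function(c) {
    m <- matrix(0, S, S)
    for (i in seq_len(S)) for (j in seq_len(S)) {
      if (lens[i] == lens[j]) m[i, j] <- sum(xb[[i]] * yb[[j]][, c])
    }
    m
  })
  ldyy <- logdet2(as.matrix(cyy))
  if (K == 1L) {
    # univariate feature: MI reduces to -0.5 log2(1 - r^2)
    cross <- vapply(seq_len(nrow(perm_matrix)), function(pi) {
      sum(G[[1]][cbind(seq_len(S), perm_matrix[pi, ])])
    }, numeric(1))
    r2 <- ((cross - N * mx * my[1]) / (N - 1))^2 / (vx * cyy[1, 1])
    return(pmax(-0.5 * log2(pmax(1 - r2, .Machine$double.eps)), 0))
  }
  apply(perm_matrix, 1L, function(p) {
    cross <- vapply(seq_len(K), function(c) {
      (sum(G[[c]][cbind(seq_len(S), p)]) - N * mx * my[c]) / (N - 1)
    }, numeric(1))
    C <- rbind(c(vx, cross), cbind(cross, cyy))
    mi <- 0.5 * (log2(vx) + ldyy - logdet2(C))
    max(mi, 0)
  })
}

# MI-by-lag scan for a univariate feature under a shared permutation
# set. Copula transforms are computed once per cell on the full
# segments; each lag then trims the transformed blocks (the rank
# difference from re-ranking the trimmed subset is negligible for lags
# that are a small fraction of the segment length, and the permutation
# family stays internally consistent). Returns the observed MI vector
# and the lags x permutations null matrix.
mi_lag_scan <- function(neural_segs, feature_segs, lags, perm_matrix) {
  S <- length(neural_segs)
  lens <- vapply(neural_segs, length, integer(1))
  x <- copula_transform(unlist(neural_segs))[, 1]
  y <- copula_transform(unlist(feature_segs))[, 1]
  offs <- cumsum(c(0L, lens[-S]))
  id_first <- all(perm_matrix[1, ] == seq_len(S))
  if (!id_first) perm_matrix <- rbind(seq_len(S), perm_matrix)
  n_perm <- nrow(perm_matrix)
  obs <- numeric(length(lags))
  fam <- matrix(0, length(lags), n_perm)
  for (li in seq_along(lags)) {
    lag <- lags[li]
    xi <- unlist(lapply(seq_len(S), function(i) offs[i] + (lag + 1L):lens[i]))
    yi_blocks <- lapply(seq_len(S), function(i) y[offs[i] + 1L:(lens[i] - lag)])
    xb <- lapply(seq_len(S), function(i) x[offs[i] + (lag + 1L):lens[i]])
    xv <- x[xi]; N <- length(xv)
    mx <- mean(xv); vx <- stats::var(xv)
    yv <- unlist(yi_blocks)
    my <- mean(yv); vy <- stats::var(yv)
    G <- matrix(0, S, S)
    for (i in seq_len(S)) for (j in seq_len(S)) {
      if (length(xb[[i]]) == length(yi_blocks[[j]])) {
        G[i, j] <- sum(xb[[i]] * yi_blocks[[j]])
      }
    }
    cross <- vapply(seq_len(n_perm), function(pi) {
      sum(G[cbind(seq_len(S), perm_matrix[pi, ])])
    }, numeric(1))
    r2 <- ((cross - N * mx * my) / (N - 1))^2 / (vx * vy)
    mi <- pmax(-0.5 * log2(pmax(1 - r2, .Machine$double.eps)), 0)
    obs[li] <- mi[1]
    fam[li, ] <- mi
  }
  if (!id_first) fam <- fam[, -1L, drop = FALSE]
  list(obs = obs, fam = fam, perm_matrix = perm_matrix)
}

# Raw MI and its permutation family in one pass (the identity row is
# prepended when the permutation set does not already lead with it).
mi_raw_and_null <- function(neural_segs, feature_segs, lag, perm_matrix) {
  S <- ncol(perm_matrix)
  id_first <- all(perm_matrix[1, ] == seq_len(S))
  pm <- if (id_first) perm_matrix else rbind(seq_len(S), perm_matrix)
  fam <- mi_family(neural_segs, feature_segs, lag, pm)
  list(raw = fam[1],
       fam = if (id_first) fam else fam[-1])
}

#' Bias-corrected mutual information at a lag
#'
#' Raw MI between per-segment neural and stimulus-feature signals at the
#' given lag, minus the median MI recomputed under every segment-to-
#' feature permutation in `perm_matrix` (the permutation-based estimate
#' of the estimator's positive sampling bias).
#'
#' @param neural_segs List of numeric vectors (one per segment).
#' @param feature_segs List of numeric vectors or matrices (one per
#'   segment, same lengths as `neural_segs`).
#' @param lag Non-negative integer lag in samples (neural relative to
#'   feature).
#' @param perm_matrix Permutation set from [segment_permutations()];
#'   must be non-empty. With the identity alone the result is exactly 0.
#' @return Bias-corrected MI in bits (may be negative).
#' @export
bias_corrected_mi <- function(neural_segs, feature_segs, lag, perm_matrix) {
  if (is.null(perm_matrix) || nrow(perm_matrix) < 1) {
    stop_invalid("empty permutation set")
  }
  feature_segs <- lapply(feature_segs, as.matrix)
  rn <- mi_raw_and_null(neural_segs, feature_segs, lag, perm_matrix)
  rn$raw - stats::median(rn$fam)
}

#' Optimal lag from a quadratic fit to MI over significant lags
#'
#' Fits a least-squares parabola to the MI values at significant lags
#' and returns its vertex, clipped to the search range and rounded to
#' the nearest sample. If the fit is not concave the boundary with the
#' larger fitted value is returned (clipping contract). With fewer than
#' 3 significant lags `NA` is returned and the caller substitutes the
#' band-wise median estimate.
#'
#' @param mi_by_lag Numeric vector of (bias-corrected) MI values.
#' @param significance_mask Logical vector flagging significant lags.
#' @param spec A [lag_search_spec()] giving the lag axis.
#' @return Integer lag in samples, or `NA` (no-estimate signal).
#' @export
estimate_optimal_lag <- function(mi_by_lag, significance_mask, spec = lag_search_spec()) {
  lags <- spec$lag_range_samples
  stopifnot(length(mi_by_lag) == length(lags),
            length(significance_mask) == length(lags))
  keep <- which(significance_mask)
  if (length(keep) < 3L) return(NA_integer_)
  l <- as.numeric(lags[keep]); m <- mi_by_lag[keep]
  fit <- stats::lm.fit(cbind(1, l, l^2), m)
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  lo <- min(lags); hi <- max(lags)
  if (!is.finite(a) || a >= 0) {
    # not concave: take the boundary favoured by the fitted trend
    flo <- sum(fit$coefficients * c(1, lo, lo^2))
    fhi <- sum(fit$coefficients * c(1, hi, hi^2))
    return(as.integer(if (fhi >= flo) hi else lo))
  }
  vertex <- -b / (2 * a)
  as.integer(round(min(max(vertex, lo), hi)))
}

# Permutation p-values with the standard +1 correction.
perm_pvalue <- function(obs, null) (1 + sum(null >= obs)) / (1 + length(null))

#' Estimate optimal stimulus-to-brain lags for every node and band
#'
#' Computes the group-average MI-by-lag curve (pooled over participants
#' and conditions), derives permutation p-values per lag from the
#' matched group-average null curves, masks lags by Benjamini-Hochberg
#' FDR, and applies the quadratic-vertex rule. Nodes/bands without an
#' estimate receive the band-wise median lag.
#'
#' @param dataset An `av_dataset` from [gen_dataset()].
#' @param bands A [band_bank()] subset (data.frame rows used as bands).
#' @param spec A [lag_search_spec()].
#' @param feature `"envelope"` or `"lip"`.
#' @param seed Seed for the permutation subset.
#' @return A data.frame `node`, `band`, `lag_samples`.
#' @export
estimate_lags <- function(dataset, bands = band_bank()[1:2, ], spec = lag_search_spec(),
                          feature = c("envelope", "lip"), seed = 1L) {
  feature <- match.arg(feature)
  fs <- dataset$sample_rate_hz
  S <- dataset$design$n_segments_per_condition
  pm <- segment_permutations(S, spec$n_null, seed = child_seed(seed, 31L))
  out <- list()
  for (bi in seq_len(nrow(bands))) {
    band <- c(bands$low_hz[bi], bands$high_hz[bi])
    est <- integer(0)
    for (nd in dataset$nodes) {
      curves <- array(0, dim = c(length(spec$lag_range_samples), nrow(pm)))
      obs <- numeric(length(spec$lag_range_samples))
      n_cells <- 0L
      for (p in seq_along(dataset$data)) {
        for (cnd in dataset$conditions$condition) {
          segs <- dataset$data[[p]][[cnd]]$segments
          neural <- lapply(segs, function(s) bandpass(s$nodes[, nd], band, rate_hz = fs)$values)
          feat <- lapply(segs, function(s) {
            v <- if (feature == "envelope") s$envelope else s$lip
            bandpass(v, band, rate_hz = fs)$values
          })
          scan <- mi_lag_scan(neural, feat, spec$lag_range_samples, pm)
          obs <- obs + scan$obs
          curves <- curves + scan$fam
          n_cells <- n_cells + 1L
        }
      }
      obs <- obs / n_cells; curves <- curves / n_cells
      # identity rows would tie with the observed value by construction;
      # p-values use the non-identity nulls (with the +1 correction)
      nonid <- !apply(pm, 1L, function(p) all(p == seq_len(S)))
      pvals <- vapply(seq_along(obs), function(li) {
        perm_pvalue(obs[li], curves[li, nonid])
      }, numeric(1))
      mask <- stats::p.adjust(pvals, method = "BH") <= spec$fdr_q
      bias <- apply(curves, 1L, stats::median)
      est[nd] <- estimate_optimal_lag(obs - bias, mask, spec)
    }
    if (all(is.na(est))) est[] <- stats::median(spec$lag_range_samples)
    med <- stats::median(est, na.rm = TRUE)
    est[is.na(est)] <- as.integer(round(med))
    out[[bi]] <- data.frame(node = dataset$nodes, band = bands$band[bi],
                            lag_samples = as.integer(est[dataset$nodes]),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Condition-specific entrainment and decomposition table
#'
#' For every participant, node, band and condition computes
#' bias-corrected speech MI, lip MI (reported for VI conditions only),
#' conditional MI (`mi_joint - mi_lip`, both bias-corrected) and the
#' normalized redundancy (VI conditions), all at the supplied optimal
#' lags and under one shared segment-permutation scheme.
#'
#' @param dataset An `av_dataset`.
#' @param bands Band data.frame (rows of [band_bank()]).
#' @param lags Lag table from [estimate_lags()] (columns `node`, `band`,
#'   `lag_samples`), applied to both features, or with an optional
#'   `feature` column for feature-specific lags.
#' @param n_perm Permutations for bias correction (default 120; `NULL`
#'   for the exhaustive set).
#' @param seed Seed for the permutation subset.
#' @return A tidy data.frame: `participant`, `node`, `band`, `band_low`,
#'   `band_high`, `condition`, `snr_db`, `visual`, `measure`, `value`.
#' @export
condition_info_table <- function(dataset, bands, lags, n_perm = 120L, seed = 1L) {
  fs <- dataset$sample_rate_hz
  S <- dataset$design$n_segments_per_condition
  pm <- segment_permutations(S, n_perm, seed = child_seed(seed, 97L))
  rows <- list(); r <- 1L
  for (bi in seq_len(nrow(bands))) {
    band <- c(bands$low_hz[bi], bands$high_hz[bi])
    for (nd in dataset$nodes) {
      lag_row <- lags[lags$node == nd & lags$band == bands$band[bi], , drop = FALSE]
      if (nrow(lag_row) < 1) stop_invalid("no lag for node %s band %s", nd, bands$band[bi])
      lag_s <- lag_row$lag_samples[1]
      lag_l <- if ("feature" %in% names(lags) && any(lag_row$feature == "lip")) {
        lag_row$lag_samples[lag_row$feature == "lip"][1]
      } else lag_s
      for (p in seq_along(dataset$data)) {
        for (ci in seq_len(nrow(dataset$conditions))) {
          cnd <- dataset$conditions$condition[ci]
          segs <- dataset$data[[p]][[cnd]]$segments
          neural <- lapply(segs, function(s) bandpass(s$nodes[, nd], band, rate_hz = fs)$values)
          env <- lapply(segs, function(s) bandpass(s$envelope, band, rate_hz = fs)$values)
          lip <- lapply(segs, function(s) bandpass(s$lip, band, rate_hz = fs)$values)
          # align lip at its own lag before joining features on a common time base
          shift_l <- lag_l - lag_s
          lip_al <- lapply(lip, function(v) shift_samples(v, -shift_l))
          env_m <- lapply(env, as.matrix)
          lip_m <- lapply(lip_al, as.matrix)
          joint_m <- Map(cbind, env_m, lip_m)
          rn_s <- mi_raw_and_null(neural, env_m, lag_s, pm)
          rn_l <- mi_raw_and_null(neural, lip_m, lag_s, pm)
          rn_j <- mi_raw_and_null(neural, joint_m, lag_s, pm)
          mi_s <- rn_s$raw - stats::median(rn_s$fam)
          mi_l <- rn_l$raw - stats::median(rn_l$fam)
          mi_j <- rn_j$raw - stats::median(rn_j$fam)
          cmi <- mi_j - mi_l
          is_vi <- dataset$conditions$visual[ci] == "VI"
          meas <- c(mi_speech = mi_s, cmi = cmi)
          if (is_vi) {
            red <- if (mi_s + mi_l > 0) redundancy(mi_s, mi_l, mi_j) else NA_real_
            meas <- c(meas, mi_lip = mi_l, red = red)
          }
          rows[[r]] <- data.frame(
            participant = p, node = nd, band = bands$band[bi],
            band_low = band[1], band_high = band[2],
            condition = cnd, snr_db = dataset$conditions$snr_db[ci],
            visual = dataset$conditions$visual[ci],
            measure = names(meas), value = unname(meas),
            stringsAsFactors = FALSE, row.names = NULL)
          r <- r + 1L
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "lags") <- lags
  attr(out, "n_perm") <- nrow(pm)
  out
}

#' Per-participant bias-corrected MI with its permutation null values
#'
#' Returns, for one node/band/feature, the participant x condition
#' matrix of bias-corrected MI together with each participant's
#' bias-corrected null distribution (null minus median of nulls),
#' condition-averaged — the inputs the random-effects one-sample
#' permutation test expects.
#'
#' @inheritParams condition_info_table
#' @param node,band_row Node name and one-row band data.frame.
#' @param lag_samples Lag at which MI is evaluated.
#' @param feature `"envelope"` or `"lip"`.
#' @return List with `values` (participants x conditions) and `nulls`
#'   (participants x n_perm).
#' @export
mi_with_nulls <- function(dataset, node, band_row, lag_samples, n_perm = 120L,
                          feature = c("envelope", "lip"), seed = 1L) {
  feature <- match.arg(feature)
  fs <- dataset$sample_rate_hz
  S <- dataset$design$n_segments_per_condition
  band <- c(band_row$low_hz[1], band_row$high_hz[1])
  pm <- segment_permutations(S, n_perm, seed = child_seed(seed, 55L))
  P <- length(dataset$data)
  nc <- nrow(dataset$conditions)
  values <- matrix(0, P, nc, dimnames = list(NULL, dataset$conditions$condition))
  nulls <- matrix(0, P, nrow(pm))
  for (p in seq_len(P)) {
    null_acc <- matrix(0, nrow(pm), nc)
    for (ci in seq_len(nc)) {
      segs <- dataset$data[[p]][[dataset$conditions$condition[ci]]]$segments
      neural <- lapply(segs, function(s) bandpass(s$nodes[, node], band, rate_hz = fs)$values)
      feat <- lapply(segs, function(s) {
        v <- if (feature == "envelope") s$envelope else s$lip
        as.matrix(bandpass(v, band, rate_hz = fs)$values)
      })
      rn <- mi_raw_and_null(neural, feat, lag_samples, pm)
      med <- stats::median(rn$fam)
      values[p, ci] <- rn$raw - med
      null_acc[, ci] <- rn$fam - med
    }
    nulls[p, ] <- rowMeans(null_acc)
  }
  list(values = values, nulls = nulls)
}
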