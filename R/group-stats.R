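# Random-effects permutation inference: one-sample tests against
# participant-specific null distributions, Freedman-Lane condition GLMs,
# cluster-mass enhancement and max-statistic FWE control.

#' Cluster specification
#'
#' @param forming_threshold_t Cluster-forming threshold on |T|
#'   (default 2.1).
#' @param adjacency Either `NULL` (every index is its own cluster), an
#'   integer edge matrix (two columns, index pairs), or `"chain"` for
#'   consecutive-index adjacency (band chains).
#' @param n_perm Number of permutations (default 10,000; scale down for
#'   desk-size runs).
#' @param alpha_fwe Family-wise error level (default 0.05).
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(forming_threshold_t = 2.1, adjacency = NULL,
                         n_perm = 10000L, alpha_fwe = 0.05) {
  if (forming_threshold_t <= 0) stop_invalid("threshold must be > 0")
  structure(list(forming_threshold_t = forming_threshold_t,
                 adjacency = adjacency, n_perm = as.integer(n_perm),
                 alpha_fwe = alpha_fwe),
            class = "cluster_spec")
}

adjacency_edges <- function(adjacency, k) {
  if (is.null(adjacency)) return(matrix(integer(0), 0, 2))
  if (identical(adjacency, "chain")) {
    if (k < 2) return(matrix(integer(0), 0, 2))
    return(cbind(1:(k - 1L), 2:k))
  }
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop_invalid("adjacency must be a 2-column edge matrix")
  adjacency
}

#' Supra-threshold clusters and their masses
#'
#' Thresholds a T map at `|T| > forming_threshold_t`, labels connected
#' components of the surviving indices on the adjacency graph (positive
#' and negative excursions separately), and sums |T| within each
#' component.
#'
#' @param stat_map Numeric vector of T statistics indexed 1..K.
#' @param spec A [cluster_spec()] whose adjacency covers the indices.
#' @return A list of clusters, each `list(indices, sign, mass)`; empty
#'   when nothing exceeds the threshold.
#' @export
cluster_mass <- function(stat_map, spec = cluster_spec()) {
  k <- length(stat_map)
  edges <- adjacency_edges(spec$adjacency, k)
  out <- list()
  for (sgn in c(1, -1)) {
    keep <- which(sgn * stat_map > spec$forming_threshold_t)
    if (length(keep) == 0) next
    comp <- label_components(keep, edges)
    for (cl in comp) {
      out[[length(out) + 1L]] <- list(indices = cl, sign = sgn,
                                      mass = sum(abs(stat_map[cl])))
    }
  }
  out
}

# Union-find component labeling restricted to `keep` vertices.
label_components <- function(keep, edges) {
  parent <- stats::setNames(keep, keep)
  find <- function(i) {
    while (parent[[as.character(i)]] != i) {
      parent[[as.character(i)]] <<- parent[[as.character(parent[[as.character(i)]])]]
      i <- parent[[as.character(i)]]
    }
    i
  }
  if (nrow(edges) > 0) {
    inset <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    for (r in seq_len(nrow(inset))) {
      a <- find(inset[r, 1]); b <- find(inset[r, 2])
      if (a != b) parent[[as.character(a)]] <- b
    }
  }
  roots <- vapply(keep, find, numeric(1))
  unname(split(keep, roots))
}

max_cluster_mass <- function(stat_map, spec) {
  cl <- cluster_mass(stat_map, spec)
  if (length(cl) == 0) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
}

one_sample_t <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv <= 0)) stop_invalid("degenerate input: zero between-participant variance")
  mu / (sdv / sqrt(n))
}

#' Random-effects one-sample permutation test
#'
#' Tests whether participant-averaged bias-corrected quantities exceed
#' zero. The observed group T per index is compared with a permutation
#' distribution of the maximum cluster-enhanced statistic, built by
#' drawing one null value per participant per sample from the
#' participant-specific null distributions (the same draw across
#' indices, preserving the spatial/spectral correlation of the nulls).
#'
#' @param values Participants x indices matrix of bias-corrected values.
#' @param subject_nulls Participant null distributions: an array
#'   `[participants, indices, draws]`, or a `[participants, draws]`
#'   matrix applied to every index.
#' @param spec A [cluster_spec()].
#' @param seed RNG seed for the permutation draws.
#' @return A `stat_result` list: `t_map`, `clusters`, `fwe_threshold`,
#'   `significant_mask`, `perm_max` (the permutation distribution).
#' @export
rfx_onesample_test <- function(values, subject_nulls, spec = cluster_spec(), seed = 1L) {
  values <- as.matrix(values)
  P <- nrow(values); K <- ncol(values)
  if (P < 2) stop_invalid("need at least 2 participants")
  shared <- length(dim(subject_nulls)) == 2L
  M <- if (shared) ncol(subject_nulls) else dim(subject_nulls)[3]
  t_obs <- one_sample_t(values)
  perm_max <- with_seed(seed, {
    vapply(seq_len(spec$n_perm), function(b) {
      draw <- sample.int(M, P, replace = TRUE)
      nv <- if (shared) {
        matrix(subject_nulls[cbind(seq_len(P), draw)], P, K)
      } else {
        m <- matrix(0, P, K)
        for (p in seq_len(P)) m[p, ] <- subject_nulls[p, , draw[p]]
        m
      }
      sdv <- apply(nv, 2L, stats::sd)
      tn <- colMeans(nv) / (pmax(sdv, .Machine$double.eps) / sqrt(P))
      max_cluster_mass(tn, spec)
    }, numeric(1))
  })
  thr <- stats::quantile(perm_max, 1 - spec$alpha_fwe, names = FALSE, type = 1)
  clusters <- cluster_mass(t_obs, spec)
  sig <- logical(K)
  for (cl in clusters) if (cl$mass > thr) sig[cl$indices] <- TRUE
  structure(list(t_map = t_obs, clusters = clusters, fwe_threshold = thr,
                 significant_mask = sig, perm_max = perm_max,
                 n_perm = spec$n_perm),
            class = "stat_result")
}

#' Standardized factorial GLM design
#'
#' Builds the condition design matrix for the SNR x visual factorial:
#' per-participant z-scored SNR and visual-context regressors and their
#' elementwise product as the interaction column.
#'
#' @param cond Data.frame from [conditions()] (columns `snr_db`,
#'   `visual_code`), one row per condition in table order.
#' @return List with `X` (conditions x 4 matrix: intercept, SNR, VIVN,
#'   SNRxVIVN) and `effects` (column names of testable effects).
#' @export
glm_design <- function(cond) {
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  snr <- zs(cond$snr_db)
  viv <- zs(cond$visual_code)
  X <- cbind(intercept = 1, SNR = snr, VIVN = viv, SNRxVIVN = snr * viv)
  if (qr(X)$rank < ncol(X)) stop_invalid("rank-deficient design")
  list(X = X, effects = c("SNR", "VIVN", "SNRxVIVN"))
}

#' Freedman-Lane permutation GLM for condition effects
#'
#' Per participant the condition responses are z-scored and regressed on
#' the standardized design; the group T statistic on the per-participant
#' standardized betas of `effect` is assessed against a Freedman-Lane
#' permutation null: residuals of the reduced model (all regressors but
#' the tested one) are permuted across conditions within participant,
#' refitted, and the resulting group |T| maps are cluster-enhanced with
#' the maximum statistic retained (two-sided max-|T| FWE).
#'
#' @param values Participants x conditions matrix, or a 3-d array
#'   `[participants, conditions, indices]` tested jointly with FWE
#'   across indices.
#' @param cond Condition data.frame matching the columns of `values`.
#' @param effect One of `"SNR"`, `"VIVN"`, `"SNRxVIVN"`.
#' @param spec A [cluster_spec()].
#' @param seed RNG seed.
#' @return A `stat_result` list: `t_map`, `beta_map` (group mean
#'   standardized beta), `beta_sem`, `clusters`, `fwe_threshold`,
#'   `significant_mask`, `perm_max`.
#' @export
freedman_lane_glm <- function(values, cond, effect, spec = cluster_spec(), seed = 1L) {
  if (length(dim(values)) == 2L) {
    values <- array(values, dim = c(dim(values), 1L))
  }
  P <- dim(values)[1]; C <- dim(values)[2]; K <- dim(values)[3]
  if (C != nrow(cond)) stop_invalid("values/condition mismatch: %d columns vs %d conditions", C, nrow(cond))
  des <- glm_design(cond)
  if (!effect %in% des$effects) stop_invalid("unknown effect '%s'", effect)
  X <- des$X
  ei <- match(effect, colnames(X))
  H <- solve(crossprod(X), t(X))            # 4 x C projector
  Xr <- X[, -ei, drop = FALSE]
  Hr <- solve(crossprod(Xr), t(Xr))
  zs_rows <- function(m) t(apply(m, 1L, function(v) {
    s <- stats::sd(v)
    if (s <= 0) stop_invalid("degenerate input: constant response across conditions")
    (v - mean(v)) / s
  }))
  # Y[[k]]: P x C standardized responses per index
  Y <- lapply(seq_len(K), function(k) zs_rows(values[, , k]))
  beta_obs <- vapply(Y, function(y) (H %*% t(y))[ei, ], numeric(P))
  beta_obs <- matrix(beta_obs, P, K)
  t_obs <- one_sample_t(beta_obs)
  fit_r <- lapply(Y, function(y) {
    br <- Hr %*% t(y)                       # (3) x P
    fitted <- t(Xr %*% br)                  # P x C
    list(fitted = fitted, resid = y - fitted)
  })
  perm_max <- with_seed(child_seed(seed, 17L), {
    vapply(seq_len(spec$n_perm), function(b) {
      perms <- replicate(P, sample.int(C))
      tn <- vapply(seq_len(K), function(k) {
        ystar <- fit_r[[k]]$fitted
        for (p in seq_len(P)) {
          ystar[p, ] <- ystar[p, ] + fit_r[[k]]$resid[p, perms[, p]]
        }
        bstar <- (H %*% t(ystar))[ei, ]
        s <- stats::sd(bstar)
        mean(bstar) / (max(s, .Machine$double.eps) / sqrt(P))
      }, numeric(1))
      max_cluster_mass(tn, spec)
    }, numeric(1))
  })
  thr <- stats::quantile(perm_max, 1 - spec$alpha_fwe, names = FALSE, type = 1)
  clusters <- cluster_mass(t_obs, spec)
  sig <- logical(K)
  for (cl in clusters) if (cl$mass > thr) sig[cl$indices] <- TRUE
  structure(list(t_map = t_obs, beta_map = colMeans(beta_obs),
                 beta_sem = apply(beta_obs, 2L, stats::sd) / sqrt(P),
                 betas = beta_obs, clusters = clusters, fwe_threshold = thr,
                 significant_mask = sig, perm_max = perm_max, effect = effect,
                 n_perm = spec$n_perm),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result>%s %d indices, FWE threshold %.3f, %d significant\n",
              if (!is.null(x$effect)) paste0(" effect ", x$effect, ":") else "",
              length(x$t_map), x$fwe_threshold, sum(x$significant_mask)))
  invisible(x)
}
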