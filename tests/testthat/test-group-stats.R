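# Cluster-mass enhancement, RFX permutation tests, Freedman-Lane GLM,
# lateralization, neuro-behavioral correlations and the behavioral
# ANOVA.

# Brute-force connected-component labeling used as the oracle for
# cluster_mass.
brute_clusters <- function(keep, edges) {
  if (length(keep) == 0) return(list())
  remaining <- keep
  out <- list()
  while (length(remaining) > 0) {
    comp <- remaining[1]
    repeat {
      grow <- unique(c(
        edges[edges[, 1] %in% comp & edges[, 2] %in% remaining, 2],
        edges[edges[, 2] %in% comp & edges[, 1] %in% remaining, 1]))
      grow <- setdiff(grow, comp)
      if (length(grow) == 0) break
      comp <- c(comp, grow)
    }
    out[[length(out) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  out
}

test_that("cluster_mass handles empty, chain and arbitrary graphs", {
  spec <- cluster_spec(adjacency = "chain")
  expect_length(cluster_mass(c(1, 2, -1.5), spec), 0)
  cl <- cluster_mass(c(3, 3, 3), spec)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 9)
  # positive and negative excursions labeled separately
  cl2 <- cluster_mass(c(3, -3, 3), spec)
  expect_length(cl2, 3)
  # random graphs against brute-force labeling
  set.seed(41)
  for (i in 1:100) {
    k <- sample(4:12, 1)
    edges <- matrix(sample.int(k, 2 * sample(2:10, 1), replace = TRUE),
                    ncol = 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    tmap <- rnorm(k, sd = 2)
    got <- cluster_mass(tmap, cluster_spec(adjacency = edges))
    for (sgn in c(1, -1)) {
      keep <- which(sgn * tmap > 2.1)
      want <- brute_clusters(keep, edges)
      have <- lapply(Filter(function(cl) cl$sign == sgn, got),
                     function(cl) sort(cl$indices))
      expect_setequal(lapply(want, paste, collapse = ","),
                      lapply(have, paste, collapse = ","))
    }
  }
})

test_that("rfx one-sample test flags real effects and is calibrated", {
  set.seed(42)
  P <- 8; K <- 5; M <- 120
  nulls <- array(rnorm(P * K * M), dim = c(P, K, M))
  vals <- matrix(rnorm(P * K), P, K)
  vals[, 3] <- vals[, 3] + 5
  r <- rfx_onesample_test(vals, nulls, cluster_spec(n_perm = 400), seed = 1)
  expect_true(r$significant_mask[3])
  expect_false(any(r$significant_mask[-3]))
  # observed T map equals the direct one-sample T
  expect_equal(r$t_map[3], mean(vals[, 3]) / (sd(vals[, 3]) / sqrt(P)))
  # determinism
  r2 <- rfx_onesample_test(vals, nulls, cluster_spec(n_perm = 400), seed = 1)
  expect_identical(r$fwe_threshold, r2$fwe_threshold)
  expect_error(rfx_onesample_test(matrix(1, 4, 2), nulls[1:4, 1:2, ]),
               "zero between-participant variance")
  # null calibration at reduced scale
  set.seed(43)
  rej <- replicate(60, {
    nl <- array(rnorm(6 * 3 * 80), dim = c(6, 3, 80))
    vv <- matrix(rnorm(18), 6, 3)
    any(rfx_onesample_test(vv, nl, cluster_spec(n_perm = 200),
                           seed = sample.int(1e6, 1))$significant_mask)
  })
  expect_lt(mean(rej), 0.15)
})

test_that("freedman-lane GLM recovers pure effects and symmetries", {
  des <- conditions(condition_design())
  X <- glm_design(des)$X
  P <- 6
  y <- t(replicate(P, X[, "SNR"])) + matrix(rnorm(P * 8, sd = 1e-9), P, 8)
  r <- freedman_lane_glm(y, des, "SNR", cluster_spec(n_perm = 300), seed = 2)
  expect_equal(r$beta_map, 1, tolerance = 1e-6)
  expect_true(r$significant_mask)
  r0 <- freedman_lane_glm(y, des, "VIVN", cluster_spec(n_perm = 300), seed = 2)
  expect_equal(r0$beta_map, 0, tolerance = 1e-6)
  # flipping the visual labels flips the VIVN beta but not |T|
  set.seed(44)
  y2 <- t(replicate(P, X[, "VIVN"])) + matrix(rnorm(P * 8, sd = 0.2), P, 8)
  des_flip <- des
  des_flip$visual_code <- -des$visual_code
  ra <- freedman_lane_glm(y2, des, "VIVN", cluster_spec(n_perm = 300), seed = 3)
  rb <- freedman_lane_glm(y2, des_flip, "VIVN", cluster_spec(n_perm = 300), seed = 3)
  expect_equal(ra$beta_map, -rb$beta_map, tolerance = 1e-10)
  expect_equal(abs(ra$t_map), abs(rb$t_map), tolerance = 1e-10)
  expect_error(freedman_lane_glm(y, des, "nope"), "unknown effect")
})

test_that("freedman-lane FWE rejection under the null is near alpha", {
  set.seed(45)
  des <- conditions(condition_design())
  rej <- replicate(100, {
    vals <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
    any(freedman_lane_glm(vals, des, "SNR", cluster_spec(n_perm = 300),
                          seed = sample.int(1e6, 1))$significant_mask)
  })
  # binomial 95% envelope around 0.05 for 100 draws
  expect_gte(mean(rej), 0.00)
  expect_lte(mean(rej), 0.12)
})

test_that("lateralization contrast is exact under exhaustive sign-flips", {
  set.seed(46)
  d <- c(0.6, 0.7, 0.5, 0.8, 0.65)
  res <- lateralization_contrast(d, rep(0, 5), n_perm = 10000)
  expect_true(attr(res, "exhaustive"))
  # all-positive differences: only the two all-same sign patterns reach |T|
  expect_equal(res$p_uncorrected, 2 / 32)
  # identical inputs -> zero variance error
  expect_error(lateralization_contrast(d, d), "zero-variance")
  # shift + noise at n = 19 detected with correct sign
  set.seed(47)
  roi <- 0.4 + rnorm(19, sd = 0.2)
  contra <- rnorm(19, sd = 0.2)
  res2 <- lateralization_contrast(cbind(a = roi, b = contra),
                                  cbind(a = contra, b = contra + rnorm(19, sd = 0.2)),
                                  n_perm = 2000, seed = 3)
  expect_true(res2$significant[1])
  expect_gt(res2$t[1], 0)
})

test_that("neuro-behavioral correlations: identity, attenuation, calibration", {
  set.seed(48)
  P <- 10; C <- 8
  perf <- matrix(rnorm(P * C), P, C)
  r1 <- neurobehav_correlation(perf, list(roi = perf), n_perm = 200, seed = 1)
  expect_equal(r1$mean_r, 1, tolerance = 1e-6)
  expect_true(r1$significant)
  expect_error(neurobehav_correlation(matrix(1, P, C), list(roi = perf)),
               "constant performance")
  # attenuation by independent noise matches 1/sqrt(1 + sigma^2)
  set.seed(49)
  P2 <- 400; C2 <- 16
  perf2 <- matrix(rnorm(P2 * C2), P2, C2)
  neural <- perf2 + matrix(rnorm(P2 * C2, sd = 1), P2, C2)
  r2 <- neurobehav_correlation(perf2, list(roi = neural), n_perm = 30, seed = 2)
  expect_equal(r2$mean_r, 1 / sqrt(2), tolerance = 0.05)
  # independent neural tables are rarely significant
  set.seed(50)
  rej <- replicate(40, {
    nb <- neurobehav_correlation(matrix(rnorm(6 * C), 6, C),
                                 list(a = matrix(rnorm(6 * C), 6, C),
                                      b = matrix(rnorm(6 * C), 6, C)),
                                 n_perm = 150, seed = sample.int(1e6, 1))
    any(nb$significant)
  })
  expect_lte(mean(rej), 0.15)
  # lag-resolved input averages Fisher-Z across lags
  arr <- array(rep(perf, 2), dim = c(P, C, 2))
  r3 <- neurobehav_correlation(perf, list(roi = arr), n_perm = 50, seed = 3)
  expect_equal(r3$mean_r, 1, tolerance = 1e-6)
})

test_that("repeated-measures ANOVA matches the aov error-strata oracle", {
  set.seed(51)
  des <- condition_design(n_participants = 10)
  beh <- gen_behavior(des, default_synth_truth(des, rng_seed = 5))
  an <- rm_anova_behavior(beh)
  df <- beh
  df$snr <- factor(df$snr_db); df$vis <- factor(df$visual)
  df$pp <- factor(df$participant)
  a <- summary(aov(accuracy ~ snr * vis + Error(pp / (snr * vis)), data = df))
  f_oracle <- c(a[["Error: pp:snr"]][[1]]$`F value`[1],
                a[["Error: pp:vis"]][[1]]$`F value`[1],
                a[["Error: pp:snr:vis"]][[1]]$`F value`[1])
  expect_equal(an$F, f_oracle, tolerance = 1e-8)
  # two-level factor: F equals the squared paired t
  vi <- with(beh, tapply(accuracy, list(participant, visual), mean))
  tstat <- t.test(vi[, "VI"], vi[, "VN"], paired = TRUE)$statistic
  expect_equal(an$F[an$effect == "VIVN"], unname(tstat^2), tolerance = 1e-8)
  # identical accuracies: all F = 0
  beh0 <- beh; beh0$accuracy <- 0.7
  an0 <- rm_anova_behavior(beh0)
  expect_true(all(an0$F == 0 | is.nan(an0$F)))
})

test_that("Huynh-Feldt epsilon matches the multivariate-model oracle", {
  skip_if_not_installed("car")
  set.seed(52)
  des <- condition_design(n_participants = 12)
  beh <- gen_behavior(des, default_synth_truth(des, rng_seed = 6))
  an <- rm_anova_behavior(beh)
  Y <- matrix(beh$accuracy[order(beh$participant, beh$snr_db, beh$visual)],
              12, 8, byrow = TRUE)
  id <- expand.grid(vis = factor(c("VI", "VN")), snr = factor(c(2, 4, 6, 8)))
  # car warns when its HF epsilon exceeds 1 before capping, as here
  s <- suppressWarnings(
    summary(car::Anova(lm(Y ~ 1), idata = id, idesign = ~ snr * vis, type = 3),
            multivariate = FALSE))
  eps_car <- s$pval.adjustments[, "HF eps"]
  expect_equal(an$eps_hf[an$effect == "SNR"], min(unname(eps_car["snr"]), 1),
               tolerance = 1e-6)
  expect_equal(an$eps_hf[an$effect == "SNRxVIVN"],
               min(unname(eps_car["snr:vis"]), 1), tolerance = 1e-6)
})

test_that("amplitude GLM detects a visual-context amplitude change", {
  des <- tiny_design(n_participants = 5, n_segments = 2, duration_s = 8)
  cond <- conditions(des)
  gains <- rbind(NodeA = ifelse(cond$visual == "VI", 2.5, 0.8))
  colnames(gains) <- cond$condition
  tr <- synth_truth(node_gain = gains, node_lag_ms = c(NodeA = 60), rng_seed = 7)
  ds <- gen_dataset(des, tr)
  res <- amplitude_condition_glm(ds, band_bank()[2, ], effect = "VIVN",
                                 spec = cluster_spec(n_perm = 300), seed = 2)
  expect_true(any(res$significant_mask))
  expect_gt(res$beta_map[which.max(abs(res$t_map))], 0)
})
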