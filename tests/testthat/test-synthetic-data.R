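# Synthetic envelope/lip/dataset/behavior generators.

test_that("condition design enumerates the full factorial", {
  d <- condition_design()
  cond <- conditions(d)
  expect_equal(nrow(cond), 8)
  expect_equal(length(unique(cond$condition)), 8)
  expect_setequal(unique(cond$snr_db), c(2, 4, 6, 8))
  expect_setequal(unique(cond$visual_code), c(-1, 1))
  d2 <- condition_design(snr_levels = c(0, 5))
  expect_equal(nrow(conditions(d2)), 4)
})

test_that("synthetic envelope is low-frequency dominated and seeded", {
  e <- gen_envelope(10, fs_test, seed = 1)
  expect_equal(length(e$values), 1500)
  expect_true(all(e$values >= 0))
  e2 <- gen_envelope(60, fs_test, seed = 5)
  v <- e2$values - mean(e2$values)
  sp <- Mod(fft(v))^2
  nf <- floor(length(v) / 2)
  freqs <- (1:nf) * fs_test / length(v)
  frac <- sum(sp[2:(nf + 1)][freqs < 8]) / sum(sp[2:(nf + 1)])
  expect_gte(frac, 0.8)
  expect_identical(gen_envelope(5, fs_test, seed = 3)$values,
                   gen_envelope(5, fs_test, seed = 3)$values)
  expect_error(gen_envelope(-1, fs_test, seed = 1), "duration")
  expect_error(gen_envelope(10, 0, seed = 1), "rate")
})

test_that("lip coherence scales with the requested level", {
  env <- gen_envelope(60, fs_test, seed = 2)
  levels <- c(0, 0.4, 1)
  coh <- vapply(levels, function(cl) {
    lip <- gen_lip(env, cl, lag_ms = 0, seed = 4)
    co <- spectral_coherence(env, lip)
    mean(co$coherence[co$freq_hz >= 1 & co$freq_hz <= 8])
  }, numeric(1))
  expect_true(all(diff(coh) > 0))
  expect_gt(coh[3], 0.9)
  co0 <- spectral_coherence(env, gen_lip(env, 0, seed = 4))
  expect_lt(coh[1], coherence_chance_level(attr(co0, "n_segments")))
  expect_identical(gen_lip(env, 0.5, 20, seed = 9)$values,
                   gen_lip(env, 0.5, 20, seed = 9)$values)
  expect_error(gen_lip(env, 1.5, 0, 1), "coherence_level")
})

test_that("dataset generation respects structure, determinism and truth", {
  des <- tiny_design(n_participants = 2, n_segments = 2, duration_s = 8)
  tr <- two_node_truth(des, rng_seed = 3)
  ds <- gen_dataset(des, tr)
  expect_equal(length(ds$data), 2)
  expect_equal(nrow(ds$conditions), 8)
  expect_setequal(ds$nodes, c("NodeA", "NodeB"))
  seg <- ds$data[[1]][[1]]$segments[[1]]
  expect_equal(dim(seg$nodes), c(8 * fs_test, 2))
  expect_equal(length(seg$envelope), 8 * fs_test)
  # determinism
  ds2 <- gen_dataset(des, tr)
  expect_identical(ds$data[[2]][[5]]$segments[[2]]$nodes,
                   ds2$data[[2]][[5]]$segments[[2]]$nodes)
  # unknown edge node is a configuration error
  expect_error(
    synth_truth(node_gain = c(A = 1), node_lag_ms = c(A = 20),
                edge_coupling = list(list(seed = "A", target = "Z",
                                          gain = 1, lag_ms = 20,
                                          speech_mediated = TRUE))),
    "unknown node")
  # non-representable lag
  expect_error(gen_dataset(des, synth_truth(node_gain = c(A = 1),
                                            node_lag_ms = c(A = 3.3))),
               "whole number")
})

test_that("gain-0 node carries no envelope information", {
  des <- tiny_design(n_participants = 1, n_segments = 6, duration_s = 10)
  gains <- rbind(Silent = rep(0, 8), Driven = rep(1.5, 8))
  colnames(gains) <- conditions(des)$condition
  tr <- synth_truth(node_gain = gains,
                    node_lag_ms = c(Silent = 60, Driven = 60), rng_seed = 6)
  ds <- gen_dataset(des, tr)
  segs <- ds$data[[1]][[1]]$segments
  band <- c(1, 4)
  env <- lapply(segs, function(s) bandpass(s$envelope, band, rate_hz = fs_test)$values)
  pm <- segment_permutations(6, 60, seed = 2)
  for (node in c("Silent", "Driven")) {
    neu <- lapply(segs, function(s) bandpass(s$nodes[, node], band, rate_hz = fs_test)$values)
    mi <- bias_corrected_mi(neu, env, 9, pm)
    if (node == "Silent") expect_lt(abs(mi), 0.05) else expect_gt(mi, 0.2)
  }
})

test_that("behavioral accuracies rise with SNR and carry the VI bonus", {
  des <- condition_design(n_participants = 200, segment_duration_s = 1)
  tr <- default_synth_truth(des, rng_seed = 8)
  beh <- gen_behavior(des, tr)
  expect_true(all(beh$accuracy >= 0 & beh$accuracy <= 1))
  m <- aggregate(accuracy ~ snr_db, data = beh, FUN = mean)
  expect_true(all(diff(m$accuracy[order(m$snr_db)]) > 0))
  # VI - VN difference per SNR approximates the configured bonus
  vi <- aggregate(accuracy ~ snr_db, data = beh[beh$visual == "VI", ], mean)
  vn <- aggregate(accuracy ~ snr_db, data = beh[beh$visual == "VN", ], mean)
  expect_lt(max(abs(vi$accuracy - vn$accuracy - tr$behavior_params$vi_bonus)),
            0.02)
  # degenerate parameters give identical accuracies
  tr0 <- tr
  tr0$behavior_params <- list(intercept = 0.2, snr_slope = 0, vi_bonus = rep(0, 4),
                              noise_sd = 0)
  beh0 <- gen_behavior(des, tr0)
  expect_equal(length(unique(round(beh0$accuracy, 12))), 1)
})
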