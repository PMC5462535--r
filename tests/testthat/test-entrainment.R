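# Optimal-lag estimation and permutation bias correction.

test_that("segment permutation sets are exhaustive or seeded subsets", {
  pm <- segment_permutations(3)
  expect_equal(nrow(pm), 6)
  expect_equal(nrow(unique(pm)), 6)
  expect_equal(pm[1, ], 1:3)
  sub <- segment_permutations(6, 50, seed = 2)
  expect_equal(nrow(sub), 50)
  expect_equal(sub[1, ], 1:6)
  expect_identical(segment_permutations(6, 50, seed = 2), sub)
  expect_true(all(apply(sub, 1, function(p) setequal(p, 1:6))))
})

test_that("quadratic vertex rule recovers exact and clipped lags", {
  spec <- lag_search_spec(0:37)
  # exact parabola peaking at 12
  lags <- 0:37
  mi <- 1 - 0.002 * (lags - 12)^2
  expect_equal(estimate_optimal_lag(mi, rep(TRUE, 38), spec), 12L)
  # monotone increase clips at the upper bound
  expect_equal(estimate_optimal_lag(0.01 * lags, rep(TRUE, 38), spec), 37L)
  # fewer than 3 significant lags -> no estimate
  expect_true(is.na(estimate_optimal_lag(mi, c(TRUE, TRUE, rep(FALSE, 36)), spec)))
  # vertex beyond the range clips
  mi2 <- 1 - 0.002 * (lags - 90)^2
  expect_equal(estimate_optimal_lag(mi2, rep(TRUE, 38), spec), 37L)
})

test_that("noisy parabola vertex is recovered within one sample", {
  spec <- lag_search_spec(0:30)
  lags <- 0:30
  truth <- 1 - 0.003 * (lags - 14)^2
  set.seed(21)
  hits <- sum(replicate(100, {
    est <- estimate_optimal_lag(truth + rnorm(31, sd = 0.05 * max(truth)),
                                rep(TRUE, 31), spec)
    abs(est - 14) <= 1
  }))
  expect_gte(hits, 95)
})

test_that("bias-corrected MI is zero for identity, null-centered, small for signal", {
  set.seed(31)
  cell <- lagged_cell(gain = 2, lag = 9, seed0 = 3)
  # identity-only permutation set gives exactly zero
  expect_equal(bias_corrected_mi(cell$neural, cell$env, 9,
                                 matrix(1:6, nrow = 1)), 0)
  expect_error(bias_corrected_mi(cell$neural, cell$env, 9,
                                 matrix(integer(0), 0, 6)), "empty")
  # strong coupling: bias is a small fraction of the raw MI
  pm <- segment_permutations(6, 120, seed = 4)
  rn <- avspeechinfo:::mi_raw_and_null(cell$neural, lapply(cell$env, as.matrix), 9, pm)
  corrected <- rn$raw - median(rn$fam)
  expect_gt(corrected, 0.9 * rn$raw)
  # independence: by segment exchangeability the expected corrected MI
  # equals the mean-median gap of the permutation family (positive for
  # the right-skewed MI null); the observed mean must match that
  # derived reference within 2 SEM, and stay small on the bits scale
  set.seed(32)
  runs <- replicate(20, {
    c2 <- lagged_cell(gain = 0, lag = 0, nseg = 4, n = 1200,
                      seed0 = sample.int(1e5, 1))
    rn <- avspeechinfo:::mi_raw_and_null(c2$neural,
                                         lapply(c2$env, as.matrix), 5,
                                         segment_permutations(4))
    c(corrected = rn$raw - median(rn$fam),
      gap = mean(rn$fam) - median(rn$fam))
  })
  expect_lt(abs(mean(runs["corrected", ]) - mean(runs["gap", ])),
            2 * sd(runs["corrected", ]) / sqrt(20))
  expect_lt(abs(mean(runs["corrected", ])), 0.01)
})

test_that("population MI increases when coupling gain doubles", {
  set.seed(33)
  mi_at_gain <- function(g) {
    mean(replicate(5, {
      cell <- lagged_cell(gain = g, lag = 9, nseg = 4, n = 1500,
                          seed0 = sample.int(1e5, 1))
      bias_corrected_mi(cell$neural, cell$env, 9, segment_permutations(4))
    }))
  }
  expect_gt(mi_at_gain(1.6), mi_at_gain(0.8))
})

test_that("estimated lags match the generating lags at high gain", {
  des <- tiny_design(n_participants = 3, n_segments = 6, duration_s = 12)
  tr <- two_node_truth(des, rng_seed = 11, base_gain = 1.4, slope = 0.2)
  ds <- gen_dataset(des, tr)
  lags <- estimate_lags(ds, band_bank()[2, ], lag_search_spec(0:25, n_null = 120),
                        seed = 5)
  expect_equal(lags$lag_samples[lags$node == "NodeA"], 9, tolerance = 1)
  expect_equal(lags$lag_samples[lags$node == "NodeB"], 15, tolerance = 1)
})

test_that("condition info table has full coverage and correct algebra", {
  des <- tiny_design(n_participants = 2, n_segments = 4, duration_s = 10)
  tr <- two_node_truth(des, rng_seed = 12)
  ds <- gen_dataset(des, tr)
  bands <- band_bank()[2, ]
  lags <- data.frame(node = c("NodeA", "NodeB"), band = bands$band,
                     lag_samples = c(9L, 15L))
  ent <- condition_info_table(ds, bands, lags, n_perm = 24, seed = 6)
  expect_setequal(unique(ent$measure), c("mi_speech", "cmi", "mi_lip", "red"))
  # mi_speech and cmi in all conditions, lip measures in VI only
  ms <- ent[ent$measure == "mi_speech", ]
  expect_equal(nrow(ms), 2 * 2 * 8)
  expect_true(all(ent$visual[ent$measure == "mi_lip"] == "VI"))
  expect_true(all(ent$visual[ent$measure == "red"] == "VI"))
  # determinism
  ent2 <- condition_info_table(ds, bands, lags, n_perm = 24, seed = 6)
  expect_identical(ent$value, ent2$value)
})

test_that("envelope-driven node yields cmi close to mi_speech under lip independence", {
  des <- tiny_design(n_participants = 2, n_segments = 6, duration_s = 12)
  cond <- conditions(des)
  gains <- rbind(NodeA = rep(1.5, 8))
  colnames(gains) <- cond$condition
  # lip fully independent of the envelope
  tr <- synth_truth(node_gain = gains, node_lag_ms = c(NodeA = 60),
                    lip_coherence = 0, rng_seed = 13)
  ds <- gen_dataset(des, tr)
  bands <- band_bank()[2, ]
  lags <- data.frame(node = "NodeA", band = bands$band, lag_samples = 9L)
  ent <- condition_info_table(ds, bands, lags, n_perm = 60, seed = 7)
  agg <- aggregate(value ~ measure, data = ent, FUN = mean)
  mi_s <- agg$value[agg$measure == "mi_speech"]
  mi_l <- agg$value[agg$measure == "mi_lip"]
  cmi <- agg$value[agg$measure == "cmi"]
  expect_gt(mi_s, 5 * max(mi_l, 0.001))
  expect_equal(cmi, mi_s, tolerance = 0.1 * mi_s)
})
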