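# Configuration-driven orchestration of the analysis stages, with
# seeding, manifests and CSV/JSON result bundling.

#' Build a run configuration
#'
#' @param design A [condition_design()].
#' @param truth A [synth_truth()] (default [default_synth_truth()]).
#' @param bands Band data.frame rows used for entrainment (default the
#'   two lowest bands, where envelope power concentrates).
#' @param lag_spec A [lag_search_spec()].
#' @param di_pairs Optional data.frame `seed`, `target` for the directed
#'   connectivity stage (`NULL` skips the stage).
#' @param di_grid A [lag_grid()] for the DI stage.
#' @param n_perm_bias Segment permutations for bias correction.
#' @param n_perm_stats Permutations for group statistics.
#' @param n_shuffles_di Shuffles for DI Z-scoring.
#' @param cluster A [cluster_spec()] template (adjacency set per stage).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory (`NULL` disables file output).
#' @return A `run_config` list.
#' @export
run_config <- function(design = condition_design(),
                       truth = default_synth_truth(design),
                       bands = band_bank()[1:2, ],
                       lag_spec = lag_search_spec(),
                       di_pairs = NULL,
                       di_grid = lag_grid(rate_hz = design$sample_rate_hz),
                       n_perm_bias = 120L,
                       n_perm_stats = 1000L,
                       n_shuffles_di = 20L,
                       cluster = cluster_spec(n_perm = 1000L),
                       seed = 1L,
                       out_dir = NULL) {
  structure(list(design = design, truth = truth, bands = bands,
                 lag_spec = lag_spec, di_pairs = di_pairs, di_grid = di_grid,
                 n_perm_bias = n_perm_bias, n_perm_stats = n_perm_stats,
                 n_shuffles_di = n_shuffles_di, cluster = cluster,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: simulate (dataset + behavior), entrain (optimal lags and the
#' condition information table), stats (condition GLMs on speech MI per
#' node/band and the behavioral ANOVA), and optionally connect (Z-scored
#' DI tables for the configured pairs). Each stage is deterministic
#' given the config seed; results are returned as a bundle and, when
#' `out_dir` is set, written as CSV tables with a JSON manifest
#' recording the configuration hash and seeds.
#'
#' @param config A [run_config()].
#' @return A list with `dataset`, `behavior`, `lags`, `entrainment`,
#'   `glm` (per effect), `behavior_anova`, and `di` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_invalid("configuration error: config must be a run_config")
  dataset <- gen_dataset(config$design, config$truth)
  behavior <- gen_behavior(config$design, config$truth)
  lags <- estimate_lags(dataset, config$bands, config$lag_spec,
                        seed = child_seed(config$seed, 1L))
  ent <- condition_info_table(dataset, config$bands, lags,
                              n_perm = config$n_perm_bias,
                              seed = child_seed(config$seed, 2L))
  glm_res <- pipeline_glm(ent, dataset$conditions, config)
  anova_res <- rm_anova_behavior(behavior)
  di_res <- NULL
  if (!is.null(config$di_pairs)) {
    di_res <- di_table(dataset, config$di_pairs, config$di_grid,
                       n_shuffles = config$n_shuffles_di,
                       seed = child_seed(config$seed, 3L))
  }
  bundle <- list(dataset = dataset, behavior = behavior, lags = lags,
                 entrainment = ent, glm = glm_res, behavior_anova = anova_res,
                 di = di_res)
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

# GLM on the mi_speech measure, indices = node x band, FWE across them.
pipeline_glm <- function(ent, cond, config) {
  mi <- ent[ent$measure == "mi_speech", , drop = FALSE]
  keys <- unique(mi[, c("node", "band")])
  P <- max(mi$participant); C <- nrow(cond)
  vals <- array(NA_real_, dim = c(P, C, nrow(keys)))
  for (k in seq_len(nrow(keys))) {
    sub <- mi[mi$node == keys$node[k] & mi$band == keys$band[k], , drop = FALSE]
    vals[, , k] <- matrix(sub$value[order(sub$participant,
                                          match(sub$condition, cond$condition))],
                          P, C, byrow = TRUE)
  }
  spec <- config$cluster
  spec$n_perm <- config$n_perm_stats
  out <- lapply(c("SNR", "VIVN", "SNRxVIVN"), function(eff) {
    res <- freedman_lane_glm(vals, cond, eff, spec,
                             seed = child_seed(config$seed, 4L, match(eff, c("SNR", "VIVN", "SNRxVIVN"))))
    res$index_labels <- paste(keys$node, keys$band, sep = "|")
    res
  })
  names(out) <- c("SNR", "VIVN", "SNRxVIVN")
  out
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$behavior, file.path(config$out_dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$entrainment, file.path(config$out_dir, "entrainment.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$lags, file.path(config$out_dir, "optimal_lags.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$behavior_anova, file.path(config$out_dir, "behavior_anova.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$di)) {
    utils::write.csv(bundle$di, file.path(config$out_dir, "di.csv"), row.names = FALSE)
  }
  glm_summary <- do.call(rbind, lapply(names(bundle$glm), function(eff) {
    r <- bundle$glm[[eff]]
    data.frame(effect = eff, index = r$index_labels, t = r$t_map,
               beta = r$beta_map, beta_sem = r$beta_sem,
               significant = r$significant_mask, fwe_threshold = r$fwe_threshold,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(glm_summary, file.path(config$out_dir, "glm_effects.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "avspeechinfo",
    seed = config$seed,
    config_hash = config_hash(config),
    n_participants = config$design$n_participants,
    n_conditions = nrow(conditions(config$design)),
    n_perm_bias = config$n_perm_bias,
    n_perm_stats = config$n_perm_stats,
    bands = config$bands$band,
    files = list.files(config$out_dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Stable hash of the configuration (numbers and labels only).
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 10)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% .Machine$integer.max)
}

#' Import deposited-style numeric tables
#'
#' Reads per-variable CSV re-exports of a deposited archive into the
#' package's table schemas, with dimension checks.
#'
#' @param path CSV file path.
#' @param variable One of `"behavior"` (participants x conditions
#'   accuracy), `"entrainment"` (tidy long table), `"di"` (tidy long
#'   table).
#' @param n_participants,n_conditions Expected dimensions for the
#'   behavior matrix (defaults 19 and 8).
#' @return A data.frame in the corresponding schema.
#' @export
import_deposited <- function(path, variable = c("behavior", "entrainment", "di"),
                             n_participants = 19L, n_conditions = 8L) {
  variable <- match.arg(variable)
  if (!file.exists(path)) stop_invalid("import error: file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_invalid("import error: unparseable file %s", path))
  if (variable == "behavior") {
    num <- df[vapply(df, is.numeric, logical(1))]
    if (nrow(num) != n_participants || ncol(num) != n_conditions) {
      stop_invalid("import error: expected %d x %d accuracy table, found %d x %d",
                   n_participants, n_conditions, nrow(num), ncol(num))
    }
    return(as.matrix(num))
  }
  required <- if (variable == "entrainment") {
    c("participant", "node", "band", "condition", "measure", "value")
  } else {
    c("participant", "seed", "target", "tau_brain_ms", "tau_speech_ms",
      "condition", "di_bits", "z")
  }
  if (!all(required %in% names(df))) {
    stop_invalid("import error: missing columns %s",
                 paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}
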