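#!/usr/bin/env Rscript
# Stage 4 — group-level condition effects and behavioral statistics.
#
# Reads the stage-2 entrainment table, fits the Freedman-Lane
# permutation GLM (SNR, visual context and their interaction) on the
# bias-corrected speech MI per node, runs the behavioral
# repeated-measures ANOVA, and the neuro-behavioral correlation between
# condition-specific accuracy and speech MI.

library(avspeechinfo)

seed <- 20260922L
ent <- read.csv("results/entrainment.csv", stringsAsFactors = FALSE)
behavior <- read.csv("results/behavior.csv", stringsAsFactors = FALSE)
design <- condition_design(n_participants = 6, n_segments_per_condition = 6,
                           segment_duration_s = 12)
cond <- conditions(design)

mi <- ent[ent$measure == "mi_speech", ]
nodes <- unique(mi$node)
P <- max(mi$participant)
vals <- array(NA_real_, dim = c(P, nrow(cond), length(nodes)))
for (k in seq_along(nodes)) {
  sub <- mi[mi$node == nodes[k], ]
  sub <- sub[order(sub$participant, match(sub$condition, cond$condition)), ]
  vals[, , k] <- matrix(sub$value, P, nrow(cond), byrow = TRUE)
}

glm_rows <- lapply(c("SNR", "VIVN", "SNRxVIVN"), function(eff) {
  r <- freedman_lane_glm(vals, cond, eff, cluster_spec(n_perm = 1000),
                         seed = seed + match(eff, c("SNR", "VIVN", "SNRxVIVN")))
  data.frame(effect = eff, node = nodes, t = r$t_map, beta = r$beta_map,
             beta_sem = r$beta_sem, significant = r$significant_mask)
})
glm_tab <- do.call(rbind, glm_rows)
write.csv(glm_tab, "results/glm_effects.csv", row.names = FALSE)
cat("Condition effects on speech MI (standardized betas):\n")
print(glm_tab, digits = 3)

anova_tab <- rm_anova_behavior(behavior)
write.csv(anova_tab, "results/behavior_anova.csv", row.names = FALSE)
cat("\nBehavioral repeated-measures ANOVA:\n")
print(anova_tab, digits = 4)

# neuro-behavioral correlation: performance vs speech MI per node
perf <- matrix(NA_real_, P, nrow(cond))
for (i in seq_len(nrow(behavior))) {
  perf[behavior$participant[i], match(behavior$condition[i], cond$condition)] <-
    behavior$accuracy[i]
}
neural <- setNames(lapply(seq_along(nodes), function(k) vals[, , k]), nodes)
nb <- neurobehav_correlation(perf, neural, n_perm = 1000, seed = seed + 7L)
write.csv(nb, "results/neurobehavior.csv", row.names = FALSE)
cat("\nNeuro-behavioral correlations (participant-average r):\n")
print(nb, digits = 3)
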