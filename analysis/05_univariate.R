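#!/usr/bin/env Rscript
# Univariate screening of the MRMR-selected features on the full cohort:
# Shapiro-Wilk-guided choice between Welch's t-test and the Mann-Whitney U
# test per feature, with pass flags at the raw 0.05 level and at the
# Bonferroni-adjusted threshold 0.05 / 50 = 0.001.

library(qusrad)

feat <- utils::read.csv("results/features.csv", check.names = FALSE)
X <- as.matrix(feat[, -(1:3)])
y <- feat$label

std <- standardize_fit_apply(X)
sel <- mrmr_select(std$dev, y, k = 50)
message(sprintf("screening the %d MRMR-selected features", length(sel)))

screen <- screen_features(X[, sel, drop = FALSE], y,
                          stats_config(alpha = 0.05, n_tests = 50))
utils::write.csv(screen, "results/univariate_screen.csv", row.names = FALSE)

n_raw <- sum(screen$raw_pass)
n_adj <- sum(screen$bonferroni_pass)
message(sprintf("  %d features pass p < 0.05; %d pass the adjusted 0.001",
                n_raw, n_adj))
print(utils::head(screen[, c("feature", "test", "p_value",
                             "bonferroni_pass")], 8), row.names = FALSE)
message("wrote results/univariate_screen.csv")
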