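#!/usr/bin/env Rscript
# Training-test comparison: a held-out test set of 40 is drawn, all methods
# sample their training sets from the remaining 150, and every cell predicts
# the identical test individuals (CDmean with targeted contrasts).
# Desk-scale replication: 10 test sets x 5 sampling reps.

library(tetrasel)

st <- readRDS("results/state_01.rds")
panel <- st$panel

tt <- run_tt_scheme(panel, st$traits$length,
                    methods = c("SRS", "STRAT", "GD", "CDMEAN"),
                    models = c("GBLUP", "BAYESC"),
                    test_size = 40, train_sizes = c(25, 50, 75, 100),
                    n_test_sets = 10, n_sampling_reps = 5,
                    seed = st$seed + 1,
                    mcmc = c(n_iter = 1000, burn_in = 500),
                    cdmean_control = list(max_stall = 300, n_starts = 1))
write.csv(tt, "results/tt_records.csv", row.names = FALSE)

means <- aggregate(accuracy ~ method + train_size, data = tt, FUN = mean)
wide <- reshape(means, idvar = "train_size", timevar = "method",
                direction = "wide")
print(wide, digits = 3)

tab <- anova_accuracy(tt)
write.csv(tab, "results/tt_anova.csv", row.names = FALSE)
print(tab, digits = 3)
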