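#!/usr/bin/env Rscript
# Marginal comparison of the three whole-genome regression models per trait
# on common 150/40 training-test splits: GBLUP (additive kernel), RKHS
# (Gaussian kernel with tuned bandwidth), BayesC-pi (marker selection).

library(tetrasel)

st <- readRDS("results/state_01.rds")
panel <- st$panel
ids <- rownames(panel$dosages)
A <- vanraden_A(panel)

rows <- list()
for (k in 1:10) {
  set.seed(st$seed + 40 + k)
  test <- sample(ids, 40)
  train <- sample(setdiff(ids, test), 150)
  for (trn in names(st$traits)) {
    y <- st$traits[[trn]]$values
    obs <- y[test]
    rows[[length(rows) + 1]] <- data.frame(
      rep = k, trait = trn,
      GBLUP = accuracy(gblup_fit_predict(A, y[train], test), obs),
      RKHS = accuracy(rkhs_fit_predict(panel, y[train], test), obs),
      BAYESC = accuracy(bayesc_fit_predict(panel, y[train], test,
                                           n_iter = 1000, burn_in = 500,
                                           seed = st$seed + 900 + k), obs))
  }
}
res <- do.call(rbind, rows)
write.csv(res, "results/model_comparison.csv", row.names = FALSE)
marg <- aggregate(cbind(GBLUP, RKHS, BAYESC) ~ trait, data = res, FUN = mean)
print(marg, digits = 3)
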