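#!/usr/bin/env Rscript
# Compare the four dosage-aware genetic distance/similarity measures on the
# panel: pairwise Mantel correlations (with permutation p-values) and the
# similarity matrices used by the genetic-distance sampler.

library(tetrasel)

st <- readRDS("results/state_01.rds")
panel <- st$panel

mats <- list(euclidean = euclidean_distance(panel),
             nei = nei_distance(panel),
             jaccard = jaccard_similarity(panel),
             kosman = kosman_leonard_similarity(panel))

pairs <- combn(names(mats), 2, simplify = FALSE)
tab <- do.call(rbind, lapply(pairs, function(pr) {
  m <- mantel_correlation(mats[[pr[1]]], mats[[pr[2]]], n_perm = 999,
                          seed = st$seed)
  data.frame(a = pr[1], b = pr[2], mantel_r = m$r, p = m$p)
}))
write.csv(tab, "results/mantel_correlations.csv", row.names = FALSE)
print(tab, digits = 3)

S <- to_similarity(mats$euclidean)
write.table(S$values, "results/similarity_euclidean.tsv", sep = "\t",
            quote = FALSE)
cat(sprintf("minimum Mantel r: %.3f (pair %s-%s)\n",
            min(tab$mantel_r), tab$a[which.min(tab$mantel_r)],
            tab$b[which.min(tab$mantel_r)]))
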