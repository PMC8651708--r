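#!/usr/bin/env Rscript
# Build the synthetic tetraploid diversity panel the whole analysis runs on:
# 190 individuals in 3 weakly separated groups, 3,262 dosage SNPs, and three
# traits spanning high to intermediate heritability (a tuber-length-like
# polygenic trait and two sugar-content-like sparse traits). Applies marker
# QC and writes everything under results/.

library(tetrasel)

dir.create("results", showWarnings = FALSE)
seed <- 2026

panel <- simulate_panel(sim_config(), seed = seed)
qc <- qc_filter(panel)
panel <- qc$panel
print(qc$report)

traits <- list(
  length = simulate_trait(panel, n_qtl = 50, h2 = 0.91,
                          trait_name = "length", seed = seed + 1),
  fructose = simulate_trait(panel, n_qtl = 10, h2 = 0.85,
                            trait_name = "fructose", seed = seed + 2),
  sucrose = simulate_trait(panel, n_qtl = 10, h2 = 0.67,
                           trait_name = "sucrose", seed = seed + 3))

write_dosage_panel(panel, "results/panel.tsv")
write.csv(data.frame(id = names(traits$length$values),
                     length = unname(traits$length$values),
                     fructose = unname(traits$fructose$values),
                     sucrose = unname(traits$sucrose$values)),
          "results/phenotypes.csv", row.names = FALSE)
write.csv(data.frame(id = rownames(panel$dosages),
                     stratum = unname(panel$strata)),
          "results/strata.csv", row.names = FALSE)
saveRDS(list(panel = panel, traits = traits, seed = seed),
        "results/state_01.rds")

cat(sprintf("panel: %d x %d after QC; realized h2: %s\n",
            nrow(panel$dosages), ncol(panel$dosages),
            paste(sprintf("%s=%.3f", names(traits),
                          sapply(traits, realized_h2)), collapse = ", ")))
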