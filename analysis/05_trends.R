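#!/usr/bin/env Rscript
# Step 5 — estimated breeding values and genetic trends.
#
# Two parts: (a) EBVs and yearly mean-EBV trends for AGE on the unselected
# study herd under both models (trends should be flat apart from drift);
# (b) a herd bred under downward truncation selection on AGE phenotype,
# where the mean EBV by birth year should decline steadily, the pattern a
# breeding program aims for in days-to-market-weight.

suppressPackageStartupMessages(library(pedblup))
factors <- c("farm", "year_season", "sex")

ped <- read_pedigree("results/herd_pedigree.csv")
pheno <- read_phenotypes("results/herd_phenotypes_filtered.csv",
                         list(traits = c("AGE"), factors = factors))
ainv <- build_a_inverse(ped)

f1 <- fit_animal_model(pheno, ped, "AGE", factors, include_litter = FALSE,
                       ainv = ainv)
f2 <- fit_animal_model(pheno, ped, "AGE", factors, include_litter = TRUE,
                       ainv = ainv)
ebv <- rbind(extract_ebv(f1, ped, "model1"), extract_ebv(f2, ped, "model2"))
utils::write.table(format(ebv, digits = 5), "results/ebv_age_unselected.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
tr0 <- genetic_trend(ebv)
cat("Unselected herd, yearly mean EBV (AGE):\n")
print(tr0, digits = 3)

# selected herd
sel <- sim_config(n_founders = 200L, n_generations = 6L, n_dams_per_gen = 20L,
                  litter_size = 10, traits = duroc_trait_specs()["AGE"],
                  selection = "phenotype", selection_trait = "AGE",
                  selection_proportion = 0.2, selection_direction = "low",
                  seed = 20231219L)
sim <- simulate_herd(sel)
fs1 <- fit_animal_model(sim$pheno, sim$ped, "AGE", factors,
                        include_litter = FALSE)
fs2 <- fit_animal_model(sim$pheno, sim$ped, "AGE", factors,
                        include_litter = TRUE)
ebv_sel <- rbind(extract_ebv(fs1, sim$ped, "model1"),
                 extract_ebv(fs2, sim$ped, "model2"))
trend <- genetic_trend(ebv_sel)
utils::write.table(format(trend, digits = 5), "results/ebv_trends_selected.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nSelected herd, yearly mean EBV (AGE):\n")
print(trend, digits = 3)

# two-model overlay of the selection trend
pdf("results/fig_trend_age.pdf", width = 6, height = 4)
t1 <- trend[trend$model == "model1", ]
t2 <- trend[trend$model == "model2", ]
plot(t1$birth_year, t1$mean_ebv, type = "b", pch = 19, col = "firebrick",
     xlab = "birth year", ylab = "mean EBV (days)",
     main = "Genetic trend for AGE under truncation selection",
     ylim = range(c(t1$mean_ebv, t2$mean_ebv)))
lines(t2$birth_year, t2$mean_ebv, type = "b", pch = 17, col = "steelblue")
legend("bottomleft", c("model 1 (animal)", "model 2 (+litter)"),
       col = c("firebrick", "steelblue"), pch = c(19, 17), bty = "n")
dev.off()
cat("\nWrote results/ebv_trends_selected.tsv and results/fig_trend_age.pdf\n")
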