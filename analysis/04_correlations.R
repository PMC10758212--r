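#!/usr/bin/env Rscript
# Step 4 — genetic and phenotypic correlations between AGE and the other
# traits, from bivariate litter-model REML fits (AGE is the pivot trait of
# the evaluation: it indexes growth rate and carries the strongest
# correlations with feed conversion and body size).

suppressPackageStartupMessages(library(pedblup))
traits <- c("BW", "AGE", "FCR", "BL", "BH", "FCC")
factors <- c("farm", "year_season", "sex")
partners <- c("FCR", "BL")   # strongest published pairs with AGE

ped <- read_pedigree("results/herd_pedigree.csv")
pheno <- read_phenotypes("results/herd_phenotypes_filtered.csv",
                         list(traits = traits, factors = factors))
ainv <- build_a_inverse(ped)
ref <- duroc_reference()

rows <- list()
d_age <- build_design(pheno, model_spec("AGE", factors, TRUE), ped)
for (tr in partners) {
  d_tr <- build_design(pheno, model_spec(tr, factors, TRUE), ped)
  fit <- reml_fit_bivariate(d_age, d_tr, ainv,
                            model_spec(c("AGE", tr), factors, TRUE))
  g <- genetic_correlation(fit)
  rows[[tr]] <- data.frame(trait1 = "AGE", trait2 = tr,
                           r_g = g$r_g, r_g_se = g$se,
                           r_p = phenotypic_correlation(fit),
                           true_r_g = ref$rg_model2["AGE", tr],
                           true_r_p = ref$rp_model2["AGE", tr],
                           converged = fit$converged)
  cat(sprintf("AGE-%s: r_g = %+.3f (SE %.3f, truth %+.2f) | r_p = %+.3f (truth %+.2f)\n",
              tr, g$r_g, g$se, ref$rg_model2["AGE", tr],
              rows[[tr]]$r_p, ref$rp_model2["AGE", tr]))
}
out <- do.call(rbind, rows)
utils::write.table(format(out, digits = 4), "results/correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
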