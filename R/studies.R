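# Replicated simulation studies: parameter recovery, AIC model selection,
# bivariate genetic-correlation recovery, and selection-trend behavior.
# These are the package's own calibration experiments; the acceptance script
# and the test suite both run them (at sizes stated in the methods vignette).

#' Single-trait parameter-recovery study
#'
#' Simulates replicate herds under the common-environment model at the
#' given trait architecture (default: the published AGE components, true
#' h2 = 0.299, c2 = 0.196), fits both the plain animal model and the litter
#' model by REML, and returns per-replicate estimates.
#'
#' @param n_reps number of replicate herds.
#' @param seed master seed; replicate r uses seed + r.
#' @param trait_spec trait architecture (list with mean/sigma_a2/sigma_c2/
#'   sigma_e2).
#' @param n_founders,n_generations,n_dams_per_gen,litter_size herd shape
#'   (defaults give about 5,000 animals in about 500 litters).
#' @param fixed_factors factors fitted (and simulated).
#' @return data.frame with one row per replicate: `h2`, `c2`, `sigma_a2`,
#'   `sigma_c2`, `sigma_e2`, `aic_model1`, `aic_model2`, `prefer_litter`,
#'   `converged`, plus attributes `true_h2`, `true_c2`.
#' @export
recovery_study <- function(n_reps = 20L, seed = 1L,
                           trait_spec = duroc_trait_specs()[["AGE"]],
                           n_founders = 200L, n_generations = 4L,
                           n_dams_per_gen = 125L, litter_size = 10,
                           fixed_factors = c("farm", "year_season", "sex")) {
  tn <- "T1"
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                      n_dams_per_gen = n_dams_per_gen,
                      litter_size = litter_size,
                      traits = stats::setNames(list(trait_spec), tn),
                      seed = derive_seed(seed, 100L + r))
    sim <- simulate_herd(cfg)
    ainv <- build_a_inverse(sim$ped)
    f2 <- fit_animal_model(sim$pheno, sim$ped, tn, fixed_factors,
                           include_litter = TRUE, ainv = ainv)
    f1 <- fit_animal_model(sim$pheno, sim$ped, tn, fixed_factors,
                           include_litter = FALSE, ainv = ainv)
    cmp <- compare_models(f1, f2)
    data.frame(rep = r,
               h2 = heritability(f2)$h2,
               c2 = litter_ratio(f2)$c2,
               sigma_a2 = f2$components$sigma_a2,
               sigma_c2 = f2$components$sigma_c2,
               sigma_e2 = f2$components$sigma_e2,
               aic_model1 = f1$aic, aic_model2 = f2$aic,
               prefer_litter = cmp$preferred == "model2",
               converged = f1$converged && f2$converged)
  })
  res <- do.call(rbind, out)
  tot <- trait_spec$sigma_a2 + trait_spec$sigma_c2 + trait_spec$sigma_e2
  attr(res, "true_h2") <- trait_spec$sigma_a2 / tot
  attr(res, "true_c2") <- trait_spec$sigma_c2 / tot
  res
}

#' Bivariate genetic-correlation recovery study
#'
#' Simulates replicate two-trait herds at a given true genetic correlation
#' and refits the bivariate litter model. Both traits use the published AGE
#' architecture (h2 = 0.30, c2 = 0.20) so that the genetic correlation is
#' estimated with useful precision at moderate herd sizes.
#'
#' @param r_g true genetic correlation.
#' @param r_c,r_e true litter and residual correlations.
#' @param n_reps replicates.
#' @param seed master seed.
#' @param n_founders,n_generations,n_dams_per_gen,litter_size herd shape
#'   (defaults give about 3,000 animals).
#' @return data.frame per replicate: `r_g`, `r_g_se`, `r_p`, `converged`;
#'   attribute `true_r_g`.
#' @export
bivariate_recovery_study <- function(r_g, r_c = r_g / 2, r_e = r_g / 4,
                                     n_reps = 6L, seed = 1L,
                                     n_founders = 150L, n_generations = 3L,
                                     n_dams_per_gen = 95L, litter_size = 10) {
  spec <- duroc_trait_specs()[["AGE"]]
  traits <- list(T1 = spec, T2 = spec)
  cmat <- function(r) matrix(c(1, r, r, 1), 2)
  facs <- c("farm", "year_season", "sex")
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                      n_dams_per_gen = n_dams_per_gen,
                      litter_size = litter_size, traits = traits,
                      genetic_cor = cmat(r_g), litter_cor = cmat(r_c),
                      residual_cor = cmat(r_e),
                      seed = derive_seed(seed, 200L + r))
    sim <- simulate_herd(cfg)
    ainv <- build_a_inverse(sim$ped)
    ms <- model_spec(c("T1", "T2"), facs, include_litter = TRUE)
    d1 <- build_design(sim$pheno, model_spec("T1", facs, TRUE), sim$ped)
    d2 <- build_design(sim$pheno, model_spec("T2", facs, TRUE), sim$ped)
    fb <- reml_fit_bivariate(d1, d2, ainv, ms)
    g <- genetic_correlation(fb)
    data.frame(rep = r, r_g = g$r_g, r_g_se = g$se,
               r_p = phenotypic_correlation(fb), converged = fb$converged)
  })
  res <- do.call(rbind, out)
  attr(res, "true_r_g") <- r_g
  res
}

#' Selection-trend study
#'
#' Simulates herds under downward truncation selection on the phenotype of
#' an AGE-like trait (top fraction of each cohort retained as parents) over
#' several generations, fits the litter model, and summarizes the genetic
#' trend of mean EBV by birth year; a matching no-selection control
#' quantifies drift.
#'
#' @param n_reps replicates.
#' @param seed master seed.
#' @param selection `"phenotype"` (default) or `"none"` for the control.
#' @param proportion selected fraction.
#' @param n_generations generations of selection.
#' @param n_founders,n_dams_per_gen,litter_size herd shape.
#' @return data.frame per replicate: `monotone` (strictly decreasing yearly
#'   mean EBV), `slope` (OLS slope of mean EBV on birth year), `range`
#'   (last minus first yearly mean).
#' @export
selection_trend_study <- function(n_reps = 10L, seed = 1L,
                                  selection = c("phenotype", "none"),
                                  proportion = 0.2, n_generations = 6L,
                                  n_founders = 200L, n_dams_per_gen = 20L,
                                  litter_size = 10) {
  selection <- match.arg(selection)
  facs <- c("farm", "year_season", "sex")
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                      n_dams_per_gen = n_dams_per_gen,
                      litter_size = litter_size,
                      traits = duroc_trait_specs()["AGE"],
                      selection = selection, selection_trait = "AGE",
                      selection_proportion = proportion,
                      selection_direction = "low",
                      seed = derive_seed(seed, 300L + r))
    sim <- simulate_herd(cfg)
    fit <- fit_animal_model(sim$pheno, sim$ped, "AGE", facs,
                            include_litter = TRUE)
    tr <- genetic_trend(extract_ebv(fit, sim$ped, "model2"))
    mu <- tr$mean_ebv[order(tr$birth_year)]
    yrs <- sort(tr$birth_year)
    data.frame(rep = r,
               monotone = all(diff(mu) < 0),
               slope = unname(stats::coef(stats::lm(mu ~ yrs))[2]),
               range = mu[length(mu)] - mu[1])
  })
  do.call(rbind, out)
}
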