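test_that("the simulator is reproducible and seeds matter", {
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_dams_per_gen = 6,
                    litter_size = 4, seed = 10)
  s1 <- simulate_herd(cfg)
  s2 <- simulate_herd(cfg)
  expect_identical(as.data.frame(s1$ped), as.data.frame(s2$ped))
  expect_identical(s1$pheno$AGE, s2$pheno$AGE)
  cfg3 <- cfg; cfg3$seed <- 11L
  s3 <- simulate_herd(cfg3)
  expect_false(identical(s1$pheno$AGE, s3$pheno$AGE))
})

test_that("a single mating produces one litter of full sibs with the dam+year litter code", {
  cfg <- sim_config(n_founders = 2, n_generations = 1, n_dams_per_gen = 1,
                    litter_size = 10, seed = 3)
  sim <- simulate_pedigree(cfg)
  ped <- sim$ped
  off <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(ped), 2 + nrow(off))
  expect_gte(nrow(off), 1)
  expect_equal(length(unique(off$litter)), 1L)
  expect_equal(length(unique(off$sire)), 1L)
  expect_equal(length(unique(off$dam)), 1L)
  # litter id encodes the dam and the birth year
  expect_match(unique(off$litter), off$dam[1], fixed = TRUE)
  expect_match(unique(off$litter), as.character(off$birth_year[1]))
  expect_error(sim_config(n_founders = 1))
})

test_that("repeated full-sib mating follows the classic inbreeding recurrence", {
  cfg <- sim_config(n_founders = 2, n_generations = 4, n_dams_per_gen = 1,
                    litter_size = 8, seed = 1)
  sim <- simulate_pedigree(cfg)
  F <- compute_inbreeding(sim$ped)
  gen <- sim$generation[sim$ped$animal]
  byg <- tapply(unname(F), gen, unique)
  expect_equal(unname(byg[["1"]]), 0)
  # F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4
  expect_equal(unname(byg[["2"]]), 0.25)
  expect_equal(unname(byg[["3"]]), (1 + 2 * 0.25 + 0) / 4)
  expect_equal(unname(byg[["4"]]), (1 + 2 * 0.375 + 0.25) / 4)
})

test_that("founder breeding-value variance approaches sigma_a2 with herd size", {
  spec <- duroc_trait_specs()["AGE"]
  va <- spec$AGE$sigma_a2
  v_of <- function(nf, seed) {
    cfg <- sim_config(n_founders = nf, n_generations = 0, traits = spec,
                      seed = seed)
    var(simulate_herd(cfg)$true_bv[, 1])
  }
  expect_lt(abs(v_of(4000, 8) - va) / va, 0.08)
  expect_lt(abs(v_of(400, 8) - va) / va, 0.25)
})

test_that("offspring breeding values regress on a parent with slope one half", {
  cfg <- sim_config(n_founders = 100, n_generations = 3, n_dams_per_gen = 45,
                    litter_size = 8, seed = 15)
  sim <- simulate_herd(cfg)
  sp <- attr(sim$ped, "sire_pos")
  off <- which(sp > 0)
  slope <- coef(lm(sim$true_bv[off, 1] ~ sim$true_bv[sp[off], 1]))[2]
  # offspring sharing a sire are correlated, so allow ~3 clustered SEs
  expect_lt(abs(slope - 0.5), 0.12)
})

test_that("simulated phenotypic variance matches the trait architecture", {
  cfg <- sim_config(n_founders = 400, n_generations = 3, n_dams_per_gen = 200,
                    litter_size = 15,
                    fixed_effect_sd = c(farm = 0, year_season = 0, sex = 0,
                                        parity = 0),
                    seed = 99)
  sim <- simulate_herd(cfg)
  expect_gt(nrow(sim$ped), 8000)
  v <- var(sim$pheno$AGE)
  expect_lt(abs(v - 121.88) / 121.88, 0.05)
})

test_that("full-sib phenotypic covariance is half the additive plus the litter variance", {
  cfg <- sim_config(n_founders = 600, n_generations = 1, n_dams_per_gen = 300,
                    litter_size = 6,
                    fixed_effect_sd = c(farm = 0, year_season = 0, sex = 0,
                                        parity = 0),
                    seed = 71)
  sim <- simulate_herd(cfg)
  off <- sim$pheno[!is.na(sim$ped$litter), ]
  g <- factor(off$litter)
  k <- nlevels(g); N <- nrow(off)
  means <- tapply(off$AGE, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (means - mean(off$AGE))^2)
  ssw <- sum((off$AGE - means[g])^2)
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  n0 <- (N - sum(ns^2) / N) / (k - 1)   # ANOVA coefficient for unbalanced data
  between <- (msb - msw) / n0
  truth <- 0.5 * 36.38 + 23.94
  expect_lt(abs(between - truth) / truth, 0.2)
})

test_that("all-zero variances reduce phenotypes to mean plus fixed effects", {
  spec <- list(T = list(mean = 10, sigma_a2 = 0, sigma_c2 = 0, sigma_e2 = 0))
  cfg <- sim_config(n_founders = 20, n_generations = 1, n_dams_per_gen = 8,
                    litter_size = 3, traits = spec,
                    fixed_effect_sd = c(farm = 0, year_season = 0, sex = 0,
                                        parity = 0),
                    seed = 5)
  sim <- simulate_herd(cfg)
  expect_equal(sim$pheno$T, rep(10, nrow(sim$pheno)))
})

test_that("selection moves the true breeding-value trend and no-selection stays flat", {
  sel <- sim_config(n_founders = 150, n_generations = 3, n_dams_per_gen = 15,
                    litter_size = 10, selection = "phenotype",
                    selection_direction = "low", selection_proportion = 0.2,
                    seed = 42)
  s1 <- simulate_herd(sel)
  m_by_gen <- tapply(s1$true_bv[, 1], s1$generation[s1$ped$animal], mean)
  expect_lt(m_by_gen[length(m_by_gen)], m_by_gen[1] - 3)

  ctl <- sel; ctl$selection <- "none"
  s0 <- simulate_herd(ctl)
  m0 <- tapply(s0$true_bv[, 1], s0$generation[s0$ped$animal], mean)
  expect_lt(abs(m0[length(m0)] - m0[1]), 3)
})

test_that("invalid correlation matrices and single-sex founder sets are rejected", {
  expect_error(sim_config(traits = duroc_trait_specs()[c("AGE", "BL")],
                          genetic_cor = matrix(c(1, 2, 2, 1), 2)),
               "PSD")
  expect_error(sim_config(n_founders = 0), "n_founders")
})

test_that("simulate_phenotypes on a fixed pedigree keeps full-sib genetic covariance consistent with A", {
  ped <- random_pedigree(300, seed = 40, n_founders = 60)
  cfg <- sim_config(traits = duroc_trait_specs()["AGE"], seed = 9)
  out <- simulate_phenotypes(ped, cfg)
  expect_equal(nrow(out$pheno), 300)
  expect_equal(dim(out$true_bv), c(300L, 1L))
  # Mendelian sampling respects inbreeding: BV variance stays near sigma_a2
  expect_lt(abs(var(out$true_bv[, 1]) - 36.38) / 36.38, 0.5)
})
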