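ref <- duroc_reference()

test_that("published variance components reproduce the published phenotypic variances", {
  m1 <- ref$model1
  for (r in seq_len(nrow(m1))) {
    sp <- phenotypic_variance(list(sigma_a2 = m1$sigma_a2[r],
                                   sigma_e2 = m1$sigma_e2[r]), "animal")
    expect_equal(sp, m1$sigma_p2[r], tolerance = 1e-12)
  }
  m2 <- ref$model2
  keep <- m2$trait != "FCR"   # published FCR litter variance is inconsistent
  for (r in which(keep)) {
    sp <- phenotypic_variance(list(sigma_a2 = m2$sigma_a2[r],
                                   sigma_c2 = m2$sigma_c2[r],
                                   sigma_e2 = m2$sigma_e2[r]), "litter")
    expect_equal(sp, m2$sigma_p2[r], tolerance = 1e-2 * m2$sigma_p2[r])
  }
})

test_that("published components reproduce heritability and litter ratio to printed precision", {
  m1 <- ref$model1
  for (r in seq_len(nrow(m1))) {
    h <- heritability(list(sigma_a2 = m1$sigma_a2[r],
                           sigma_e2 = m1$sigma_e2[r]), "animal")$h2
    expect_lt(abs(h - m1$h2[r]), 0.0101)
  }
  m2 <- ref$model2
  for (r in which(m2$trait != "FCR")) {
    vc <- list(sigma_a2 = m2$sigma_a2[r], sigma_c2 = m2$sigma_c2[r],
               sigma_e2 = m2$sigma_e2[r])
    ulp_h <- if (m2$h2[r] < 0.1) 0.00101 else 0.0101
    expect_lt(abs(heritability(vc, "litter")$h2 - m2$h2[r]), ulp_h)
    expect_lt(abs(litter_ratio(vc)$c2 - m2$c2[r]), 0.0101)
  }
  # the variant ratio uses the smaller denominator and is always larger
  vc <- list(sigma_a2 = 36.38, sigma_c2 = 23.94, sigma_e2 = 61.56)
  lr <- litter_ratio(vc)
  expect_gt(lr$c2_alt, lr$c2)
})

test_that("model-2 variance ratios partition to one exactly", {
  vc <- list(sigma_a2 = 36.38, sigma_c2 = 23.94, sigma_e2 = 61.56)
  sp <- phenotypic_variance(vc, "litter")
  expect_equal(heritability(vc, "litter")$h2 + litter_ratio(vc)$c2 +
                 vc$sigma_e2 / sp, 1, tolerance = 1e-12)
})

test_that("correlation formulas: arithmetic, clamping, and the residual-only case", {
  expect_equal(genetic_correlation(list(gen = matrix(c(4, 3, 3, 9), 2),
                                        res = diag(2)))$r_g, 0.5)
  expect_equal(genetic_correlation(list(gen = matrix(c(4, 0, 0, 9), 2),
                                        res = diag(2)))$r_g, 0)
  expect_warning(
    rg <- genetic_correlation(list(gen = matrix(c(1, 1.2, 1.2, 1), 2),
                                   res = diag(2)))$r_g,
    "clamped")
  expect_equal(rg, 1)

  # only a residual correlation rho: r_p = rho * sigma_e2 / sigma_p2
  se2 <- 6; sa2 <- 4; rho <- 0.3
  vc <- list(gen = diag(c(sa2, sa2)),
             res = matrix(c(se2, rho * se2, rho * se2, se2), 2))
  expect_equal(phenotypic_correlation(vc), rho * se2 / (sa2 + se2))

  dup <- list(gen = matrix(c(4, 4, 4, 4), 2), res = matrix(c(1, 1, 1, 1), 2))
  expect_equal(phenotypic_correlation(dup), 1)
  expect_error(genetic_correlation(list(gen = diag(c(0, 1)), res = diag(2))),
               "zero genetic variance")
})

test_that("model mismatches are rejected", {
  expect_error(phenotypic_variance(list(sigma_a2 = 1, sigma_c2 = 1,
                                        sigma_e2 = 1), "animal"),
               "litter variance")
  expect_error(litter_ratio(list(sigma_a2 = 1, sigma_e2 = 1)), "litter-model")
})

test_that("AIC comparison prefers the smaller value, reports ties, and guards the data fingerprint", {
  f1 <- list(aic = 3193.7691, loglik = (2 * 2 - 3193.7691) / 2, k = 2,
             fingerprint = "BW:100:x:y")
  f2 <- list(aic = 1368.5132, loglik = (2 * 3 - 1368.5132) / 2, k = 3,
             fingerprint = "BW:100:x:y")
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$preferred, "model2")
  expect_equal(cmp$delta_aic, 3193.7691 - 1368.5132)

  f3 <- f2; f3$aic <- f1$aic; f3$k <- 2; f3$loglik <- f1$loglik
  expect_equal(compare_models(f1, f3)$preferred, "tie")

  f4 <- f2; f4$fingerprint <- "BW:99:x:y"
  expect_error(compare_models(f1, f4), "not comparable")
})

test_that("delta-method standard errors shrink with sample size", {
  fit_se <- function(dams) {
    cfg <- sim_config(n_founders = 60, n_generations = 2,
                      n_dams_per_gen = dams, litter_size = 6, seed = 50)
    sim <- simulate_herd(cfg)
    f <- fit_animal_model(sim$pheno, sim$ped, "AGE", c("farm", "sex"),
                          include_litter = TRUE)
    heritability(f)$se
  }
  se_small <- fit_se(10)
  se_large <- fit_se(28)
  expect_true(is.finite(se_small) && is.finite(se_large))
  expect_lt(se_large, se_small)
})
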