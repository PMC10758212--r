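test_that("the one-founder one-record system matches the hand-assembled MME", {
  ped <- pedigree("X", "0", "0")
  rec <- founder_records("X", 3)
  d <- build_design(rec, model_spec("y", character(), FALSE), ped)
  sys <- build_mme(d, build_a_inverse(ped), list(sigma_a2 = 1, sigma_e2 = 1))
  expect_equal(unname(as.matrix(sys$C)), matrix(c(1, 1, 1, 2), 2))
  expect_equal(sys$rhs, c(3, 3))
  expect_error(build_mme(d, build_a_inverse(ped),
                         list(sigma_a2 = 0, sigma_e2 = 1)), "positive")
})

test_that("coefficient matrix is exactly symmetric and litter block is I(1 + lambda_c) plus cross-terms", {
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_dams_per_gen = 8,
                    litter_size = 3, seed = 2)
  sim <- simulate_herd(cfg)
  d <- herd_design(sim)
  sys <- build_mme(d, build_a_inverse(sim$ped),
                   list(sigma_a2 = 30, sigma_c2 = 20, sigma_e2 = 60))
  C <- sys$C
  expect_equal(max(abs(C - Matrix::t(C))), 0)
  lb <- sys$blocks$litter
  litter_diag <- unname(Matrix::diag(C[lb, lb]))
  counts <- as.numeric(Matrix::colSums(d$Z_c))
  expect_equal(litter_diag, counts + 60 / 20)
})

test_that("with identity A and lambda 1, BLUP shrinks founder deviations by half", {
  n <- 12
  ids <- sprintf("F%02d", 1:n)
  ped <- pedigree(ids, rep("0", n), rep("0", n))
  set.seed(3)
  y <- rnorm(n, 5, 2)
  d <- build_design(founder_records(ids, y),
                    model_spec("y", character(), FALSE), ped)
  sys <- build_mme(d, build_a_inverse(ped), list(sigma_a2 = 1, sigma_e2 = 1))
  sol <- solve_blup(sys)
  expect_equal(unname(sol$b), mean(y))
  expect_equal(unname(sol$a), (y - mean(y)) / 2)
})

test_that("constant records give zero BLUPs and the common value as intercept", {
  cfg <- sim_config(n_founders = 16, n_generations = 1, n_dams_per_gen = 6,
                    litter_size = 3, seed = 5)
  sim <- simulate_herd(cfg)
  sim$pheno$AGE <- 7
  d <- herd_design(sim, factors = character())
  sys <- build_mme(d, build_a_inverse(sim$ped),
                   list(sigma_a2 = 2, sigma_c2 = 1, sigma_e2 = 3))
  sol <- solve_blup(sys)
  expect_equal(unname(sol$b), 7)
  expect_lt(max(abs(sol$a)), 1e-10)
  expect_lt(max(abs(sol$c)), 1e-10)
})

test_that("sparse MME solutions equal the dense GLS BLUP", {
  for (seed in c(1, 6, 9)) {
    ped <- random_pedigree(40, seed = seed)
    set.seed(seed + 100)
    rec <- data.frame(animal = ped$animal,
                      litter = sample(paste0("L", 1:8), nrow(ped), TRUE),
                      farm = sample(c("f1", "f2"), nrow(ped), TRUE),
                      y = rnorm(nrow(ped), 100, 10))
    d <- build_design(rec, model_spec("y", "farm", TRUE), ped)
    vc <- list(sigma_a2 = 40, sigma_c2 = 25, sigma_e2 = 60)
    sys <- build_mme(d, build_a_inverse(ped), vc)
    sol <- solve_blup(sys)
    oracle <- gls_blup(d, build_a_dense(ped), vc)
    expect_lt(max(abs(unname(sol$b) - oracle$b)), 1e-8)
    expect_lt(max(abs(unname(sol$a) - oracle$a)), 1e-8)
    expect_lt(max(abs(unname(sol$c) - oracle$c)), 1e-8)
  }
})

test_that("restricted log-likelihood agrees between sparse MME and dense V evaluation", {
  ped <- random_pedigree(25, seed = 8)
  set.seed(42)
  rec <- data.frame(animal = ped$animal,
                    litter = sample(paste0("L", 1:6), nrow(ped), TRUE),
                    farm = sample(c("f1", "f2"), nrow(ped), TRUE),
                    y = rnorm(nrow(ped), 50, 8))
  d <- build_design(rec, model_spec("y", "farm", TRUE), ped)
  ai <- build_a_inverse(ped)
  vc <- list(sigma_a2 = 20, sigma_c2 = 10, sigma_e2 = 35)
  expect_equal(restricted_loglik(vc, d, ai, "sparse"),
               restricted_loglik(vc, d, ai, "dense"),
               tolerance = 1e-10)
})

test_that("scaling the data and all variances obeys the REML Jacobian identity", {
  ped <- random_pedigree(30, seed = 12)
  set.seed(7)
  rec <- data.frame(animal = ped$animal, litter = NA_character_,
                    y = rnorm(nrow(ped), 10, 3))
  d <- build_design(rec, model_spec("y", character(), FALSE), ped)
  ai <- build_a_inverse(ped)
  vc <- list(sigma_a2 = 4, sigma_e2 = 9)
  ll1 <- restricted_loglik(vc, d, ai)
  rec2 <- rec; rec2$y <- 2 * rec$y
  d2 <- build_design(rec2, model_spec("y", character(), FALSE), ped)
  ll2 <- restricted_loglik(list(sigma_a2 = 16, sigma_e2 = 36), d2, ai)
  np <- d$n - d$p
  expect_equal(ll2 - ll1, -np * log(2), tolerance = 1e-9)
})
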