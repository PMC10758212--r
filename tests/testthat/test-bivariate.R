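# dense REML log-likelihood for the stacked two-trait model, used as oracle
dense_bivar_loglik <- function(d1, d2, A, G0, C0, R0) {
  n1 <- d1$n; n2 <- d2$n
  y <- c(d1$y, d2$y)
  X <- as.matrix(Matrix::bdiag(Matrix::Matrix(d1$X), Matrix::Matrix(d2$X)))
  Za <- as.matrix(Matrix::bdiag(d1$Z_a, d2$Z_a))
  lev <- sort(union(colnames(d1$Z_c), colnames(d2$Z_c)))
  ex <- function(Z) {
    M <- matrix(0, nrow(Z), length(lev), dimnames = list(NULL, lev))
    M[, colnames(Z)] <- as.matrix(Z)
    M
  }
  Zc <- as.matrix(Matrix::bdiag(ex(d1$Z_c), ex(d2$Z_c)))
  V <- Za %*% kronecker(G0, A) %*% t(Za) +
       Zc %*% kronecker(C0, diag(length(lev))) %*% t(Zc)
  # residual: R0 cross-covariance only for animals measured on both traits
  R <- diag(c(rep(R0[1, 1], n1), rep(R0[2, 2], n2)))
  both <- intersect(d1$animal, d2$animal)
  i1 <- match(both, d1$animal); i2 <- n1 + match(both, d2$animal)
  R[cbind(i1, i2)] <- R0[1, 2]
  R[cbind(i2, i1)] <- R0[2, 1]
  V <- V + R
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  np <- length(y) - ncol(X)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
          determinant(XtViX, logarithm = TRUE)$modulus[1] +
          as.numeric(t(y) %*% P %*% y)) - 0.5 * np * log(2 * pi)
}

small_bivar <- function(seed, drop1 = 4, drop2 = 5) {
  cfg <- sim_config(n_founders = 14, n_generations = 2, n_dams_per_gen = 5,
                    litter_size = 3,
                    traits = list(T1 = duroc_trait_specs()$AGE,
                                  T2 = duroc_trait_specs()$BL),
                    genetic_cor = matrix(c(1, -.5, -.5, 1), 2),
                    seed = seed)
  sim <- simulate_herd(cfg)
  ph1 <- sim$pheno; ph2 <- sim$pheno
  set.seed(seed)
  ph1$T1[sample(nrow(ph1), drop1)] <- NA   # records missing one trait
  ph2$T2[sample(nrow(ph2), drop2)] <- NA
  ph <- ph1; ph$T2 <- ph2$T2
  spec1 <- model_spec("T1", "sex", TRUE)
  spec2 <- model_spec("T2", "sex", TRUE)
  list(sim = sim,
       d1 = build_design(ph, spec1, sim$ped),
       d2 = build_design(ph, spec2, sim$ped),
       ainv = build_a_inverse(sim$ped))
}

test_that("sparse bivariate likelihood matches the dense oracle, with missing records", {
  sb <- small_bivar(3)
  G0 <- matrix(c(30, -4, -4, 1.4), 2)
  C0 <- matrix(c(20, -2, -2, 2.0), 2)
  R0 <- matrix(c(55, -4, -4, 5.5), 2)
  skel <- pedblup:::bivariate_skeleton(sb$d1, sb$d2, sb$ainv)
  ll_sparse <- pedblup:::bivariate_loglik(skel, G0, C0, R0)$loglik
  ll_dense <- dense_bivar_loglik(sb$d1, sb$d2, build_a_dense(sb$sim$ped),
                                 G0, C0, R0)
  expect_equal(ll_sparse, ll_dense, tolerance = 1e-9)
})

test_that("bivariate REML is a local maximum and reports PSD covariance matrices", {
  sb <- small_bivar(11)
  ms <- model_spec(c("T1", "T2"), "sex", TRUE, max_iter = 300)
  fit <- reml_fit_bivariate(sb$d1, sb$d2, sb$ainv, ms)
  expect_true(fit$converged)
  for (M in fit$components[c("gen", "lit", "res")]) {
    expect_equal(M, t(M))
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  ll0 <- fit$loglik
  skel <- pedblup:::bivariate_skeleton(sb$d1, sb$d2, sb$ainv)
  for (fac in c(0.95, 1.05)) {
    ll <- pedblup:::bivariate_loglik(skel, fit$components$gen * fac,
                                     fit$components$lit,
                                     fit$components$res)$loglik
    expect_lte(ll, ll0 + 1e-6)
  }
})

test_that("duplicated trait drives the genetic correlation estimate to one", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_dams_per_gen = 15,
                    litter_size = 5, seed = 19)
  sim <- simulate_herd(cfg)
  ph <- sim$pheno
  ph$T1 <- ph$AGE
  ph$T2 <- ph$AGE     # identical copy
  d1 <- build_design(ph, model_spec("T1", "sex", TRUE), sim$ped)
  d2 <- build_design(ph, model_spec("T2", "sex", TRUE), sim$ped)
  fit <- reml_fit_bivariate(d1, d2, build_a_inverse(sim$ped),
                            model_spec(c("T1", "T2"), "sex", TRUE))
  expect_gt(genetic_correlation(fit)$r_g, 0.95)
  expect_gt(phenotypic_correlation(fit), 0.95)
})

test_that("non-overlapping trait measurement is rejected as unidentifiable", {
  sb <- small_bivar(5)
  ph <- sb$sim$pheno
  n <- nrow(ph)
  half <- seq_len(floor(n / 2))
  ph$T1[half] <- NA
  ph$T2[-half] <- NA
  d1 <- build_design(ph, model_spec("T1", "sex", TRUE), sb$sim$ped)
  d2 <- build_design(ph, model_spec("T2", "sex", TRUE), sb$sim$ped)
  expect_error(reml_fit_bivariate(d1, d2, sb$ainv,
                                  model_spec(c("T1", "T2"), "sex", TRUE)),
               "unidentifiable")
})
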