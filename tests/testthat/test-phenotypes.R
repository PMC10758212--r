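pheno_cfg <- list(traits = c("BW", "FCR"), factors = c("farm", "sex"))

test_that("phenotype files round-trip, preserve missing values, and flag bad cells", {
  set.seed(5)
  n <- 500
  df <- data.frame(animal = sprintf("A%03d", 1:n),
                   litter = sprintf("L%02d", rep(1:50, each = 10)),
                   farm = sample(paste0("farm", 1:3), n, TRUE),
                   sex = sample(c("M", "F"), n, TRUE),
                   BW = round(rnorm(n, 1.66, 0.27), 3),
                   FCR = round(rnorm(n, 2.33, 0.24), 3))
  df$FCR[sample(n, 60)] <- NA
  f <- tempfile(fileext = ".csv")
  write_phenotypes(df, f)
  rd <- read_phenotypes(f, pheno_cfg)
  expect_equal(rd$BW, df$BW)
  expect_equal(rd$FCR, df$FCR)
  expect_equal(sum(is.na(rd$FCR)), 60)
  expect_equal(rd$farm, df$farm)

  bad <- df
  bad$BW <- as.character(bad$BW)
  bad$BW[7] <- "oops"
  f2 <- tempfile(fileext = ".csv")
  utils::write.table(bad, f2, sep = ",", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(f2, pheno_cfg), "line 7")
})

test_that("3-SD outlier rule removes only clear outliers, in a single pass", {
  # n <= 10 cannot produce |z| > 3 with the sample SD
  r1 <- data.frame(animal = letters[1:9], y = as.numeric(1:9))
  out1 <- filter_outliers(r1, "y", k = 3)
  expect_equal(out1$removed, 0)
  expect_equal(out1$records$y, r1$y)

  # 19 zeros + one 100: mean 5, sd sqrt(500) ~ 22.36, 3 sd ~ 67.1
  r2 <- data.frame(animal = paste0("a", 1:20), y = c(rep(0, 19), 100))
  out2 <- filter_outliers(r2, "y", k = 3)
  expect_equal(out2$removed, 1)
  expect_true(is.na(out2$records$y[20]))
  expect_equal(sum(!is.na(out2$records$y)), 19)
  expect_equal(unname(out2$bounds),
               c(5 - 3 * sqrt(500), 5 + 3 * sqrt(500)))

  # k = Inf is the identity
  out3 <- filter_outliers(r2, "y", k = Inf)
  expect_equal(out3$removed, 0)
  expect_equal(out3$records$y, r2$y)

  # identical values: sd 0, nothing removed
  r4 <- data.frame(animal = 1:5, y = rep(2, 5))
  expect_equal(filter_outliers(r4, "y")$removed, 0)

  # the record survives for other traits
  r5 <- data.frame(animal = paste0("a", 1:20), y = c(rep(0, 19), 100),
                   z = 1:20)
  out5 <- filter_outliers(r5, "y")
  expect_equal(out5$records$z, 1:20)
})

test_that("descriptive statistics report the sample SD and CV in percent", {
  set.seed(1)
  x <- rnorm(100, 10, 2)
  st <- descriptive_stats(data.frame(y = x), "y")
  expect_equal(st$mean, mean(x))
  expect_equal(st$sd, sd(x))
  expect_equal(st$cv_percent, 100 * sd(x) / mean(x))
  expect_equal(st$n, 100)
  expect_equal(st$min, min(x))

  cst <- descriptive_stats(data.frame(y = rep(3, 10)), "y")
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv_percent, 0)

  expect_warning(
    st2 <- descriptive_stats(data.frame(y = c(-1, -2, 3 - 0.1)), "y"),
    "CV undefined")
  expect_true(is.na(st2$cv_percent))
})

test_that("fixed-effect screen reproduces a hand-computed one-way ANOVA", {
  # groups {1,2,3} and {4,5,6}: SSB = 13.5, MSW = 1 -> F = 13.5 on (1, 4) df
  rec <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                    g = rep(c("a", "b"), each = 3))
  ft <- screen_fixed_effects(rec, "y", "g")
  expect_equal(ft$df, 1)
  expect_equal(ft$f_value, 13.5)
  expect_equal(ft$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  # identical group means -> F = 0, p = 1
  rec2 <- data.frame(y = c(1, 2, 3, 1, 2, 3),
                     g = rep(c("a", "b"), each = 3))
  ft2 <- screen_fixed_effects(rec2, "y", "g")
  expect_equal(ft2$f_value, 0)
  expect_equal(ft2$p_value, 1)
})

test_that("aliased factors are reported untestable, not dropped silently", {
  rec <- data.frame(y = rnorm(12), g = rep(c("a", "b"), 6))
  rec$h <- rec$g  # perfectly confounded
  ft <- screen_fixed_effects(rec, "y", c("g", "h"))
  expect_equal(nrow(ft), 2)
  expect_true(ft$testable[ft$factor == "g"])
  expect_false(ft$testable[ft$factor == "h"])
})

test_that("a 1-SD farm effect is detected in at least 95 percent of replicates", {
  hits <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    farm <- rep(paste0("f", 1:3), each = 20)
    eff <- c(f1 = 0, f2 = 1, f3 = -1)  # ~1 SD apart
    y <- rnorm(60) + eff[farm]
    screen_fixed_effects(data.frame(y = y, farm = farm), "y",
                         "farm")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("design matrices have the stated incidence structure", {
  ped <- pedigree(c("S", "D", "P", "Q"), c("0", "0", "S", "S"),
                  c("0", "0", "D", "D"))
  rec <- data.frame(animal = c("P", "Q", "S", "D"),
                    litter = c("L1", "L1", NA, "L2"),
                    farm = c("f1", "f2", "f1", "f2"),
                    y = c(1, 2, 3, 4))
  d1 <- build_design(rec, model_spec("y", "farm", include_litter = FALSE), ped)
  expect_equal(ncol(d1$X), 2)   # intercept + one farm contrast
  expect_null(d1$Z_c)
  expect_equal(qr(d1$X)$rank, ncol(d1$X))

  d2 <- build_design(rec, model_spec("y", "farm", include_litter = TRUE), ped)
  expect_equal(dim(d2$Z_c), c(4L, 3L))  # L1, L2, singleton for S
  expect_equal(as.numeric(Matrix::rowSums(d2$Z_c)), rep(1, 4))
  expect_equal(as.numeric(Matrix::rowSums(d2$Z_a)), rep(1, 4))
  expect_equal(ncol(d2$Z_a), nrow(ped))
  # each record's single 1 sits at the animal's pedigree position
  idx <- attr(ped, "id_index")
  expect_equal(apply(as.matrix(d2$Z_a), 1, which.max), unname(idx[rec$animal]))

  expect_error(build_design(rec, model_spec("BW", "farm"), ped), "absent")
})

test_that("design row sums hold on random inputs", {
  for (seed in c(3, 8)) {
    cfg <- sim_config(n_founders = 30, n_generations = 2, n_dams_per_gen = 10,
                      litter_size = 4, seed = seed)
    sim <- simulate_herd(cfg)
    d <- herd_design(sim, factors = c("farm", "year_season", "sex"))
    expect_equal(as.numeric(Matrix::rowSums(d$Z_a)), rep(1, d$n))
    expect_equal(as.numeric(Matrix::rowSums(d$Z_c)), rep(1, d$n))
    expect_equal(qr(d$X)$rank, ncol(d$X))
  }
})
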