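#' Simulation configuration for the synthetic herd
#'
#' Describes a multi-generation pig herd with discrete, non-overlapping
#' generations, litters around a mean size, and trait architectures given as
#' additive-genetic, common-litter and residual variances (the generative
#' model of the common-environment animal model). Defaults emulate a large
#' purebred Duroc nucleus herd: litters of about 10 piglets, six farms,
#' year-season levels built from generation x season, two sexes, parities
#' cycling over 1..11, trait scales and variance components from
#' [duroc_trait_specs].
#'
#' @param n_founders number of founder animals (half sires, half dams).
#' @param n_generations number of discrete offspring generations.
#' @param n_dams_per_gen dams mated each generation.
#' @param litters_per_dam litters per dam per generation.
#' @param litter_size mean Poisson litter size (minimum 1).
#' @param traits named list of trait specs, each a list with `mean`,
#'   `sigma_a2`, `sigma_c2`, `sigma_e2` (see [duroc_trait_specs]).
#' @param genetic_cor,litter_cor,residual_cor between-trait correlation
#'   matrices (symmetric PSD, unit diagonal); identity when NULL.
#' @param n_farms farm levels; farms are assigned per litter.
#' @param n_seasons seasons per generation-year; year_season levels are
#'   generation x season.
#' @param fixed_effect_sd named numeric: SD of the drawn level effects for
#'   `farm`, `year_season`, `sex`, `parity`, in units of each trait's
#'   phenotypic SD.
#' @param selection `"none"`, `"phenotype"` or `"tbv"` (true breeding
#'   value); truncation acts on the parent candidates of each generation.
#' @param selection_trait trait the truncation acts on.
#' @param selection_proportion proportion of candidates kept as parents.
#' @param selection_direction `"low"` (select smaller values, e.g. fewer
#'   days to market weight) or `"high"`.
#' @param seed integer seed; stages derive substreams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 120L,
                       n_generations = 5L,
                       n_dams_per_gen = 50L,
                       litters_per_dam = 1L,
                       litter_size = 10,
                       traits = duroc_trait_specs()["AGE"],
                       genetic_cor = NULL,
                       litter_cor = NULL,
                       residual_cor = NULL,
                       n_farms = 6L,
                       n_seasons = 4L,
                       fixed_effect_sd = c(farm = 0.3, year_season = 0.3,
                                           sex = 0.3, parity = 0.2),
                       selection = c("none", "phenotype", "tbv"),
                       selection_trait = names(traits)[1],
                       selection_proportion = 0.2,
                       selection_direction = c("low", "high"),
                       seed = 1L) {
  selection <- match.arg(selection)
  selection_direction <- match.arg(selection_direction)
  stopifnot(n_founders >= 2, litter_size >= 1,
            selection_proportion > 0, selection_proportion <= 1)
  nt <- length(traits)
  fix_cor <- function(M, what) {
    if (is.null(M)) return(diag(nt))
    M <- as.matrix(M)
    stopifnot(nrow(M) == nt, ncol(M) == nt)
    if (any(abs(M - t(M)) > 1e-12) || any(abs(diag(M) - 1) > 1e-12) ||
        min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(what, " correlation matrix must be symmetric PSD with unit diagonal")
    M
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_dams_per_gen = as.integer(n_dams_per_gen),
                 litters_per_dam = as.integer(litters_per_dam),
                 litter_size = litter_size,
                 traits = traits,
                 genetic_cor = fix_cor(genetic_cor, "genetic"),
                 litter_cor = fix_cor(litter_cor, "litter"),
                 residual_cor = fix_cor(residual_cor, "residual"),
                 n_farms = as.integer(n_farms),
                 n_seasons = as.integer(n_seasons),
                 fixed_effect_sd = fixed_effect_sd,
                 selection = selection,
                 selection_trait = selection_trait,
                 selection_proportion = selection_proportion,
                 selection_direction = selection_direction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Trait architectures of a purebred Duroc herd
#'
#' Published means and litter-model variance components for six traits of a
#' large purebred Duroc population: birth weight (BW, kg), age at 115 kg
#' (AGE, days), feed conversion ratio (FCR), body length (BL, cm), body
#' height (BH, cm) and front cannon circumference (FCC, cm). FCR's published
#' litter variance (0.079) is inconsistent with its published total (0.0429);
#' the reconciled value 0.0079 is used here.
#'
#' @return named list of trait specs usable in [sim_config].
#' @export
duroc_trait_specs <- function() {
  list(
    BW  = list(mean = 1.66,  sigma_a2 = 0.011, sigma_c2 = 0.016,  sigma_e2 = 0.038),
    AGE = list(mean = 185.4, sigma_a2 = 36.38, sigma_c2 = 23.94,  sigma_e2 = 61.56),
    FCR = list(mean = 2.33,  sigma_a2 = 0.012, sigma_c2 = 0.0079, sigma_e2 = 0.023),
    BL  = list(mean = 116.36, sigma_a2 = 1.55, sigma_c2 = 2.18,   sigma_e2 = 5.93),
    BH  = list(mean = 62.11, sigma_a2 = 0.45,  sigma_c2 = 0.59,   sigma_e2 = 2.14),
    FCC = list(mean = 18.86, sigma_a2 = 0.046, sigma_c2 = 0.094,  sigma_e2 = 0.43))
}

# substream seeds below 2^31, derived deterministically from the master seed
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483647)
}

# one multivariate normal draw matrix (n x t), covariance diag(sds) R diag(sds)
mvn_draw <- function(n, sds, R) {
  t_ <- length(sds)
  Z <- matrix(stats::rnorm(n * t_), n, t_)
  L <- t(chol(R + diag(1e-12, t_)))
  sweep(Z %*% t(L), 2, sds, `*`)
}

# ---------------------------------------------------------------------------
# Generational engine. Builds pedigree, true breeding values, litter effects,
# fixed-effect assignments and phenotypes generation by generation so that
# truncation selection can act between generations.
herd_engine <- function(cfg) {
  traits <- names(cfg$traits)
  nt <- length(traits)
  sa <- sqrt(vapply(cfg$traits, `[[`, 0, "sigma_a2"))
  sc <- sqrt(vapply(cfg$traits, `[[`, 0, "sigma_c2"))
  sde <- sqrt(vapply(cfg$traits, `[[`, 0, "sigma_e2"))
  mu <- vapply(cfg$traits, `[[`, 0, "mean")
  sp <- sqrt(sa^2 + sc^2 + sde^2)

  set.seed(derive_seed(cfg$seed, 1L))

  # fixed-effect level values (trait units)
  lev_eff <- function(nlev, frac)
    matrix(stats::rnorm(nlev * nt), nlev, nt) %*% diag(frac * sp, nt)
  n_ys <- (cfg$n_generations + 1L) * cfg$n_seasons
  eff <- list(farm = lev_eff(cfg$n_farms, cfg$fixed_effect_sd[["farm"]]),
              year_season = lev_eff(n_ys, cfg$fixed_effect_sd[["year_season"]]),
              sex = lev_eff(2L, cfg$fixed_effect_sd[["sex"]]),
              parity = lev_eff(11L, cfg$fixed_effect_sd[["parity"]]))

  nf <- cfg$n_founders
  n_m <- ceiling(nf / 2)
  animal <- sprintf("F%04d", seq_len(nf))
  sex <- c(rep("M", n_m), rep("F", nf - n_m))
  if (!any(sex == "M") || !any(sex == "F"))
    stop("founders must include both sexes")
  sire_pos <- dam_pos <- rep(0L, nf)
  litter <- rep(NA_character_, nf)
  gen <- rep(0L, nf)
  farm <- sample.int(cfg$n_farms, nf, replace = TRUE)
  ys <- sample.int(cfg$n_seasons, nf, replace = TRUE)    # generation-0 seasons
  parity <- rep(1L, nf)
  Fcoef <- rep(0, nf)
  Dms <- rep(1, nf)

  bv <- mvn_draw(nf, sa, cfg$genetic_cor)
  le <- mvn_draw(nf, sc, cfg$litter_cor)  # founders: singleton litters
  make_pheno <- function(idx) {
    fx <- eff$farm[farm[idx], , drop = FALSE] +
      eff$year_season[ys[idx], , drop = FALSE] +
      eff$sex[ifelse(sex[idx] == "M", 1L, 2L), , drop = FALSE] +
      eff$parity[parity[idx], , drop = FALSE]
    matrix(mu, length(idx), nt, byrow = TRUE) + fx +
      bv[idx, , drop = FALSE] + le[idx, , drop = FALSE] +
      mvn_draw(length(idx), sde, cfg$residual_cor)
  }
  Y <- make_pheno(seq_len(nf))

  sel_tr <- match(cfg$selection_trait, traits)
  select_parents <- function(idx) {
    if (cfg$selection == "none" || length(idx) <= 2) return(idx)
    crit <- if (cfg$selection == "phenotype") Y[idx, sel_tr] else bv[idx, sel_tr]
    k <- max(2L, ceiling(cfg$selection_proportion * length(idx)))
    idx[order(crit, decreasing = (cfg$selection_direction == "high"))[seq_len(k)]]
  }

  cur_m <- which(sex == "M")
  cur_f <- which(sex == "F")
  dam_litters <- integer(nf)   # litters borne so far, drives parity

  for (g in seq_len(cfg$n_generations)) {
    cand_m <- select_parents(cur_m)
    cand_f <- select_parents(cur_f)
    n_dams <- min(cfg$n_dams_per_gen, length(cand_f))
    dams <- if (length(cand_f) == 1) cand_f else sort(sample(cand_f, n_dams))
    for (d in dams) {
      for (l in seq_len(cfg$litters_per_dam)) {
        s <- if (length(cand_m) == 1) cand_m else sample(cand_m, 1L)
        size <- max(1L, stats::rpois(1L, cfg$litter_size))
        lid <- paste0(animal[d], "_y", 2012L + g)
        if (cfg$litters_per_dam > 1L) lid <- paste0(lid, "m", l)
        new_ids <- sprintf("%s_%02d", lid, seq_len(size))
        dam_litters[d] <- dam_litters[d] + 1L
        d_ms <- 0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
        idx <- length(animal) + seq_len(size)

        animal <- c(animal, new_ids)
        sex <- c(sex, sample(c("M", "F"), size, replace = TRUE))
        sire_pos <- c(sire_pos, rep(s, size))
        dam_pos <- c(dam_pos, rep(as.integer(d), size))
        litter <- c(litter, rep(lid, size))
        gen <- c(gen, rep(g, size))
        farm <- c(farm, rep(sample.int(cfg$n_farms, 1L), size))
        ys <- c(ys, rep(g * cfg$n_seasons + sample.int(cfg$n_seasons, 1L), size))
        parity <- c(parity, rep(1L + (dam_litters[d] - 1L) %% 11L, size))
        Dms <- c(Dms, rep(d_ms, size))
        Fcoef <- c(Fcoef, rep(NA_real_, size))

        pa <- (bv[s, ] + bv[d, ]) / 2
        bv <- rbind(bv, sweep(mvn_draw(size, sa * sqrt(d_ms), cfg$genetic_cor),
                              2, pa, `+`))
        le <- rbind(le, matrix(mvn_draw(1L, sc, cfg$litter_cor),
                               size, nt, byrow = TRUE))
      }
    }
    # inbreeding of the grown pedigree (positions already topological)
    Fcoef <- ml_inbreeding(sire_pos, dam_pos)$F
    dam_litters <- c(dam_litters, integer(length(animal) - length(dam_litters)))
    new_idx <- which(gen == g)
    Y <- rbind(Y, make_pheno(new_idx))
    cur_m <- new_idx[sex[new_idx] == "M"]
    cur_f <- new_idx[sex[new_idx] == "F"]
    if (!length(cur_m) || !length(cur_f))
      stop("generation ", g, " produced a single-sex cohort; increase sizes")
  }

  ped <- pedigree(animal,
                  ifelse(sire_pos == 0L, NA, animal[pmax(sire_pos, 1L)]),
                  ifelse(dam_pos == 0L, NA, animal[pmax(dam_pos, 1L)]),
                  birth_year = 2012L + gen, sex = sex, litter = litter)
  # engine order is already topological, so positions are unchanged
  stopifnot(identical(ped$animal, animal))

  colnames(Y) <- traits
  pheno <- data.frame(animal = animal, litter = litter,
                      farm = paste0("farm", farm),
                      year_season = sprintf("ys%02d", ys),
                      sex = sex, parity = paste0("p", parity),
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(Y))
  class(pheno) <- c("pheno_table", "data.frame")

  true <- data.frame(animal = rep(animal, nt),
                     trait = rep(traits, each = length(animal)),
                     true_bv = as.numeric(bv),
                     true_litter = as.numeric(le),
                     stringsAsFactors = FALSE)
  list(ped = ped, pheno = pheno, true = true,
       generation = stats::setNames(gen, animal),
       true_bv = bv, config = cfg)
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: each mated dam receives one random sire per litter;
#' litter sizes are Poisson around the configured mean (minimum 1); litter
#' ids combine the dam id and the birth year (the dam + birth-period
#' convention); sex is Bernoulli(1/2). Founders are generation 0 born 2012.
#' If the configuration requests selection, parents are the truncated
#' fraction of each cohort.
#'
#' @param cfg a [sim_config].
#' @return list: `ped` (a [pedigree]), `generation` (named integer),
#'   `litter_map` (named character: animal -> litter id).
#' @export
simulate_pedigree <- function(cfg) {
  sim <- herd_engine(cfg)
  list(ped = sim$ped, generation = sim$generation,
       litter_map = stats::setNames(sim$ped$litter, sim$ped$animal))
}

#' Simulate phenotypes and true values for a herd
#'
#' Runs the full generative model of the common-environment animal model
#' (see [sim_config]) and returns the pedigree, one phenotypic record per
#' animal, and the latent truth (breeding values, litter effects) retained
#' for recovery testing.
#'
#' @param cfg a [sim_config].
#' @return list: `ped`, `pheno` (a `pheno_table`), `true` (long data.frame
#'   animal/trait/true_bv/true_litter), `generation`, `true_bv` (matrix),
#'   `config`.
#' @export
simulate_herd <- function(cfg) {
  herd_engine(cfg)
}

#' Simulate phenotypes on a fixed pedigree
#'
#' Draws true breeding values down an existing pedigree (founder variance
#' sigma_a2, Mendelian sampling variance reduced by parental inbreeding),
#' one litter effect per litter code (animals without a litter code get
#' singleton litters), and i.i.d. residuals; no fixed effects beyond the
#' trait mean. Useful for checks on hand-built pedigrees.
#'
#' @param ped a [pedigree].
#' @param cfg a [sim_config] (its `traits` and correlation matrices are
#'   used).
#' @return list: `pheno` (animal, litter, trait columns), `true_bv` matrix,
#'   `litter_eff` matrix.
#' @export
simulate_phenotypes <- function(ped, cfg) {
  traits <- names(cfg$traits)
  nt <- length(traits)
  sa <- sqrt(vapply(cfg$traits, `[[`, 0, "sigma_a2"))
  sc <- sqrt(vapply(cfg$traits, `[[`, 0, "sigma_c2"))
  sde <- sqrt(vapply(cfg$traits, `[[`, 0, "sigma_e2"))
  mu <- vapply(cfg$traits, `[[`, 0, "mean")
  set.seed(derive_seed(cfg$seed, 3L))

  n <- nrow(ped)
  sp_ <- attr(ped, "sire_pos"); dp_ <- attr(ped, "dam_pos")
  D <- mendelian_ratios(ped)
  z <- mvn_draw(n, rep(1, nt), cfg$genetic_cor)
  bv <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    pa <- numeric(nt)
    if (sp_[i] > 0L) pa <- pa + bv[sp_[i], ] / 2
    if (dp_[i] > 0L) pa <- pa + bv[dp_[i], ] / 2
    bv[i, ] <- pa + sqrt(D[i]) * sa * z[i, ]
  }
  lit <- ped$litter
  lit[is.na(lit)] <- paste0("singleton_", ped$animal[is.na(lit)])
  lev <- unique(lit)
  le_lev <- mvn_draw(length(lev), sc, cfg$litter_cor)
  le <- le_lev[match(lit, lev), , drop = FALSE]
  Y <- matrix(mu, n, nt, byrow = TRUE) + bv + le +
    mvn_draw(n, sde, cfg$residual_cor)
  colnames(Y) <- traits
  colnames(bv) <- traits
  pheno <- cbind(data.frame(animal = ped$animal, litter = lit,
                            stringsAsFactors = FALSE),
                 as.data.frame(Y))
  class(pheno) <- c("pheno_table", "data.frame")
  list(pheno = pheno, true_bv = bv, litter_eff = le)
}
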