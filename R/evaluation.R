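#' Fit an animal model for one trait
#'
#' Convenience wrapper: builds the design for the trait and fixed factors,
#' then runs REML. The A-inverse can be passed in (and reused across traits
#' and models) or is built from the pedigree.
#'
#' @param pheno phenotype table (`pheno_table` or data.frame with `animal`,
#'   `litter`, factor and trait columns).
#' @param ped a [pedigree].
#' @param trait trait column name.
#' @param fixed_factors character vector of factor columns.
#' @param include_litter fit the common-environment model (TRUE) or the
#'   plain animal model (FALSE).
#' @param ainv optional prebuilt A-inverse.
#' @param ... passed to [model_spec].
#' @return a `fit_result`.
#' @export
fit_animal_model <- function(pheno, ped, trait, fixed_factors,
                             include_litter = TRUE, ainv = NULL, ...) {
  if (is.null(ainv)) ainv <- build_a_inverse(ped)
  spec <- model_spec(trait, fixed_factors, include_litter = include_litter, ...)
  design <- build_design(pheno, spec, ped)
  reml_fit(design, ainv, spec)
}

#' Extract estimated breeding values
#'
#' Maps the additive solutions of a solved model back to animal ids with
#' birth years attached. Every pedigree animal has an EBV, phenotyped or
#' not; animals without a birth year are retained but flagged so trend
#' computation can exclude them.
#'
#' @param fit a `fit_result` (or a [solve_blup] result) with an additive
#'   solution named by animal.
#' @param ped the [pedigree] the model was fitted over.
#' @param model_label label recorded in the output (e.g. "model1").
#' @return data.frame of class `ebv_result`: `animal`, `trait`, `model`,
#'   `ebv`, `birth_year`.
#' @export
extract_ebv <- function(fit, ped, model_label = NULL) {
  a <- if (!is.null(fit$solutions)) fit$solutions$a else fit$a
  if (is.null(a)) stop("no additive solutions found")
  trait <- if (!is.null(fit$trait)) fit$trait else NA_character_
  if (is.null(model_label)) {
    model_label <- if (!is.null(fit$model) && isTRUE(fit$model$include_litter))
      "litter" else "animal"
  }
  if (is.matrix(a)) {   # bivariate fit: one column per trait
    out <- do.call(rbind, lapply(seq_len(ncol(a)), function(k)
      data.frame(animal = rownames(a), trait = colnames(a)[k],
                 model = model_label, ebv = a[, k],
                 stringsAsFactors = FALSE)))
  } else {
    out <- data.frame(animal = names(a), trait = trait, model = model_label,
                      ebv = unname(a), stringsAsFactors = FALSE)
  }
  by <- ped$birth_year[match(out$animal, ped$animal)]
  if (anyNA(by))
    message(sum(is.na(by[!duplicated(out$animal)])),
            " animal(s) lack a birth year; excluded from trends")
  out$birth_year <- by
  rownames(out) <- NULL
  class(out) <- c("ebv_result", "data.frame")
  out
}

#' Genetic trend by birth year
#'
#' Arithmetic mean EBV per birth year, per trait and model. Years with no
#' animals are absent (not zero-filled); animals without a birth year are
#' excluded.
#'
#' @param ebv an `ebv_result` from [extract_ebv].
#' @return data.frame: `trait`, `model`, `birth_year`, `mean_ebv`, `n`.
#' @export
genetic_trend <- function(ebv) {
  dat <- ebv[!is.na(ebv$birth_year), , drop = FALSE]
  if (!nrow(dat)) stop("no animal with a known birth year")
  agg <- stats::aggregate(dat$ebv,
                          by = list(trait = dat$trait, model = dat$model,
                                    birth_year = dat$birth_year),
                          FUN = mean)
  cnt <- stats::aggregate(dat$ebv,
                          by = list(trait = dat$trait, model = dat$model,
                                    birth_year = dat$birth_year),
                          FUN = length)
  out <- data.frame(trait = agg$trait, model = agg$model,
                    birth_year = agg$birth_year, mean_ebv = agg$x,
                    n = cnt$x, stringsAsFactors = FALSE)
  out[order(out$trait, out$model, out$birth_year), , drop = FALSE]
}

#' Run the full evaluation pipeline
#'
#' End-to-end orchestration: read (or accept) pedigree and phenotypes,
#' apply the 3-SD outlier filter per trait, produce descriptive statistics,
#' screen fixed effects by Type-II F tests, fit both the plain animal model
#' and the common-environment model per trait, derive genetic parameters,
#' compare models by AIC, and compute EBVs and genetic trends under both
#' models. Deterministic: fitting is non-stochastic given the data.
#'
#' @param config list with elements:
#'   `pedigree` (a [pedigree] or file path), `phenotypes` (a table or file
#'   path, with `pheno_config` passed to [read_phenotypes] when a path),
#'   `traits` (character), `fixed_factors` (character),
#'   `outlier_k` (SD multiplier, default 3), `screen_alpha` (default 0.05),
#'   `use_screen` (drop non-significant factors per trait, default FALSE:
#'   the screen is advisory and all factors are kept unless asked).
#' @return list of class `pipeline_result`: `summary_stats`, `fixed_tests`,
#'   `fits` (per trait, `$animal` and `$litter`), `parameters` (tables for
#'   both models), `comparison` (per trait), `ebv`, `trends`, `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(outlier_k = 3, screen_alpha = 0.05,
                                use_screen = FALSE), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ped <- stage("pedigree", {
    if (inherits(cfg$pedigree, "pedigree")) cfg$pedigree
    else read_pedigree(cfg$pedigree, cfg$pedigree_dialect %||% list())
  })
  pheno <- stage("phenotypes", {
    if (is.data.frame(cfg$phenotypes)) cfg$phenotypes
    else read_phenotypes(cfg$phenotypes,
                         cfg$pheno_config %||% list(traits = cfg$traits,
                                                    factors = cfg$fixed_factors))
  })
  log <- list(n_pedigree = nrow(ped), n_records = nrow(pheno),
              outlier_k = cfg$outlier_k, removed = integer(0))

  for (tr in cfg$traits) {
    flt <- stage(paste0("outlier_filter:", tr),
                 filter_outliers(pheno, tr, k = cfg$outlier_k))
    pheno <- flt$records
    log$removed[tr] <- flt$removed
  }
  summary_stats <- stage("descriptives", trait_summary_table(pheno, cfg$traits))
  fixed_tests <- stage("fixed_effect_screen", {
    out <- lapply(cfg$traits, function(tr)
      cbind(trait = tr,
            screen_fixed_effects(pheno, tr, cfg$fixed_factors,
                                 alpha = cfg$screen_alpha)))
    do.call(rbind, out)
  })

  ainv <- stage("relationship", build_a_inverse(ped))
  fits <- list()
  comparison <- list()
  for (tr in cfg$traits) {
    facs <- cfg$fixed_factors
    if (isTRUE(cfg$use_screen)) {
      keep <- fixed_tests$factor[fixed_tests$trait == tr &
                                 fixed_tests$significant %in% TRUE]
      if (length(keep)) facs <- intersect(cfg$fixed_factors, keep)
    }
    fits[[tr]] <- list(
      animal = stage(paste0("fit_model1:", tr),
                     fit_animal_model(pheno, ped, tr, facs,
                                      include_litter = FALSE, ainv = ainv)),
      litter = stage(paste0("fit_model2:", tr),
                     fit_animal_model(pheno, ped, tr, facs,
                                      include_litter = TRUE, ainv = ainv)))
    comparison[[tr]] <- compare_models(fits[[tr]]$animal, fits[[tr]]$litter)
  }
  parameters <- list(
    animal = parameter_table(lapply(fits, `[[`, "animal")),
    litter = parameter_table(lapply(fits, `[[`, "litter")))

  ebv <- do.call(rbind, lapply(cfg$traits, function(tr) rbind(
    extract_ebv(fits[[tr]]$animal, ped, "model1"),
    extract_ebv(fits[[tr]]$litter, ped, "model2"))))
  trends <- genetic_trend(ebv)

  structure(list(summary_stats = summary_stats, fixed_tests = fixed_tests,
                 fits = fits, parameters = parameters,
                 comparison = comparison, ebv = ebv, trends = trends,
                 log = log),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
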