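#' Read a phenotype file
#'
#' Reads a delimited phenotype table (comma or tab autodetected). Trait
#' columns become numeric with missing values preserved; factor, animal and
#' litter columns stay character. A record must carry at least one trait
#' value. Unparseable numeric cells are an error naming the line.
#'
#' @param path delimited text file with a header.
#' @param config named list: `traits` (character vector of trait column
#'   names), `factors` (fixed-effect column names), `animal` (id column,
#'   default "animal"), `litter` (litter column, default "litter", may be
#'   absent from the file), `missing` (missing-value token, default "NA").
#' @return data.frame of class `pheno_table` with attribute `config`.
#' @export
read_phenotypes <- function(path, config) {
  stopifnot(is.list(config), !is.null(config$traits))
  config <- utils::modifyList(
    list(animal = "animal", litter = "litter", factors = character(),
         missing = "NA"), config)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c(config$missing, ""))
  absent <- setdiff(c(config$animal, config$factors, config$traits), names(raw))
  if (length(absent))
    stop("phenotype file lacks column(s): ", paste(absent, collapse = ", "))
  df <- data.frame(animal = raw[[config$animal]], stringsAsFactors = FALSE)
  df$litter <- if (config$litter %in% names(raw)) raw[[config$litter]]
               else NA_character_
  for (f in config$factors) df[[f]] <- raw[[f]]
  for (tr in config$traits) {
    v <- raw[[tr]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("unparseable value '", v[bad[1]], "' for trait ", tr,
           " at data line ", bad[1])
    df[[tr]] <- num
  }
  none <- rowSums(!is.na(df[, config$traits, drop = FALSE])) == 0
  if (any(none))
    warning(sum(none), " record(s) carry no trait value")
  attr(df, "config") <- config
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes]; round-trips a `pheno_table`.
#' @param pheno a `pheno_table` or plain data.frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_phenotypes <- function(pheno, path, sep = ",") {
  utils::write.table(as.data.frame(pheno), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Remove trait outliers beyond k standard deviations
#'
#' Single-pass rule: mean and sample SD are computed once over all
#' non-missing values of `trait`, and values with |x - mean| > k * sd are
#' blanked (set missing) for that trait only; the record is retained for
#' other traits. The filter is applied once per trait before model fitting,
#' never iterated.
#'
#' @param records data.frame with a numeric `trait` column.
#' @param trait trait column name.
#' @param k SD multiplier (default 3).
#' @return list with `records` (filtered table), `removed` (count of blanked
#'   values), and `bounds` (the mean +/- k*sd interval used).
#' @export
filter_outliers <- function(records, trait, k = 3) {
  x <- records[[trait]]
  obs <- !is.na(x)
  if (sum(obs) < 2) stop("need at least 2 non-missing values for ", trait)
  m <- mean(x[obs])
  s <- stats::sd(x[obs])
  if (is.infinite(k)) {
    out <- rep(FALSE, length(x))
  } else {
    out <- obs & abs(x - m) > k * s
    out[is.na(out)] <- FALSE
  }
  records[[trait]][out] <- NA_real_
  list(records = records, removed = sum(out),
       bounds = c(lower = m - k * s, upper = m + k * s))
}

#' Descriptive statistics for one trait
#'
#' @param records data.frame with the trait column.
#' @param trait trait column name.
#' @return one-row data.frame: `trait`, `n`, `mean`, `sd`, `min`, `max`,
#'   `cv_percent` (= 100 * sd / mean; `NA` with a warning when mean <= 0).
#' @export
descriptive_stats <- function(records, trait) {
  x <- records[[trait]]
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 non-missing values for ", trait)
  m <- mean(x)
  s <- stats::sd(x)
  cv <- if (m > 0) 100 * s / m else {
    warning("mean of ", trait, " is not positive; CV undefined")
    NA_real_
  }
  data.frame(trait = trait, n = length(x), mean = m, sd = s,
             min = min(x), max = max(x), cv_percent = cv,
             stringsAsFactors = FALSE)
}

#' Descriptive summary table for several traits
#' @param records data.frame with trait columns.
#' @param traits character vector of trait column names.
#' @return data.frame, one row per trait (columns as [descriptive_stats]).
#' @export
trait_summary_table <- function(records, traits) {
  do.call(rbind, lapply(traits, function(tr) descriptive_stats(records, tr)))
}

#' F-test screen of fixed effects
#'
#' Fits an ordinary least-squares model of the trait on all candidate
#' factors jointly and reports a per-factor F test from Type-II sums of
#' squares (robust to factor order for main-effects models). Factors with
#' aliased (confounded) columns are reported as untestable rather than
#' silently dropped.
#'
#' @param records data.frame with trait and factor columns.
#' @param trait trait column name.
#' @param factors character vector of factor column names (>= 2 observed
#'   levels each among records with the trait observed).
#' @param alpha significance threshold flagging factors for model inclusion.
#' @return data.frame: `factor`, `df`, `f_value`, `p_value`, `significant`,
#'   `testable`.
#' @export
screen_fixed_effects <- function(records, trait, factors, alpha = 0.05) {
  dat <- records[!is.na(records[[trait]]), c(trait, factors), drop = FALSE]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2)
      stop("factor ", f, " has fewer than 2 observed levels")
  }
  fml <- stats::as.formula(paste(trait, "~", paste(factors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  aliased_terms <- character()
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    aliased_terms <- unique(factors[vapply(
      factors, function(f) any(startsWith(bad, f)), TRUE)])
    ok <- setdiff(factors, aliased_terms)
    if (!length(ok))
      stop("all factors aliased; nothing testable")
    fit <- stats::lm(stats::as.formula(
      paste(trait, "~", paste(ok, collapse = " + "))), data = dat)
  }
  an <- car::Anova(fit, type = 2)
  rows <- setdiff(rownames(an), "Residuals")
  out <- data.frame(factor = rows,
                    df = an[rows, "Df"],
                    f_value = an[rows, "F value"],
                    p_value = an[rows, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  if (length(aliased_terms))
    out <- rbind(out, data.frame(factor = aliased_terms, df = NA_integer_,
                                 f_value = NA_real_, p_value = NA_real_))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$testable <- !is.na(out$f_value)
  rownames(out) <- NULL
  out[match(factors, out$factor), , drop = FALSE]
}

#' Model specification for the animal model
#'
#' @param traits one trait name (single-trait) or two (bivariate).
#' @param fixed_factors character vector of fixed-effect factor columns.
#' @param include_litter logical: add the common-litter random effect
#'   (the common-environment model) or not (the plain animal model).
#' @param tol relative convergence tolerance for REML.
#' @param max_iter maximum optimizer iterations.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(traits, fixed_factors, include_litter = TRUE,
                       tol = 1e-8, max_iter = 200L) {
  stopifnot(length(traits) %in% 1:2, !anyDuplicated(traits), tol > 0)
  structure(list(traits = traits, fixed_factors = fixed_factors,
                 include_litter = include_litter, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "model_spec")
}

#' Build design matrices for one trait
#'
#' Assembles the observation vector and incidence matrices of the animal
#' model: `X` (fixed effects, full-rank treatment coding with intercept,
#' reference level = first level lexicographically), `Z_a` (one 1 per row at
#' the animal's pedigree position; unphenotyped animals enter only through
#' A), and, when the model includes litters, `Z_c` (one 1 per row at its
#' litter column; records with unknown litter get a singleton litter).
#'
#' @param records data.frame with trait, factor, `animal` and `litter`
#'   columns; rows with the trait missing are dropped.
#' @param model a [model_spec] (its first trait is used).
#' @param ped a [pedigree] containing every phenotyped animal.
#' @return list of class `design`: `y`, `X`, `Z_a`, `Z_c` (NULL without
#'   litter effect), `labels`, `trait`, `animal`, `n`, `p`.
#' @export
build_design <- function(records, model, ped) {
  trait <- model$traits[1]
  if (!trait %in% names(records) || all(is.na(records[[trait]])))
    stop("trait ", trait, " absent from all records")
  dat <- records[!is.na(records[[trait]]), , drop = FALSE]
  idx <- attr(ped, "id_index")
  unknown <- setdiff(dat$animal, names(idx))
  if (length(unknown))
    stop(length(unknown), " phenotyped animal(s) not in pedigree (first: ",
         unknown[1], "); register them as founders first")

  y <- dat[[trait]]
  n <- length(y)

  keep <- character()
  for (f in model$fixed_factors) {
    dat[[f]] <- factor(as.character(dat[[f]]))  # sorted levels -> first ref
    if (nlevels(dat[[f]]) >= 2) keep <- c(keep, f)
    else warning("factor ", f, " constant among ", trait,
                 " records; dropped from X")
  }
  fml <- if (length(keep)) stats::as.formula(paste("~", paste(keep, collapse = " + ")))
         else ~ 1
  X <- stats::model.matrix(fml, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop_cols), " aliased fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }

  Z_a <- Matrix::sparseMatrix(i = seq_len(n), j = unname(idx[dat$animal]),
                              x = 1, dims = c(n, nrow(ped)),
                              dimnames = list(NULL, ped$animal))
  Z_c <- NULL
  if (isTRUE(model$include_litter)) {
    lit <- dat$litter
    lit[is.na(lit)] <- paste0("singleton_", dat$animal[is.na(lit)])
    lev <- sort(unique(lit))
    Z_c <- Matrix::sparseMatrix(i = seq_len(n), j = match(lit, lev),
                                x = 1, dims = c(n, length(lev)),
                                dimnames = list(NULL, lev))
  }
  structure(list(y = y, X = X, Z_a = Z_a, Z_c = Z_c,
                 labels = list(fixed = colnames(X), additive = ped$animal,
                               litter = if (!is.null(Z_c)) colnames(Z_c)),
                 trait = trait, animal = dat$animal,
                 n = n, p = ncol(X)),
            class = "design")
}
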