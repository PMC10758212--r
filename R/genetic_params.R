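# Derived quantitative-genetic parameters: phenotypic variance, heritability,
# litter-effect ratio, genetic/phenotypic correlations, and AIC-based model
# comparison. All accept either a fitted `fit_result` or a bare component
# list such as published table entries.

components_of <- function(x) {
  if (inherits(x, "fit_result")) x$components else x
}

#' Phenotypic variance from variance components
#'
#' The plain animal model decomposes the phenotype into additive genetic and
#' residual parts (sigma_p2 = sigma_a2 + sigma_e2); the litter model adds the
#' common-litter variance (sigma_p2 = sigma_a2 + sigma_c2 + sigma_e2).
#'
#' @param vc `fit_result` or list with `sigma_a2`, `sigma_e2` and, for the
#'   litter model, `sigma_c2`.
#' @param model `"animal"` (no litter term) or `"litter"`.
#' @return scalar phenotypic variance.
#' @export
phenotypic_variance <- function(vc, model = c("litter", "animal")) {
  vc <- components_of(vc)
  model <- match.arg(model)
  if (model == "animal") {
    if (!is.null(vc$sigma_c2))
      stop("plain animal model cannot carry a litter variance")
    vc$sigma_a2 + vc$sigma_e2
  } else {
    if (is.null(vc$sigma_c2)) stop("litter model requires sigma_c2")
    vc$sigma_a2 + vc$sigma_c2 + vc$sigma_e2
  }
}

# delta-method SE of a ratio num/den where num = w'x, den = 1'x for
# component vector x with covariance S: gradient g_i = (d_i*den - num)/den^2
ratio_se <- function(num_w, x, S) {
  num <- sum(num_w * x)
  den <- sum(x)
  g <- (num_w * den - num) / den^2
  sqrt(max(as.numeric(t(g) %*% S %*% g), 0))
}

#' Heritability
#'
#' h2 = sigma_a2 / sigma_p2 under the model's phenotypic-variance
#' decomposition, with a delta-method standard error when the component
#' covariance matrix is available (it is for fitted models).
#'
#' @inheritParams phenotypic_variance
#' @return list with `h2` and `se` (`NA` when no covariance is available).
#' @export
heritability <- function(vc, model = c("litter", "animal")) {
  model <- match.arg(model)
  vc <- components_of(vc)
  sp2 <- phenotypic_variance(vc, model)
  if (sp2 <= 0) stop("phenotypic variance is zero; heritability undefined")
  h2 <- vc$sigma_a2 / sp2
  se <- NA_real_
  if (!is.null(vc$cov) && all(is.finite(vc$cov))) {
    x <- if (model == "litter") c(vc$sigma_a2, vc$sigma_c2, vc$sigma_e2)
         else c(vc$sigma_a2, vc$sigma_e2)
    se <- ratio_se(c(1, rep(0, length(x) - 1)), x, vc$cov)
  }
  list(h2 = h2, se = se)
}

#' Common-litter effect ratio
#'
#' Proportion of the total phenotypic variance explained by the shared
#' litter environment: c2 = sigma_c2 / (sigma_a2 + sigma_c2 + sigma_e2).
#' A variant ratio with the litter variance left out of the denominator
#' (sigma_c2 / (sigma_a2 + sigma_e2)) is also returned as `c2_alt`, since
#' both conventions circulate; the total-variance form is the primary value.
#'
#' @param vc `fit_result` or component list with `sigma_c2`.
#' @return list with `c2`, `c2_alt` and `se` (delta method, for `c2`).
#' @export
litter_ratio <- function(vc) {
  vc <- components_of(vc)
  if (is.null(vc$sigma_c2))
    stop("litter ratio requires a litter-model fit (sigma_c2)")
  sp2 <- vc$sigma_a2 + vc$sigma_c2 + vc$sigma_e2
  se <- NA_real_
  if (!is.null(vc$cov) && all(is.finite(vc$cov)))
    se <- ratio_se(c(0, 1, 0), c(vc$sigma_a2, vc$sigma_c2, vc$sigma_e2), vc$cov)
  list(c2 = vc$sigma_c2 / sp2,
       c2_alt = vc$sigma_c2 / (vc$sigma_a2 + vc$sigma_e2),
       se = se)
}

# pull 2x2 covariance matrices out of a bivariate fit or bare list
bivar_components <- function(x) {
  vc <- components_of(x)
  if (is.null(vc$gen) || is.null(vc$res))
    stop("bivariate components require 'gen' and 'res' 2x2 matrices")
  vc
}

#' Genetic correlation between two traits
#'
#' r_g = sigma_a12 / sqrt(sigma_a1^2 * sigma_a2^2) from the 2x2 genetic
#' covariance matrix of a bivariate fit. Values are clamped to [-1, 1] with
#' a warning (possible when a boundary fit leaves the estimate marginally
#' outside). The standard error is by the delta method from the asymptotic
#' covariance of (g11, g12, g22) when available.
#'
#' @param vc bivariate `fit_result` or list with matrix `gen` (and
#'   optionally `cov` whose first three rows/cols are g11, g12, g22).
#' @return list with `r_g` and `se`.
#' @export
genetic_correlation <- function(vc) {
  vc <- bivar_components(vc)
  G <- vc$gen
  if (G[1, 1] <= 0 || G[2, 2] <= 0)
    stop("zero genetic variance; correlation undefined")
  r <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  if (abs(r) > 1) {
    warning("genetic correlation ", format(r), " clamped to [-1, 1]")
    r <- sign(r)
  }
  se <- NA_real_
  if (!is.null(vc$cov) && all(c("g11", "g12", "g22") %in% rownames(vc$cov))) {
    S <- vc$cov[c("g11", "g12", "g22"), c("g11", "g12", "g22")]
    if (all(is.finite(S))) {
      g <- c(-r / (2 * G[1, 1]), 1 / sqrt(G[1, 1] * G[2, 2]), -r / (2 * G[2, 2]))
      se <- sqrt(max(as.numeric(t(g) %*% S %*% g), 0))
    }
  }
  list(r_g = r, se = se)
}

#' Phenotypic correlation between two traits
#'
#' The phenotypic covariance is the sum of the component covariances
#' (genetic + litter when present + residual for doubly-measured records),
#' divided by the square root of the product of phenotypic variances.
#'
#' @param vc bivariate `fit_result` or list with matrices `gen`, `res` and
#'   optionally `lit`.
#' @return scalar phenotypic correlation.
#' @export
phenotypic_correlation <- function(vc) {
  vc <- bivar_components(vc)
  P <- vc$gen + vc$res
  if (!is.null(vc$lit)) P <- P + vc$lit
  if (P[1, 1] <= 0 || P[2, 2] <= 0)
    stop("zero phenotypic variance; correlation undefined")
  r <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  if (abs(r) > 1) {
    warning("phenotypic correlation ", format(r), " clamped to [-1, 1]")
    r <- sign(r)
  }
  r
}

#' Compare two fitted models by AIC
#'
#' Flags the smaller-AIC model as preferred. Refuses the comparison when the
#' two fits were not produced from the same records and trait (their
#' likelihoods would not be comparable).
#'
#' @param fit1,fit2 `fit_result` objects on identical data (e.g. the plain
#'   animal model and the litter model).
#' @return list of class `model_comparison`: `aic_model1`, `aic_model2`,
#'   `delta_aic` (= aic1 - aic2), `preferred` ("model1"/"model2"/"tie").
#' @export
compare_models <- function(fit1, fit2) {
  if (!identical(fit1$fingerprint, fit2$fingerprint))
    stop("fits are not on the same records; AIC not comparable")
  a1 <- aic(fit1); a2 <- aic(fit2)
  structure(list(aic_model1 = a1, aic_model2 = a2, delta_aic = a1 - a2,
                 preferred = if (isTRUE(all.equal(a1, a2))) "tie"
                             else if (a1 < a2) "model1" else "model2"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("AIC model 1: %.4f | AIC model 2: %.4f | delta: %.4f -> %s\n",
              x$aic_model1, x$aic_model2, x$delta_aic, x$preferred))
  invisible(x)
}

#' Single-trait parameter report
#'
#' Tabulates variance components, phenotypic variance, heritability (+/- SE)
#' and, for litter models, the litter-effect ratio, alongside AIC — the
#' layout of a standard variance-component report.
#'
#' @param fits named list of `fit_result` objects (names = traits).
#' @return data.frame, one row per fit.
#' @export
parameter_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(tr) {
    f <- fits[[tr]]
    cc <- f$components
    litter <- !is.null(cc$sigma_c2)
    h <- heritability(f, model = if (litter) "litter" else "animal")
    data.frame(trait = tr,
               sigma_a2 = cc$sigma_a2,
               sigma_c2 = if (litter) cc$sigma_c2 else NA_real_,
               sigma_e2 = cc$sigma_e2,
               sigma_p2 = phenotypic_variance(f, if (litter) "litter" else "animal"),
               h2 = h$h2, h2_se = h$se,
               c2 = if (litter) litter_ratio(f)$c2 else NA_real_,
               loglik = f$loglik, aic = f$aic, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
}
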