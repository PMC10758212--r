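#' REML variance-component estimation for a single-trait animal model
#'
#' Maximizes the restricted log-likelihood of the animal model (with or
#' without a common-litter random effect) over the variance ratios
#' sigma_a2/sigma_e2 (and sigma_c2/sigma_e2), with the residual variance
#' profiled out analytically. Every likelihood evaluation is a single sparse
#' Cholesky factorization of the mixed-model equations, so the fit is
#' deterministic given the data. Standard errors come from the inverse
#' average-information matrix evaluated at convergence.
#'
#' @param design a `design` from [build_design].
#' @param ainv sparse A-inverse over the full pedigree.
#' @param model a [model_spec] (controls litter inclusion, tolerance,
#'   iteration cap).
#' @param init optional list of starting values `sigma_a2`, `sigma_c2`,
#'   `sigma_e2`; the default assigns a quarter of the OLS residual variance
#'   to each random component and the remainder to the residual.
#' @return list of class `fit_result`: `components` (named variances with
#'   `se`, and `cov` = their asymptotic covariance matrix), `loglik`, `k`,
#'   `aic`, `converged`, `iterations`, `ai_matrix`, `solutions` (BLUE/BLUP
#'   at the estimates), `blocks`, `labels`, `model`, `fingerprint`.
#' @export
reml_fit <- function(design, ainv, model, init = NULL) {
  has_c <- isTRUE(model$include_litter)
  if (has_c && is.null(design$Z_c))
    stop("model includes litter effect but design has no Z_c")
  if (has_c && ncol(design$Z_c) < 2)
    stop("litter model needs at least 2 litters")
  skel <- mme_skeleton(design, ainv)

  # starting ratios gamma = sigma_x2 / sigma_e2
  if (is.null(init)) {
    ols <- stats::lm.fit(design$X, design$y)
    v <- stats::var(ols$residuals)
    gam0 <- if (has_c) c(0.5, 0.5) else 1 / 3
  } else {
    gam0 <- init$sigma_a2 / init$sigma_e2
    if (has_c) gam0 <- c(gam0, init$sigma_c2 / init$sigma_e2)
  }

  negll <- function(par) {
    g <- exp(par)
    la <- 1 / g[1]
    lc <- if (has_c) 1 / g[2]
    -loglik_lambda(skel, la, lc)$loglik
  }
  opt <- nlminb_restarted(log(gam0), negll,
                          lower = log(1e-8), upper = log(1e8),
                          iter.max = model$max_iter,
                          rel.tol = min(model$tol, 1e-10))
  g <- exp(opt$par)
  la <- 1 / g[1]
  lc <- if (has_c) 1 / g[2]
  final <- loglik_lambda(skel, la, lc)
  se2 <- final$sigma_e2
  vc <- list(sigma_a2 = g[1] * se2,
             sigma_c2 = if (has_c) g[2] * se2,
             sigma_e2 = se2)

  ai <- ai_matrix(design, ainv, skel, final, vc)
  cov <- tryCatch(solve(ai), error = function(e) {
    warning("average-information matrix singular; SEs unavailable")
    matrix(NA_real_, nrow(ai), ncol(ai), dimnames = dimnames(ai))
  })
  se <- sqrt(pmax(diag(cov), 0))

  sol <- final$sol
  k <- if (has_c) 3L else 2L
  fit <- list(components = list(sigma_a2 = vc$sigma_a2,
                                sigma_c2 = vc$sigma_c2,
                                sigma_e2 = vc$sigma_e2,
                                se = se, cov = cov),
              loglik = final$loglik,
              k = k,
              aic = 2 * k - 2 * final$loglik,
              converged = opt$convergence == 0 && opt$iterations < model$max_iter,
              iterations = opt$iterations,
              message = opt$message,
              ai_matrix = ai,
              solutions = list(
                b = stats::setNames(sol[skel$blocks$fixed], skel$labels$fixed),
                a = stats::setNames(sol[skel$blocks$additive], skel$labels$additive),
                c = if (has_c) stats::setNames(sol[skel$blocks$litter],
                                               skel$labels$litter)),
              blocks = skel$blocks, labels = skel$labels,
              model = model,
              trait = design$trait,
              n = design$n,
              fingerprint = data_fingerprint(design))
  class(fit) <- "fit_result"
  fit
}

# Average-information matrix at the REML estimates, on the variance scale
# (order a, [c,] e). Uses the identity P x = (x - X b_x - W u_x)/sigma_e2,
# where (b_x, u_x) solve the MME with working response x, so each column
# costs one triangular solve against the converged factorization.
ai_matrix <- function(design, ainv, skel, final, vc) {
  has_c <- !is.null(vc$sigma_c2)
  y <- design$y
  X <- design$X; Za <- design$Z_a; Zc <- design$Z_c
  sol <- final$sol
  fitted <- as.numeric(X %*% sol[skel$blocks$fixed]) +
    as.numeric(Za %*% sol[skel$blocks$additive])
  if (has_c) fitted <- fitted + as.numeric(Zc %*% sol[skel$blocks$litter])
  Py <- (y - fitted) / vc$sigma_e2

  Pvec <- function(x) {
    rhs <- c(as.numeric(Matrix::crossprod(X, x)),
             as.numeric(Matrix::crossprod(Za, x)),
             if (has_c) as.numeric(Matrix::crossprod(Zc, x)))
    s <- as.numeric(Matrix::solve(final$chol, rhs, system = "A"))
    fx <- as.numeric(X %*% s[skel$blocks$fixed]) +
      as.numeric(Za %*% s[skel$blocks$additive])
    if (has_c) fx <- fx + as.numeric(Zc %*% s[skel$blocks$litter])
    (x - fx) / vc$sigma_e2
  }

  f_a <- as.numeric(Za %*% Matrix::solve(ainv, Matrix::crossprod(Za, Py)))
  fs <- list(a = f_a)
  if (has_c) fs$c <- as.numeric(Zc %*% Matrix::crossprod(Zc, Py))
  fs$e <- Py

  Pf <- lapply(fs, Pvec)
  k <- length(fs)
  ai <- matrix(0, k, k, dimnames = list(names(fs), names(fs)))
  for (i in seq_len(k))
    for (j in i:k)
      ai[i, j] <- ai[j, i] <- 0.5 * sum(fs[[i]] * Pf[[j]])
  ai
}

# Fingerprint guarding AIC comparisons: same trait, same records.
data_fingerprint <- function(design) {
  ids <- sort(design$animal)
  paste(design$trait, design$n,
        format(sum(design$y) + sum(design$y^2), digits = 15),
        sum(cumsum(utf8ToInt(paste(ids, collapse = ""))) %% 2147483647) %% 2147483647,
        sep = ":")
}

# nlminb with one restart on non-zero convergence codes. PORT's
# "false convergence (8)" routinely fires when the start is already near the
# optimum and the finite-difference gradient is noise-dominated; in that case
# a local probe (no coordinate perturbation improves the objective beyond
# round-off) decides whether the point is accepted as converged.
nlminb_restarted <- function(start, objective, lower, upper, iter.max,
                             rel.tol) {
  ctrl <- list(iter.max = iter.max, eval.max = 40L * iter.max,
               rel.tol = rel.tol)
  opt <- stats::nlminb(start, objective, lower = lower, upper = upper,
                       control = ctrl)
  total_iter <- opt$iterations
  if (opt$convergence != 0) {
    opt2 <- stats::nlminb(opt$par, objective, lower = lower, upper = upper,
                          control = ctrl)
    if (opt2$objective <= opt$objective) {
      opt2$iterations <- total_iter + opt2$iterations
      opt <- opt2
    }
  }
  if (opt$convergence != 0) {
    f0 <- opt$objective
    probe <- vapply(seq_along(opt$par), function(k) {
      delta <- 1e-4 * max(abs(opt$par[k]), 1e-2)
      up <- replace(opt$par, k, min(opt$par[k] + delta, upper[min(k, length(upper))]))
      dn <- replace(opt$par, k, max(opt$par[k] - delta, lower[min(k, length(lower))]))
      min(objective(up), objective(dn))
    }, 0)
    if (all(probe >= f0 - 1e-6 * max(1, abs(f0)))) opt$convergence <- 0L
  }
  opt
}

#' Akaike information criterion of a fitted model
#'
#' AIC = 2k - 2 logL, where k counts the variance parameters of the model
#' (2 for the plain animal model, 3 with a litter effect, 6/9 for bivariate
#' fits); fixed effects are identical across the models being compared so
#' they cancel in AIC differences.
#'
#' @param fit a `fit_result`.
#' @return scalar AIC.
#' @export
aic <- function(fit) {
  stopifnot(!is.null(fit$loglik), !is.null(fit$k))
  2 * fit$k - 2 * fit$loglik
}

#' @export
print.fit_result <- function(x, ...) {
  cc <- x$components
  cat("REML fit:", if (length(x$trait) > 1) paste(x$trait, collapse = " & ")
      else x$trait,
      "|", if (!is.null(cc$sigma_c2) || !is.null(cc$litter)) "litter model"
      else "plain animal model", "\n")
  if (!is.null(cc$sigma_a2) && is.numeric(cc$sigma_a2) && length(cc$sigma_a2) == 1) {
    cat(sprintf("  sigma_a2 = %.6g  ", cc$sigma_a2))
    if (!is.null(cc$sigma_c2)) cat(sprintf("sigma_c2 = %.6g  ", cc$sigma_c2))
    cat(sprintf("sigma_e2 = %.6g\n", cc$sigma_e2))
  }
  cat(sprintf("  logL = %.4f  k = %d  AIC = %.4f  converged = %s (%d iter)\n",
              x$loglik, x$k, x$aic, x$converged, x$iterations))
  invisible(x)
}
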