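# Henderson's mixed-model equations, assembled in "lambda" form:
#   [ X'X        X'Z_a              X'Z_c        ] [b]   [X'y ]
#   [ Z_a'X      Z_a'Z_a + Ainv*la  Z_a'Z_c      ] [a] = [Za'y]
#   [ Z_c'X      Z_c'Z_a            Z_c'Z_c + I*lc] [c]   [Zc'y]
# with la = sigma_e2/sigma_a2, lc = sigma_e2/sigma_c2. Solutions equal those
# of the unscaled (R-inverse) system; determinants are related by the scale.

# Precompute the variance-free pieces so the REML iteration only rescales
# the A-inverse and litter augmentations.
mme_skeleton <- function(design, ainv) {
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Za <- design$Z_a
  Zc <- design$Z_c
  W <- if (is.null(Zc)) cbind(X, Za) else cbind(X, Za, Zc)
  C0 <- Matrix::crossprod(W)
  p <- ncol(X); qa <- ncol(Za); qc <- if (is.null(Zc)) 0L else ncol(Zc)
  zp <- function(k) Matrix::Matrix(0, k, k, sparse = TRUE)
  aug_a <- Matrix::bdiag(zp(p), ainv, zp(qc))
  aug_c <- if (qc > 0) Matrix::bdiag(zp(p + qa), Matrix::Diagonal(qc)) else NULL
  list(C0 = Matrix::forceSymmetric(C0),
       aug_a = Matrix::forceSymmetric(aug_a),
       aug_c = if (!is.null(aug_c)) Matrix::forceSymmetric(aug_c),
       rhs = as.numeric(Matrix::crossprod(W, design$y)),
       yty = sum(design$y^2),
       p = p, qa = qa, qc = qc, n = design$n,
       log_det_A = attr(ainv, "log_det_A"),
       blocks = list(fixed = seq_len(p),
                     additive = p + seq_len(qa),
                     litter = if (qc > 0) p + qa + seq_len(qc)),
       labels = design$labels)
}

mme_coef <- function(skel, lambda_a, lambda_c = NULL) {
  C <- skel$C0 + lambda_a * skel$aug_a
  if (!is.null(skel$aug_c)) {
    stopifnot(!is.null(lambda_c))
    C <- C + lambda_c * skel$aug_c
  }
  Matrix::forceSymmetric(C)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side of the mixed-model
#' equations for the supplied design and variance components, in the
#' variance-ratio ("lambda") form.
#'
#' @param design a `design` from [build_design].
#' @param ainv sparse A-inverse from [build_a_inverse] (full pedigree).
#' @param vc list with strictly positive `sigma_a2`, `sigma_e2`, and
#'   `sigma_c2` when the design carries a litter incidence matrix.
#' @return list of class `mme`: `C` (sparse symmetric coefficient matrix),
#'   `rhs`, `blocks` (index sets of the fixed/additive/litter equations),
#'   `labels`, and the variance ratios used.
#' @export
build_mme <- function(design, ainv, vc) {
  if (is.null(vc$sigma_a2) || vc$sigma_a2 <= 0 || vc$sigma_e2 <= 0)
    stop("variance components must be strictly positive")
  has_c <- !is.null(design$Z_c)
  if (has_c && (is.null(vc$sigma_c2) || vc$sigma_c2 <= 0))
    stop("litter design present but sigma_c2 missing or non-positive")
  skel <- mme_skeleton(design, ainv)
  la <- vc$sigma_e2 / vc$sigma_a2
  lc <- if (has_c) vc$sigma_e2 / vc$sigma_c2 else NULL
  structure(list(C = mme_coef(skel, la, lc), rhs = skel$rhs,
                 blocks = skel$blocks, labels = skel$labels,
                 lambda_a = la, lambda_c = lc, skel = skel),
            class = "mme")
}

#' Solve the mixed-model equations
#'
#' Sparse Cholesky solve of an assembled system; returns labeled BLUE/BLUP
#' solutions.
#'
#' @param sys an `mme` from [build_mme].
#' @return list: `b` (fixed-effect solutions, named), `a` (breeding values,
#'   named by animal), `c` (litter solutions or NULL), `solution` (the full
#'   stacked vector).
#' @export
solve_blup <- function(sys) {
  ch <- tryCatch(Matrix::Cholesky(sys$C, LDL = FALSE, perm = TRUE),
                 error = function(e) stop("MME coefficient matrix not positive definite: ",
                                          conditionMessage(e)))
  sol <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
  b <- stats::setNames(sol[sys$blocks$fixed], sys$labels$fixed)
  a <- stats::setNames(sol[sys$blocks$additive], sys$labels$additive)
  cc <- if (!is.null(sys$blocks$litter))
    stats::setNames(sol[sys$blocks$litter], sys$labels$litter)
  list(b = b, a = a, c = cc, solution = sol)
}

# log-determinant of a sparse symmetric PD matrix via its Cholesky factor
chol_logdet <- function(ch) {
  as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
}

#' Restricted log-likelihood of an animal model
#'
#' Evaluates the REML log-likelihood (including the -(n-p)/2 log(2*pi)
#' constant) at the supplied variance components, through the sparse
#' mixed-model factorization by default, or through the dense
#' variance-matrix formula -1/2 [log|V| + log|X'V^-1 X| + y'Py] for small
#' cross-checks.
#'
#' @param vc list with `sigma_a2`, `sigma_e2`, and `sigma_c2` if the design
#'   has litters.
#' @param design a `design` from [build_design].
#' @param ainv sparse A-inverse (with `log_det_A` attribute).
#' @param method `"sparse"` (MME route) or `"dense"` (explicit V, for
#'   pedigrees small enough to invert densely).
#' @return scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(vc, design, ainv, method = c("sparse", "dense")) {
  method <- match.arg(method)
  has_c <- !is.null(design$Z_c)
  if (method == "dense") {
    A <- solve(as.matrix(ainv))
    V <- design$Z_a %*% A %*% Matrix::t(design$Z_a) * vc$sigma_a2
    if (has_c)
      V <- V + Matrix::tcrossprod(design$Z_c) * vc$sigma_c2
    V <- as.matrix(V) + diag(vc$sigma_e2, design$n)
    X <- design$X
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    yPy <- as.numeric(t(design$y) %*% P %*% design$y)
    return(-0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
                   determinant(XtViX, logarithm = TRUE)$modulus[1] + yPy) -
           0.5 * (design$n - ncol(X)) * log(2 * pi))
  }
  skel <- mme_skeleton(design, ainv)
  la <- vc$sigma_e2 / vc$sigma_a2
  lc <- if (has_c) vc$sigma_e2 / vc$sigma_c2
  loglik_lambda(skel, la, lc, sigma_e2 = vc$sigma_e2)$loglik
}

# Core evaluation in lambda form. When sigma_e2 is NULL it is profiled out
# (its REML maximizer ype/(n-p) is substituted).
loglik_lambda <- function(skel, lambda_a, lambda_c = NULL, sigma_e2 = NULL,
                          chol_template = NULL) {
  C <- mme_coef(skel, lambda_a, lambda_c)
  ch <- if (is.null(chol_template)) Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
        else Matrix::update(chol_template, C)
  sol <- as.numeric(Matrix::solve(ch, skel$rhs, system = "A"))
  ype <- skel$yty - sum(sol * skel$rhs)
  np <- skel$n - skel$p
  if (ype <= 0) return(list(loglik = -Inf, sol = sol, sigma_e2 = NA_real_, chol = ch))
  se2 <- if (is.null(sigma_e2)) ype / np else sigma_e2
  m2ll <- np * log(se2) + skel$log_det_A - skel$qa * log(lambda_a) +
    chol_logdet(ch) + ype / se2 + np * log(2 * pi)
  if (!is.null(lambda_c)) m2ll <- m2ll - skel$qc * log(lambda_c)
  list(loglik = -0.5 * m2ll, sol = sol, sigma_e2 = se2, chol = ch, ype = ype)
}
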