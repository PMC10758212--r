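# Bivariate animal model. Effects are stacked trait-major:
#   y = [y1; y2],  b = [b1; b2],  a = [a1; a2] ~ N(0, G0 (x) A),
#   c = [c1; c2] ~ N(0, C0 (x) I),  e ~ N(0, R) with per-record residual
# blocks: a 2x2 block R0 for animals measured on both traits, a scalar
# R0[t,t] otherwise (so the residual covariance contributes only to
# doubly-measured records).

# pairing/bookkeeping shared by the likelihood and the AI matrix
bivariate_skeleton <- function(design1, design2, ainv) {
  n1 <- design1$n; n2 <- design2$n
  q <- ncol(design1$Z_a)
  both <- intersect(design1$animal, design2$animal)
  i1 <- match(both, design1$animal)        # rows in trait-1 block
  i2 <- n1 + match(both, design2$animal)   # rows in stacked trait-2 block
  only1 <- setdiff(seq_len(n1), i1)
  only2 <- setdiff(n1 + seq_len(n2), i2)

  X <- Matrix::bdiag(Matrix::Matrix(design1$X, sparse = TRUE),
                     Matrix::Matrix(design2$X, sparse = TRUE))
  Za <- Matrix::bdiag(design1$Z_a, design2$Z_a)
  has_c <- !is.null(design1$Z_c) && !is.null(design2$Z_c)
  Zc <- NULL; nl <- 0L
  if (has_c) {
    lev <- sort(union(colnames(design1$Z_c), colnames(design2$Z_c)))
    nl <- length(lev)
    expand <- function(Z) {
      T <- methods::as(Z, "TsparseMatrix")
      Matrix::sparseMatrix(i = T@i + 1L, j = match(colnames(Z), lev)[T@j + 1L],
                           x = T@x, dims = c(nrow(Z), nl),
                           dimnames = list(NULL, lev))
    }
    Zc <- Matrix::bdiag(expand(design1$Z_c), expand(design2$Z_c))
  }
  T <- if (has_c) cbind(X, Za, Zc) else cbind(X, Za)
  p <- ncol(X)
  # T' R^-1 T, T' R^-1 y and y' R^-1 y are linear in the five distinct
  # entries of the per-record residual precision; precompute their bases
  y <- c(design1$y, design2$y)
  Tb1 <- T[i1, , drop = FALSE]; Tb2 <- T[i2, , drop = FALSE]
  To1 <- T[only1, , drop = FALSE]; To2 <- T[only2, , drop = FALSE]
  cross12 <- Matrix::crossprod(Tb1, Tb2)
  m <- ncol(T)
  nl_ <- if (has_c) length(lev) else 0L
  q_ <- ncol(design1$Z_a)
  embed_block <- function(M, roff, coff) {
    # place a q x q sparse block into an m x m matrix at (roff, coff)
    Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    Matrix::sparseMatrix(i = Tm@i + 1L + roff, j = Tm@j + 1L + coff,
                         x = Tm@x, dims = c(m, m))
  }
  pq <- p; q2 <- q_
  Cmats <- list(b11 = Matrix::crossprod(Tb1), b22 = Matrix::crossprod(Tb2),
                b12 = cross12 + Matrix::t(cross12),
                o1 = Matrix::crossprod(To1), o2 = Matrix::crossprod(To2),
                g11 = embed_block(ainv, pq, pq),
                g22 = embed_block(ainv, pq + q2, pq + q2),
                g12 = embed_block(ainv, pq, pq + q2) +
                      embed_block(ainv, pq + q2, pq))
  if (has_c) {
    I_l <- Matrix::Diagonal(nl_)
    co <- pq + 2L * q2
    Cmats$c11 <- embed_block(I_l, co, co)
    Cmats$c22 <- embed_block(I_l, co + nl_, co + nl_)
    Cmats$c12 <- embed_block(I_l, co, co + nl_) +
                 embed_block(I_l, co + nl_, co)
  }
  bases <- list(
    C = lincomb_template(Cmats, m),
    rhs = list(b11 = as.numeric(Matrix::crossprod(Tb1, y[i1])),
               b22 = as.numeric(Matrix::crossprod(Tb2, y[i2])),
               b12 = as.numeric(Matrix::crossprod(Tb1, y[i2]) +
                                Matrix::crossprod(Tb2, y[i1])),
               o1 = as.numeric(Matrix::crossprod(To1, y[only1])),
               o2 = as.numeric(Matrix::crossprod(To2, y[only2]))),
    yy = list(b11 = sum(y[i1]^2), b22 = sum(y[i2]^2),
              b12 = 2 * sum(y[i1] * y[i2]),
              o1 = sum(y[only1]^2), o2 = sum(y[only2]^2)))
  list(y = y, T = T, X = X, Za = Za, Zc = Zc, bases = bases,
       n = n1 + n2, n1 = n1, n2 = n2, p = p, q = q, nl = nl,
       i1 = i1, i2 = i2, only1 = only1, only2 = only2,
       has_c = has_c, log_det_A = attr(ainv, "log_det_A"), ainv = ainv,
       cache = new.env(parent = emptyenv()),
       blocks = list(fixed = seq_len(p),
                     additive = p + seq_len(2L * q),
                     litter = if (has_c) p + 2L * q + seq_len(2L * nl)),
       traits = c(design1$trait, design2$trait),
       fingerprint = paste(data_fingerprint(design1),
                           data_fingerprint(design2), sep = "|"))
}

# Precompute a shared symmetric sparsity template for a set of symmetric
# sparse matrices, so weighted sums reduce to arithmetic on the x slot.
lincomb_template <- function(mats, n) {
  trip <- lapply(mats, function(M) {
    Tm <- methods::as(Matrix::forceSymmetric(methods::as(M, "CsparseMatrix")),
                      "TsparseMatrix")  # upper triangle
    ord <- order(as.double(Tm@j) * n + Tm@i)
    list(key = (as.double(Tm@j) * n + Tm@i)[ord], x = Tm@x[ord])
  })
  allkey <- sort(unique(unlist(lapply(trip, `[[`, "key"))))
  i <- as.integer(allkey %% n)
  j <- as.integer(allkey %/% n)
  tmpl <- methods::new("dsCMatrix", i = i,
                       p = c(0L, cumsum(tabulate(j + 1L, nbins = n))),
                       x = numeric(length(allkey)),
                       Dim = c(n, n), uplo = "U")
  list(tmpl = tmpl,
       idx = lapply(trip, function(t) match(t$key, allkey)),
       vals = lapply(trip, `[[`, "x"))
}

# weighted sum over the template; w is a named vector matching the bases
lincomb_eval <- function(lc, w) {
  x <- numeric(length(lc$tmpl@x))
  for (nm in names(w)) {
    if (w[[nm]] == 0) next
    k <- lc$idx[[nm]]
    x[k] <- x[k] + w[[nm]] * lc$vals[[nm]]
  }
  out <- lc$tmpl
  out@x <- x
  out
}

# sparse R-inverse for a residual covariance matrix R0
residual_inverse <- function(skel, R0) {
  iv <- solve(R0)
  i <- c(skel$only1, skel$only2, skel$i1, skel$i2, skel$i1, skel$i2)
  j <- c(skel$only1, skel$only2, skel$i1, skel$i2, skel$i2, skel$i1)
  x <- c(rep(1 / R0[1, 1], length(skel$only1)),
         rep(1 / R0[2, 2], length(skel$only2)),
         rep(iv[1, 1], length(skel$i1)), rep(iv[2, 2], length(skel$i2)),
         rep(iv[1, 2], length(skel$i1)), rep(iv[2, 1], length(skel$i2)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(skel$n, skel$n))
}

log_det_R <- function(skel, R0) {
  length(skel$i1) * as.numeric(determinant(R0, logarithm = TRUE)$modulus) +
    length(skel$only1) * log(R0[1, 1]) + length(skel$only2) * log(R0[2, 2])
}

# assemble, factorize and evaluate -2 logL at (G0, C0, R0).
# The nonzero pattern of the coefficient matrix is constant across
# iterations, so the symbolic analysis is cached in `skel$cache` and only
# the numeric factorization is redone.
bivariate_loglik <- function(skel, G0, C0, R0, with_rinv = FALSE) {
  iv <- solve(R0)
  wr <- c(b11 = iv[1, 1], b22 = iv[2, 2], b12 = iv[1, 2],
          o1 = 1 / R0[1, 1], o2 = 1 / R0[2, 2])
  Gi <- solve(G0)
  w <- c(wr, g11 = Gi[1, 1], g22 = Gi[2, 2], g12 = Gi[1, 2])
  if (skel$has_c) {
    Ci <- solve(C0)
    w <- c(w, c11 = Ci[1, 1], c22 = Ci[2, 2], c12 = Ci[1, 2])
  }
  C <- lincomb_eval(skel$bases$C, w)
  rhs <- as.numeric(Reduce(`+`, Map(`*`, as.list(wr),
                                    skel$bases$rhs[names(wr)])))
  yRy <- sum(unlist(skel$bases$yy[names(wr)]) * wr)
  ch <- NULL
  if (!is.null(skel$cache) && !is.null(skel$cache$chol))
    ch <- tryCatch(Matrix::update(skel$cache$chol, C),
                   error = function(e) NULL)
  if (is.null(ch)) {
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    if (!is.null(skel$cache)) skel$cache$chol <- ch
  }
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  ypy <- yRy - sum(sol * rhs)
  m2ll <- log_det_R(skel, R0) +
    skel$q * as.numeric(determinant(G0, logarithm = TRUE)$modulus) +
    2 * skel$log_det_A +
    (if (skel$has_c) skel$nl * as.numeric(determinant(C0, logarithm = TRUE)$modulus) else 0) +
    chol_logdet(ch) + ypy + (skel$n - skel$p) * log(2 * pi)
  list(loglik = -0.5 * m2ll, sol = sol, chol = ch,
       Rinv = if (with_rinv) residual_inverse(skel, R0))
}

kron2 <- function(M2, S) {
  # kronecker of a dense 2x2 with a sparse q x q, trait-major ordering
  rbind(cbind(M2[1, 1] * S, M2[1, 2] * S),
        cbind(M2[2, 1] * S, M2[2, 2] * S))
}

# log-Cholesky (un)packing: theta = (log l11, l21, log l22) <-> SPD 2x2
theta_to_cov <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  L %*% t(L)
}
cov_to_theta <- function(M) {
  L <- t(chol(M))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

#' Bivariate REML fit
#'
#' Estimates the full 2x2 genetic (and litter, if modeled) and residual
#' (co)variance matrices of a two-trait animal model by direct maximization
#' of the restricted log-likelihood, with each covariance matrix kept
#' positive definite through a log-Cholesky parameterization. Records
#' missing one trait contribute only their measured trait; the residual
#' covariance enters only for animals measured on both.
#'
#' @param design1,design2 single-trait designs from [build_design] over the
#'   same pedigree (and same litter coding when the model has litters).
#' @param ainv sparse A-inverse over the full pedigree.
#' @param model a [model_spec] with two traits.
#' @param init optional list with 2x2 matrices `gen`, `lit`, `res`; by
#'   default diagonals come from single-trait REML fits and covariances
#'   start at zero.
#' @return `fit_result` whose `components` hold matrices `gen`, `lit`
#'   (NULL for the plain model), `res`, plus `cov` (asymptotic covariance of
#'   the stacked distinct elements, order g11,g12,g22[,c11,c12,c22],r11,r12,r22).
#' @export
reml_fit_bivariate <- function(design1, design2, ainv, model, init = NULL) {
  skel <- bivariate_skeleton(design1, design2, ainv)
  if (!length(skel$i1))
    stop("no animal measured for both traits; covariances unidentifiable")
  has_c <- skel$has_c
  if (isTRUE(model$include_litter) && !has_c)
    stop("model includes litter effect but designs lack Z_c")

  if (is.null(init)) {
    f1 <- reml_fit(design1, ainv, model_spec(design1$trait, model$fixed_factors,
                                             include_litter = has_c))
    f2 <- reml_fit(design2, ainv, model_spec(design2$trait, model$fixed_factors,
                                             include_litter = has_c))
    # warm-start covariances from the OLS-residual correlation of
    # doubly-measured records, applied to every component
    r1 <- stats::lm.fit(design1$X, design1$y)$residuals
    r2 <- stats::lm.fit(design2$X, design2$y)$residuals
    r0 <- stats::cor(r1[match(intersect(design1$animal, design2$animal),
                              design1$animal)],
                     r2[match(intersect(design1$animal, design2$animal),
                              design2$animal)])
    if (!is.finite(r0)) r0 <- 0
    r0 <- max(min(r0, 0.9), -0.9)
    mk <- function(v1, v2) matrix(c(v1, r0 * sqrt(v1 * v2),
                                    r0 * sqrt(v1 * v2), v2), 2, 2)
    init <- list(gen = mk(f1$components$sigma_a2, f2$components$sigma_a2),
                 lit = if (has_c) mk(f1$components$sigma_c2,
                                     f2$components$sigma_c2),
                 res = mk(f1$components$sigma_e2, f2$components$sigma_e2))
  }
  theta0 <- c(cov_to_theta(init$gen),
              if (has_c) cov_to_theta(init$lit),
              cov_to_theta(init$res))
  unpack <- function(theta) {
    G0 <- theta_to_cov(theta[1:3])
    C0 <- if (has_c) theta_to_cov(theta[4:6])
    R0 <- theta_to_cov(theta[(length(theta) - 2):length(theta)])
    list(G0 = G0, C0 = C0, R0 = R0)
  }
  negll <- function(theta) {
    m <- unpack(theta)
    ll <- tryCatch(bivariate_loglik(skel, m$G0, m$C0, m$R0)$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  np <- length(theta0)
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  diag_pos <- c(1, 3, if (has_c) c(4, 6), np - 2, np)
  lower[diag_pos] <- -12; upper[diag_pos] <- 20
  opt <- nlminb_restarted(theta0, negll, lower = lower, upper = upper,
                          iter.max = model$max_iter,
                          rel.tol = min(model$tol, 1e-10))
  m <- unpack(opt$par)
  final <- bivariate_loglik(skel, m$G0, m$C0, m$R0, with_rinv = TRUE)
  dn <- list(skel$traits, skel$traits)
  dimnames(m$G0) <- dn; dimnames(m$R0) <- dn
  if (has_c) dimnames(m$C0) <- dn

  ai <- bivariate_ai(skel, m, final)
  cov <- tryCatch(solve(ai), error = function(e) {
    warning("average-information matrix singular; SEs unavailable")
    matrix(NA_real_, nrow(ai), ncol(ai), dimnames = dimnames(ai))
  })

  k <- if (has_c) 9L else 6L
  sol <- final$sol
  fit <- list(components = list(gen = m$G0, lit = m$C0, res = m$R0, cov = cov),
              loglik = final$loglik, k = k, aic = 2 * k - 2 * final$loglik,
              converged = opt$convergence == 0 && opt$iterations < model$max_iter,
              iterations = opt$iterations, message = opt$message,
              ai_matrix = ai,
              solutions = list(
                b = sol[skel$blocks$fixed],
                a = matrix(sol[skel$blocks$additive], ncol = 2,
                           dimnames = list(design1$labels$additive, skel$traits)),
                c = if (has_c) matrix(sol[skel$blocks$litter], ncol = 2)),
              blocks = skel$blocks,
              model = model, trait = skel$traits, n = skel$n,
              fingerprint = skel$fingerprint)
  class(fit) <- "fit_result"
  fit
}

# AI matrix on the covariance-element scale (g11,g12,g22[,c...],r11,r12,r22):
# V is linear in each element, so AI_kl = f_k' P f_l / 2 with f_k = dV/dtheta_k Py.
bivariate_ai <- function(skel, m, final) {
  Py <- as.numeric(final$Rinv %*% (skel$y - skel$T %*% final$sol))
  q <- skel$q; nl <- skel$nl; has_c <- skel$has_c

  Pvec <- function(x) {
    rhs <- as.numeric(Matrix::crossprod(skel$T, final$Rinv %*% x))
    s <- as.numeric(Matrix::solve(final$chol, rhs, system = "A"))
    as.numeric(final$Rinv %*% (x - skel$T %*% s))
  }
  S <- list(`11` = matrix(c(1, 0, 0, 0), 2),
            `12` = matrix(c(0, 1, 1, 0), 2),
            `22` = matrix(c(0, 0, 0, 1), 2))
  kron_mult <- function(Smat, v, solve_A) {
    v1 <- v[seq_len(length(v) / 2)]; v2 <- v[-seq_len(length(v) / 2)]
    a1 <- if (solve_A) as.numeric(Matrix::solve(skel$ainv, v1)) else v1
    a2 <- if (solve_A) as.numeric(Matrix::solve(skel$ainv, v2)) else v2
    c(Smat[1, 1] * a1 + Smat[1, 2] * a2, Smat[2, 1] * a1 + Smat[2, 2] * a2)
  }
  fs <- list()
  va <- as.numeric(Matrix::crossprod(skel$Za, Py))
  for (nm in names(S))
    fs[[paste0("g", nm)]] <- as.numeric(skel$Za %*% kron_mult(S[[nm]], va, TRUE))
  if (has_c) {
    vc <- as.numeric(Matrix::crossprod(skel$Zc, Py))
    for (nm in names(S))
      fs[[paste0("c", nm)]] <- as.numeric(skel$Zc %*% kron_mult(S[[nm]], vc, FALSE))
  }
  # residual elements act record-wise
  r11 <- numeric(skel$n); r11[c(skel$only1, skel$i1)] <- Py[c(skel$only1, skel$i1)]
  r22 <- numeric(skel$n); r22[c(skel$only2, skel$i2)] <- Py[c(skel$only2, skel$i2)]
  r12 <- numeric(skel$n); r12[skel$i1] <- Py[skel$i2]; r12[skel$i2] <- Py[skel$i1]
  fs$r11 <- r11; fs$r12 <- r12; fs$r22 <- r22

  Pf <- lapply(fs, Pvec)
  k <- length(fs)
  ai <- matrix(0, k, k, dimnames = list(names(fs), names(fs)))
  for (i in seq_len(k))
    for (j in i:k)
      ai[i, j] <- ai[j, i] <- 0.5 * sum(fs[[i]] * Pf[[j]])
  ai
}
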