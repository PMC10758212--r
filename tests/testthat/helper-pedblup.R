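# Shared fixtures, built in code.

# Random pedigree with founders, one-parent and two-parent animals.
# Parents are drawn from earlier animals so the input is always acyclic.
random_pedigree <- function(n, seed, n_founders = max(4L, round(n / 5)),
                            p_one_parent = 0.1, p_unknown = 0.05) {
  set.seed(seed)
  animal <- sprintf("A%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    u <- stats::runif(1)
    pool <- seq_len(i - 1L)
    if (u < p_unknown) next
    picks <- sample(pool, min(2L, length(pool)))
    if (u < p_unknown + p_one_parent || length(picks) < 2) {
      sire[i] <- animal[picks[1]]
    } else {
      sire[i] <- animal[picks[1]]
      dam[i] <- animal[picks[2]]
    }
  }
  pedigree(animal, sire, dam,
           birth_year = 2012L + (seq_len(n) - 1L) %/% max(1L, n %/% 6L))
}

# small phenotype table over founders of a pedigree
founder_records <- function(ids, y, litter = NA_character_) {
  data.frame(animal = ids, litter = litter, y = y, stringsAsFactors = FALSE)
}

# dense GLS-based BLUP oracle: V = Za A Za' sa2 + Zc Zc' sc2 + I se2
gls_blup <- function(design, A, vc) {
  n <- design$n
  V <- as.matrix(design$Z_a %*% A %*% Matrix::t(design$Z_a)) * vc$sigma_a2
  if (!is.null(design$Z_c) && !is.null(vc$sigma_c2))
    V <- V + as.matrix(Matrix::tcrossprod(design$Z_c)) * vc$sigma_c2
  V <- V + diag(vc$sigma_e2, n)
  Vi <- solve(V)
  X <- design$X
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% design$y)
  resid <- design$y - X %*% b
  a <- vc$sigma_a2 * A %*% Matrix::t(design$Z_a) %*% Vi %*% resid
  cc <- if (!is.null(design$Z_c) && !is.null(vc$sigma_c2))
    vc$sigma_c2 * Matrix::t(design$Z_c) %*% Vi %*% resid
  list(b = as.numeric(b), a = as.numeric(a),
       c = if (!is.null(cc)) as.numeric(cc))
}

# quick single-trait design over a simulated herd
herd_design <- function(sim, trait = "AGE", factors = c("farm", "sex"),
                        include_litter = TRUE) {
  build_design(sim$pheno, model_spec(trait, factors, include_litter), sim$ped)
}
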