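#' Construct a validated, topologically sorted pedigree
#'
#' Builds a `pedigree` object from parallel vectors of animal, sire and dam
#' identifiers. Parents that never appear as animals are auto-registered as
#' founders (with a warning giving the count). Records are re-ordered so that
#' every known parent precedes its offspring; a cycle (an animal that is its
#' own ancestor) is a structural error.
#'
#' @param animal character vector of unique animal ids.
#' @param sire,dam character vectors of parent ids; `NA` or the missing token
#'   means unknown.
#' @param birth_year optional integer vector of birth years.
#' @param sex optional character vector (`"M"`/`"F"`).
#' @param litter optional character vector of litter codes (dam id + birth
#'   period by convention); `NA` means unknown.
#' @param missing token in `sire`/`dam` denoting an unknown parent
#'   (default `"0"`), in addition to `NA` and the empty string.
#' @return An object of class `pedigree`: a data.frame with columns
#'   `animal`, `sire`, `dam`, `birth_year`, `sex`, `litter` (parents `NA`
#'   when unknown), rows in topological order, plus attributes
#'   `id_index` (named integer map id -> row) and integer parent position
#'   vectors `sire_pos`/`dam_pos` (0 = unknown).
#' @export
pedigree <- function(animal, sire, dam, birth_year = NULL, sex = NULL,
                     litter = NULL, missing = "0") {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  stopifnot(length(sire) == length(animal), length(dam) == length(animal))
  if (any(is.na(animal) | animal == ""))
    stop("animal ids must be nonempty")
  if (anyDuplicated(animal))
    stop("duplicate animal ids: ", paste(unique(animal[duplicated(animal)])[1:3], collapse = ", "))
  unk <- function(x) ifelse(is.na(x) | x %in% c(missing, ""), NA_character_, x)
  sire <- unk(sire)
  dam <- unk(dam)
  if (any(animal == sire & !is.na(sire)) || any(animal == dam & !is.na(dam)))
    stop("animal listed as its own parent: ",
         animal[which((animal == sire & !is.na(sire)) | (animal == dam & !is.na(dam)))[1]])

  n0 <- length(animal)
  extra <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(extra)) {
    warning(length(extra), " parent id(s) not declared as animals; auto-registered as founders")
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  pad <- function(x, default = NA) {
    if (is.null(x)) return(rep(default, length(animal)))
    c(x, rep(default, length(animal) - length(x)))
  }
  birth_year <- as.integer(pad(birth_year, NA_integer_))
  sex <- as.character(pad(sex, NA_character_))
  litter <- as.character(pad(litter, NA_character_))

  df <- data.frame(animal = animal, sire = sire, dam = dam,
                   birth_year = birth_year, sex = sex, litter = litter,
                   stringsAsFactors = FALSE)
  df <- sort_pedigree(df)

  idx <- seq_len(nrow(df))
  names(idx) <- df$animal
  attr(df, "id_index") <- idx
  attr(df, "sire_pos") <- ifelse(is.na(df$sire), 0L, idx[df$sire])
  attr(df, "dam_pos") <- ifelse(is.na(df$dam), 0L, idx[df$dam])
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological sort: founders first, then animals whose parents are all
# placed; ties broken by original row order (stable and deterministic).
sort_pedigree <- function(df) {
  n <- nrow(df)
  pos <- seq_len(n)
  names(pos) <- df$animal
  sp <- ifelse(is.na(df$sire), 0L, pos[df$sire])
  dp <- ifelse(is.na(df$dam), 0L, pos[df$dam])
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  remaining <- seq_len(n)
  parent_ok <- function(p) p == 0L | placed[pmax(p, 1L)]
  while (length(remaining)) {
    ready <- remaining[parent_ok(sp[remaining]) & parent_ok(dp[remaining])]
    if (!length(ready))
      stop("pedigree cycle detected involving animal ", df$animal[remaining[1]])
    order_out[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    placed[ready] <- TRUE
    remaining <- remaining[!placed[remaining]]
  }
  out <- df[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree file (comma or tab, autodetected from the
#' header line) and returns a validated [pedigree]. Column names are mapped
#' through `dialect`.
#'
#' @param path path to a delimited text file with a header.
#' @param dialect named list mapping roles to column names; defaults are
#'   `animal`, `sire`, `dam`, `birth_year`, `sex`, `litter` (the last three
#'   optional). Element `missing` sets the unknown-parent token (default "0").
#' @return A [pedigree].
#' @export
read_pedigree <- function(path, dialect = list()) {
  d <- utils::modifyList(
    list(animal = "animal", sire = "sire", dam = "dam",
         birth_year = "birth_year", sex = "sex", litter = "litter",
         missing = "0"),
    dialect)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  need <- c("animal", "sire", "dam")
  miss <- need[!vapply(need, function(r) d[[r]] %in% names(raw), TRUE)]
  if (length(miss))
    stop("pedigree file lacks required column(s): ",
         paste(unlist(d[miss]), collapse = ", "))
  opt <- function(role) if (d[[role]] %in% names(raw)) raw[[d[[role]]]] else NULL
  by <- opt("birth_year")
  pedigree(raw[[d$animal]], raw[[d$sire]], raw[[d$dam]],
           birth_year = if (!is.null(by)) as.integer(by) else NULL,
           sex = opt("sex"), litter = opt("litter"), missing = d$missing)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Write a pedigree to delimited text
#'
#' @param ped a [pedigree].
#' @param path output file path.
#' @param sep field separator.
#' @param missing token written for unknown parents.
#' @export
write_pedigree <- function(ped, path, sep = ",", missing = "0") {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- missing
  out$dam[is.na(out$dam)] <- missing
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient F of every animal by the
#' Meuwissen-Luo recursive algorithm (exact; equals `diag(A) - 1` of the
#' numerator relationship matrix). Animals with any unknown parent have
#' F = 0 (unknown parents are treated as unrelated, non-inbred base animals).
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  res <- ml_inbreeding(attr(ped, "sire_pos"), attr(ped, "dam_pos"))
  stats::setNames(res$F, ped$animal)
}

# Mendelian sampling variance ratios d_i (within-family variance / sigma_a^2);
# log|A| = sum(log(d)).
mendelian_ratios <- function(ped) {
  ml_inbreeding(attr(ped, "sire_pos"), attr(ped, "dam_pos"))$D
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds the full additive relationship matrix A by the tabular method:
#' a(i,j) = (a(j,s_i) + a(j,d_i))/2 for j earlier than i, and
#' a(i,i) = 1 + a(s_i,d_i)/2, with unknown parents contributing 0.
#' Intended as a small-scale oracle; use [build_a_inverse] for model fitting.
#'
#' @param ped a [pedigree].
#' @param cap maximum pedigree size accepted (guards against accidental
#'   dense allocation for large herds).
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @export
build_a_dense <- function(ped, cap = 5000L) {
  n <- nrow(ped)
  if (n > cap)
    stop("pedigree has ", n, " animals, above the dense cap (", cap,
         "); use the sparse inverse instead")
  sp <- attr(ped, "sire_pos")
  dp <- attr(ped, "dam_pos")
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[s, j]
      if (d > 0L) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules, accounting for inbreeding:
#' for animal i with Mendelian sampling variance ratio d_i, b_i = 1/d_i is
#' added at (i,i), -b_i/2 at (i,parent) and b_i/4 between known parents.
#'
#' @param ped a [pedigree].
#' @param F inbreeding coefficients from [compute_inbreeding]; recomputed
#'   when `NULL`. Supplied values are validated for length.
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) with attribute
#'   `log_det_A` = log-determinant of A (= sum(log d_i)).
#' @export
build_a_inverse <- function(ped, F = NULL) {
  n <- nrow(ped)
  if (!is.null(F) && length(F) != n)
    stop("F has length ", length(F), " but pedigree has ", n, " animals")
  D <- mendelian_ratios(ped)
  b <- 1 / D
  sp <- attr(ped, "sire_pos")
  dp <- attr(ped, "dam_pos")

  ii <- seq_len(n)
  hs <- sp > 0L; hd <- dp > 0L
  both <- hs & hd
  # each rule entry once; off-diagonal entries are mirrored afterwards
  tri_i <- c(ii, sp[hs], dp[hd], ii[hs], ii[hd], sp[both])
  tri_j <- c(ii, sp[hs], dp[hd], sp[hs], dp[hd], dp[both])
  tri_x <- c(b, b[hs] / 4, b[hd] / 4, -b[hs] / 2, -b[hd] / 2, b[both] / 4)
  off <- tri_i != tri_j
  Ainv <- Matrix::sparseMatrix(i = c(tri_i, tri_j[off]),
                               j = c(tri_j, tri_i[off]),
                               x = c(tri_x, tri_x[off]),
                               dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "log_det_A") <- sum(log(D))
  Ainv
}

#' Pedigree relationship structure
#'
#' Convenience wrapper bundling inbreeding coefficients, the sparse
#' A-inverse, its log-determinant, and (for small pedigrees) the dense A.
#'
#' @param ped a [pedigree].
#' @param dense_cap materialize dense A only when the pedigree has at most
#'   this many animals.
#' @return List with elements `F`, `a_inverse`, `log_det_A`, `a_dense`
#'   (NULL above the cap).
#' @export
relationship_structure <- function(ped, dense_cap = 300L) {
  F <- compute_inbreeding(ped)
  Ainv <- build_a_inverse(ped, F)
  list(F = F,
       a_inverse = Ainv,
       log_det_A = attr(Ainv, "log_det_A"),
       a_dense = if (nrow(ped) <= dense_cap) build_a_dense(ped) else NULL)
}

#' Export a sparse A-inverse as coordinate triplets
#'
#' Writes the lower triangle as `i j value` (1-based) for inspection or
#' exchange with other BLUP software.
#'
#' @param ainv sparse symmetric matrix from [build_a_inverse].
#' @param path output file path.
#' @export
write_ainv_triplets <- function(ainv, path) {
  T <- methods::as(Matrix::tril(ainv), "TsparseMatrix")
  utils::write.table(
    data.frame(i = T@i + 1L, j = T@j + 1L, value = T@x),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree: ", nrow(x), " animals (",
      sum(is.na(x$sire) & is.na(x$dam)), " founders), ",
      length(unique(stats::na.omit(x$litter))), " litters\n", sep = "")
  NextMethod()
}
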