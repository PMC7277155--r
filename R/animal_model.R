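#' Pedigree BLUP with known variance components
#'
#' Solves the single-trait mixed-model equations for
#' `y = X b + Z_a u + Z_l c + e` with fixed contemporary-group effects `b`,
#' additive animal effects `u ~ N(0, A sigma2_a)` over every pedigree animal,
#' common-litter effects `c ~ N(0, I sigma2_c)` (omitted when
#' `sigma2_c = 0`), and residuals `e ~ N(0, I sigma2_e)`. A-inverse comes
#' from [build_A_inverse()] (Henderson's rules with inbreeding). Reliability
#' is `r2_i = 1 - PEV_i / ((1 + F_i) sigma2_a)` with PEV from the inverse of
#' the coefficient matrix; the parent average is the mean of the parents'
#' EBVs with unknown parents contributing 0.
#'
#' @param phenotypes Tibble with `animal`, `value`, `cg` (contemporary
#'   group), and `litter` (needed when `sigma2_c > 0`); one record per animal.
#' @param pedigree Pedigree tibble, parents before offspring.
#' @param variances List with `sigma2_a`, `sigma2_e`, and optionally
#'   `sigma2_c` (default 0).
#' @param trait Trait label carried into the output (defaults to the
#'   phenotype table's `trait` column when present).
#' @return A tibble of class `ebv_table` with one row per pedigree animal:
#'   `animal`, `trait`, `ebv`, `reliability`, `pa`.
#' @export
solve_animal_model <- function(phenotypes, pedigree, variances, trait = NULL) {
  check_pedigree(pedigree)
  v <- variances
  if (is.null(v$sigma2_c)) v$sigma2_c <- 0
  if (any(c(v$sigma2_a, v$sigma2_e) <= 0) || v$sigma2_c < 0) {
    stop_input("variance components must be positive (sigma2_c may be 0)")
  }
  trait <- trait %||% (if ("trait" %in% names(phenotypes)) phenotypes$trait[1] else "trait")
  ids <- pedigree$animal
  rec <- match(phenotypes$animal, ids)
  if (anyNA(rec)) stop_input("phenotyped animals missing from the pedigree")

  nrec <- nrow(phenotypes)
  n <- length(ids)
  cg <- factor(phenotypes$cg)
  empty <- levels(cg)[tabulate(cg, nlevels(cg)) == 0]
  if (length(empty)) {
    stop_input("confounded contemporary groups (no records): ",
               paste(empty, collapse = ", "))
  }
  incidence <- function(fac, ncol_) {
    Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(fac), x = 1,
                         dims = c(nrec, ncol_))
  }
  X <- incidence(cg, nlevels(cg))
  Za <- Matrix::sparseMatrix(i = seq_len(nrec), j = rec, x = 1,
                             dims = c(nrec, n))
  use_litter <- v$sigma2_c > 0
  if (use_litter) {
    if (!"litter" %in% names(phenotypes)) {
      stop_input("`sigma2_c` > 0 requires a `litter` column")
    }
    lit <- factor(phenotypes$litter)
    Zl <- incidence(lit, nlevels(lit))
  }

  f <- inbreeding(pedigree)$f
  Ainv <- build_A_inverse(pedigree, f = f)
  la <- v$sigma2_e / v$sigma2_a
  y <- phenotypes$value

  W <- if (use_litter) cbind(X, Za, Zl) else cbind(X, Za)
  LHS <- Matrix::crossprod(W)
  ia <- ncol(X) + seq_len(n)
  LHS[ia, ia] <- LHS[ia, ia] + Ainv * la
  if (use_litter) {
    il <- ncol(X) + n + seq_len(ncol(Zl))
    LHS[il, il] <- LHS[il, il] + Matrix::Diagonal(ncol(Zl)) * (v$sigma2_e / v$sigma2_c)
  }
  RHS <- Matrix::crossprod(W, y)
  # dense inverse: PEV needs the diagonal of the inverted coefficient matrix
  Cinv <- solve(as.matrix(LHS))
  sol <- drop(Cinv %*% as.matrix(RHS))
  u <- sol[ia]
  pev <- diag(Cinv)[ia] * v$sigma2_e
  r2 <- pmin(1, pmax(0, 1 - pev / ((1 + f) * v$sigma2_a)))

  ebvs <- tibble(animal = ids, trait = trait, ebv = u, reliability = r2)
  ebvs$pa <- parent_average(pedigree, ebvs)$pa
  class(ebvs) <- c("ebv_table", class(ebvs))
  ebvs
}

#' Parent-average EBV
#'
#' `PA = (EBV_sire + EBV_dam) / 2`; an unknown parent contributes 0 (the
#' base-population mean).
#'
#' @param pedigree Pedigree tibble.
#' @param ebvs Tibble with `animal` and `ebv` covering all known parents.
#' @return Tibble with `animal`, `pa`.
#' @export
parent_average <- function(pedigree, ebvs) {
  e <- setNames(ebvs$ebv, as.character(ebvs$animal))
  get0 <- function(id) ifelse(id == 0L, 0, unname(e[as.character(id)]))
  es <- get0(pedigree$sire); ed <- get0(pedigree$dam)
  if (anyNA(es) || anyNA(ed)) stop_input("a known parent has no EBV")
  tibble(animal = pedigree$animal, pa = (es + ed) / 2)
}
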