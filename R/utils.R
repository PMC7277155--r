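#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a configuration/input error
#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

#' Allele frequency of the counted allele per marker (column)
#'
#' @param geno animals x markers matrix of 0/1/2 allele counts, `NA` missing.
#' @return Numeric vector of allele frequencies in `[0, 1]`, one per column.
#' @export
allele_freq <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

#' Minor allele frequency per marker
#'
#' @inheritParams allele_freq
#' @return Numeric vector of MAFs in `[0, 0.5]`.
#' @export
maf <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}

#' Center a genotype matrix by twice the allele frequency
#'
#' Standard centering for whole-genome regression: column `j` becomes
#' `Z[, j] - 2 p_j`. Frequencies may be supplied (e.g. training-set
#' frequencies when centering a validation set) to avoid information leakage.
#'
#' @inheritParams allele_freq
#' @param p Allele frequencies to center by; defaults to frequencies computed
#'   from `geno` itself.
#' @return A numeric matrix of the same dimensions; missing genotypes are
#'   replaced by the column mean (i.e. 0 after centering).
#' @export
center_genotypes <- function(geno, p = NULL) {
  p <- p %||% allele_freq(geno)
  Z <- sweep(geno, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0
  Z
}
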