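#' Deregress EBVs into genomic-model response variables
#'
#' Undoes BLUP shrinkage by dividing the Mendelian-sampling deviation of the
#' EBV by its reliability, producing two response variables:
#' `DEBVexcPA = (EBV - PA) / r2` (parental contribution removed) and
#' `DEBVincPA = PA + (EBV - PA) / r2` (parent average added back to retain
#' family differences). Each record gets the Garrick weighting factor
#' `w = (1 - h2) / ((c + (1 - r2) / r2) * h2)`, where `c` is the proportion
#' of genetic variance not captured by the markers; `w` scales the record's
#' residual precision in the whole-genome regression (residual variance
#' `sigma2_e / w`).
#'
#' @param ebvs Tibble with `animal`, `ebv`, `reliability`, `pa` (e.g. from
#'   [solve_animal_model()]).
#' @param h2 Trait heritability in `(0, 1)`.
#' @param c Proportion of genetic variance not explained by markers
#'   (default 0.40).
#' @return The input tibble with added columns `debv_exc`, `debv_inc`,
#'   `weight`.
#' @export
deregress <- function(ebvs, h2, c = 0.40) {
  stopifnot(all(c("animal", "ebv", "reliability", "pa") %in% names(ebvs)))
  if (h2 <= 0 || h2 >= 1) stop_input("`h2` must be in (0, 1)")
  if (c < 0) stop_input("`c` must be >= 0")
  r2 <- ebvs$reliability
  if (any(r2 <= 0)) {
    stop_input("deregression undefined for reliability 0; filter such records first")
  }
  if (any(r2 > 1)) stop_input("reliability above 1")
  dev <- (ebvs$ebv - ebvs$pa) / r2
  dplyr::mutate(ebvs,
    debv_exc = dev,
    debv_inc = .data$pa + dev,
    weight = (1 - h2) / ((c + (1 - r2) / r2) * h2)
  )
}

#' Drop records with low EBV reliability
#'
#' Removes records whose reliability is strictly less than `min_r2` (a record
#' at exactly the threshold survives).
#'
#' @param records Tibble with a `reliability` column.
#' @param min_r2 Minimum reliability (default 0.10).
#' @return The filtered tibble; the number of removed records is attached as
#'   attribute `"n_removed"`.
#' @export
filter_reliability <- function(records, min_r2 = 0.10) {
  if (min_r2 < 0 || min_r2 > 1) stop_input("`min_r2` must be in [0, 1]")
  keep <- records$reliability >= min_r2
  out <- records[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}
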