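#' Molecular breeding values
#'
#' `MBV_i = sum_j (Z_ij - 2 p_j) u_j`: the sum of estimated marker effects
#' over an animal's centered genotypes. Centering uses the supplied (training
#' set) allele frequencies so that prediction-set information never leaks
#' into the centering.
#'
#' @param geno Genotype matrix (0/1/2).
#' @param effects Named vector of marker effects (names = marker ids present
#'   in `geno`'s colnames), or an unnamed vector aligned with `geno` columns.
#' @param p Allele frequencies for centering, aligned with `effects`.
#' @return Tibble with `animal` and `mbv`.
#' @export
molecular_breeding_values <- function(geno, effects, p = NULL) {
  if (!is.null(names(effects))) {
    missing <- setdiff(names(effects), colnames(geno))
    if (length(missing)) {
      stop_input(length(missing), " fitted markers absent from genotypes")
    }
    geno <- geno[, names(effects), drop = FALSE]
    if (!is.null(p) && !is.null(names(p))) p <- p[names(effects)]
  } else if (length(effects) != ncol(geno)) {
    stop_input("unnamed `effects` must match the genotype columns")
  }
  Z <- center_genotypes(geno, p)
  tibble(animal = rownames(geno) %||% as.character(seq_len(nrow(geno))),
         mbv = unname(drop(Z %*% unname(effects))))
}

#' Cross-validated genomic prediction accuracy
#'
#' For each fold, a sampler is trained on the animals outside the fold
#' (chain seed = configured seed + fold index), molecular breeding values are
#' predicted for the held-out animals using training-set allele frequencies,
#' and the fold accuracy is the Pearson correlation `r(MBV, response)` in the
#' held-out set. The summary accuracy is the mean over folds with
#' `SE = sd(r) / sqrt(k)`.
#'
#' @param geno Genotype matrix for all genotyped animals (rownames = ids).
#' @param responses Tibble with `animal` and `value` (e.g. a deregressed EBV
#'   column), covering every genotyped animal.
#' @param weights Optional tibble with `animal` and `weight`
#'   (residual-precision multipliers); default weight 1.
#' @param folds A `fold_assignment` from [kmeans_folds()].
#' @param config An [bayes_config()].
#' @param trait,response Labels carried into the result.
#' @param pooled Also report the pooled correlation over all held-out
#'   predictions (default TRUE).
#' @return An object of class `accuracy_result`: tibble `per_fold` (`fold`,
#'   `n_test`, `r`), `mean_r`, `se`, optional `pooled_r`, labels.
#' @export
cross_validate <- function(geno, responses, weights = NULL, folds,
                           config = bayes_config(), trait = "trait",
                           response = "response", pooled = TRUE) {
  ids <- rownames(geno)
  if (is.null(ids)) stop_input("genotypes need animal ids as rownames")
  y <- responses$value[match(ids, as.character(responses$animal))]
  if (anyNA(y)) stop_input("responses missing for some genotyped animals")
  w <- if (is.null(weights)) rep(1, length(y)) else {
    wv <- weights$weight[match(ids, as.character(weights$animal))]
    if (anyNA(wv)) stop_input("weights missing for some genotyped animals")
    wv
  }
  fold_of <- folds$fold[match(ids, as.character(folds$animal))]
  if (anyNA(fold_of)) stop_input("fold assignment missing for some animals")
  ks <- sort(unique(fold_of))
  if (any(table(fold_of) < 3)) {
    stop_input("every fold needs at least 3 animals for a stable correlation")
  }

  preds <- numeric(length(y))
  per_fold <- purrr::map_dfr(ks, function(f) {
    test <- fold_of == f
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- run_chain(y[!test], geno[!test, , drop = FALSE], w[!test], cfg)
    mbv <- predict(fit, geno[test, , drop = FALSE])$mbv
    preds[test] <<- mbv
    tibble(fold = f, n_test = sum(test), r = cor(mbv, y[test]))
  })
  out <- structure(list(
    trait = trait, method = config$method, response = response,
    per_fold = per_fold,
    mean_r = mean(per_fold$r),
    se = sd(per_fold$r) / sqrt(nrow(per_fold)),
    pooled_r = if (pooled) cor(preds, y) else NA_real_,
    k = length(ks), config = config
  ), class = "accuracy_result")
  out
}

#' @exportS3Method base::print
print.accuracy_result <- function(x, ...) {
  cat(sprintf("%s / %s / %s: mean r = %.3f (SE %.3f) over %d folds\n",
              x$trait, x$method, x$response, x$mean_r, x$se, x$k))
  invisible(x)
}

#' Per-fold accuracies of a cross-validation
#'
#' @param x An `accuracy_result`.
#' @param ... Unused.
#' @return Tibble with `trait`, `method`, `response`, `fold`, `n_test`, `r`.
#' @export
tidy.accuracy_result <- function(x, ...) {
  dplyr::mutate(x$per_fold, trait = x$trait, method = x$method,
                response = x$response, .before = 1L)
}

#' @rdname tidy.accuracy_result
#' @export
glance.accuracy_result <- function(x, ...) {
  tibble(trait = x$trait, method = x$method, response = x$response,
         k = x$k, mean_r = x$mean_r, se = x$se, pooled_r = x$pooled_r)
}

#' Accuracy comparison grid across response variables
#'
#' Collects several cross-validation results into one table (one row per
#' trait x method x response) and, where both response variables are present
#' for a trait/method pair, the accuracy difference
#' `DEBVincPA - DEBVexcPA`.
#'
#' @param results A list of `accuracy_result` objects.
#' @return A list with `grid` (tibble of mean (SE) accuracies) and `deltas`
#'   (tibble of between-response differences, when computable).
#' @export
summarize_accuracy <- function(results) {
  if (!length(results)) stop_input("no results to summarise")
  grid <- purrr::map_dfr(results, glance)
  wide <- tidyr::pivot_wider(
    dplyr::select(grid, "trait", "method", "response", "mean_r"),
    names_from = "response", values_from = "mean_r"
  )
  deltas <- if (all(c("DEBVincPA", "DEBVexcPA") %in% names(wide))) {
    dplyr::mutate(wide, delta = .data$DEBVincPA - .data$DEBVexcPA)
  } else tibble()
  list(grid = grid, deltas = deltas)
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object An `accuracy_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r, linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "r(MBV, response)",
                  title = sprintf("%s / %s / %s", object$trait,
                                  object$method, object$response)) +
    ggplot2::theme_minimal()
}
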