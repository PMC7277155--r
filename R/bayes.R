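#' MCMC configuration for the marker-effect samplers
#'
#' Defaults follow common practice for moderate-density pig panels: the
#' mixture proportion `pi = 0.99` (1% of markers in the model a priori), a
#' 110,000-iteration chain with 10,000 burn-in and thinning interval 10, and
#' weakly informative scaled-inverse-chi-square priors with `nu = 4.2` whose
#' scales are set from `sigma2_a_prior`/`sigma2_e_prior` at run time (see
#' [run_chain()]). Desk-scale analyses override `chain_length`, `burn_in`
#' and `thin`.
#'
#' @param method "BayesC" (common effect variance, normal prior) or "BayesB"
#'   (locus-specific variances, t prior).
#' @param pi Prior probability that a marker has zero effect, in `[0, 1)`.
#' @param chain_length Total Gibbs iterations.
#' @param burn_in Iterations discarded before summarising.
#' @param thin Thinning interval for stored effect samples.
#' @param seed Integer seed; chains are reproducible given the seed.
#' @param nu Prior degrees of freedom for both variance priors.
#' @param sigma2_a_prior Prior total additive genetic variance of the
#'   response; defaults at run time to half the response variance.
#' @param sigma2_e_prior Prior residual variance; defaults at run time to
#'   half the response variance.
#' @param fix_variances Keep `sigma2_u`/`sigma2_e` fixed at their prior means
#'   instead of sampling them (used for exact conjugate checks).
#' @return A list of class `mcmc_config`.
#' @export
bayes_config <- function(method = c("BayesC", "BayesB"), pi = 0.99,
                         chain_length = 110000L, burn_in = 10000L, thin = 10L,
                         seed = 1L, nu = 4.2, sigma2_a_prior = NULL,
                         sigma2_e_prior = NULL, fix_variances = FALSE) {
  method <- match.arg(method)
  if (pi < 0 || pi >= 1) stop_input("`pi` must be in [0, 1)")
  if (burn_in >= chain_length) stop_input("`burn_in` must be < `chain_length`")
  if (thin < 1) stop_input("`thin` must be >= 1")
  if (nu <= 2) stop_input("`nu` must exceed 2 for the prior mean to exist")
  structure(list(
    method = method, pi = pi, chain_length = as.integer(chain_length),
    burn_in = as.integer(burn_in), thin = as.integer(thin),
    seed = as.integer(seed), nu = nu,
    sigma2_a_prior = sigma2_a_prior, sigma2_e_prior = sigma2_e_prior,
    fix_variances = isTRUE(fix_variances)
  ), class = "mcmc_config")
}

#' Fit a BayesB/BayesC whole-genome regression by Gibbs sampling
#'
#' Fits `y_i = mu + sum_j Z_ij u_j delta_j + e_i` where each marker effect is
#' zero with prior probability `pi` and, when present, normal with a common
#' variance (BayesC) or a locus-specific variance under a
#' scaled-inverse-chi-square prior (BayesB, marginally a t prior). Record
#' residual variances are `sigma2_e / w_i`, so deregressed responses enter
#' with their Garrick weights. Genotype columns are centered by twice the
#' allele frequency; monomorphic columns are dropped. `delta_j` and `u_j`
#' are updated jointly per locus, with `u_j` integrated out of the `delta_j`
#' step.
#'
#' The prior scale for the effect variance is chosen so that its prior mean
#' equals `sigma2_a_prior / ((1 - pi) * sum_j 2 p_j (1 - p_j))`, i.e. the
#' genetic variance is spread over the markers expected in the model.
#'
#' @param y Numeric response (one record per genotyped animal).
#' @param geno Genotype matrix (0/1/2 allele counts), rows aligned with `y`.
#' @param weights Positive residual-precision multipliers (default 1).
#' @param config An [bayes_config()] object.
#' @param p Allele frequencies used for centering (default: computed from
#'   `geno`). Supply training frequencies when refitting on subsets.
#' @return An object of class `bayes_fit`: per-marker posterior summaries
#'   (`markers` tibble with `marker`, `freq`, `effect`, `inclusion_prob`),
#'   posterior means of `mu` and the variance components, per-sample genetic
#'   variance (variance of `Z u` across animals), thinned effect samples,
#'   the frequencies used for centering, and the configuration.
#' @export
run_chain <- function(y, geno, weights = NULL, config = bayes_config(),
                      p = NULL) {
  stopifnot(inherits(config, "mcmc_config"))
  if (length(y) != nrow(geno)) stop_input("length(y) must equal nrow(geno)")
  if (any(!is.finite(y))) stop_input("non-finite response values")
  if (any(!is.finite(geno))) stop_input("non-finite genotypes (impute or drop NAs first)")
  weights <- weights %||% rep(1, length(y))
  if (length(weights) != length(y) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop_input("`weights` must be positive and finite for every record")
  }

  p <- p %||% allele_freq(geno)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_input("no polymorphic markers")
  if (!all(poly)) {
    message(sum(!poly), " monomorphic marker(s) dropped before sampling")
  }
  Z <- center_genotypes(geno[, poly, drop = FALSE], p[poly])
  sum2pq <- sum(2 * p[poly] * (1 - p[poly]))

  vy <- var(y)
  sigma2_a_prior <- config$sigma2_a_prior %||% (0.5 * vy)
  sigma2_e_prior <- config$sigma2_e_prior %||% (0.5 * vy)
  mean_u <- sigma2_a_prior / ((1 - config$pi) * sum2pq)
  S_u <- mean_u * (config$nu - 2) / config$nu
  S_e <- sigma2_e_prior * (config$nu - 2) / config$nu

  set.seed(config$seed)
  res <- cpp_bayes_chain(
    Z, as.numeric(y), as.numeric(weights),
    bayesB = config$method == "BayesB", pi = config$pi,
    chain_length = config$chain_length, burn_in = config$burn_in,
    thin = config$thin, nu_u = config$nu, S_u = S_u,
    nu_e = config$nu, S_e = S_e, fix_var = config$fix_variances,
    sigma2_u_init = mean_u, sigma2_e_init = sigma2_e_prior
  )

  markers <- tibble(
    marker = colnames(geno)[poly] %||% paste0("m", which(poly)),
    freq = p[poly],
    effect = drop(res$effect),
    inclusion_prob = drop(res$inclusion_prob)
  )
  U <- res$samples_u
  colnames(U) <- markers$marker
  # per-sample genetic variance: variance of Z u across the training animals
  G <- Z %*% t(U)
  genvar <- apply(G, 2L, var)

  structure(list(
    markers = markers, mu = res$mu,
    post_mean_sigma2_u = res$post_mean_sigma2_u,
    post_mean_sigma2_e = res$post_mean_sigma2_e,
    genetic_variance_samples = genvar,
    post_mean_genetic_variance = mean(genvar),
    samples_u = U,
    samples_sigma2_u = drop(res$samples_sigma2_u),
    samples_sigma2_e = drop(res$samples_sigma2_e),
    samples_mu = drop(res$samples_mu),
    p = p, polymorphic = poly, sum2pq = sum2pq,
    n = nrow(Z), config = config
  ), class = "bayes_fit")
}

#' @exportS3Method base::print
print.bayes_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: %d animals, %d markers, pi = %g\n", x$config$method, x$n,
    nrow(x$markers), x$config$pi))
  cat(sprintf("  chain %d (burn-in %d, thin %d), %d stored samples\n",
              x$config$chain_length, x$config$burn_in, x$config$thin,
              nrow(x$samples_u)))
  cat(sprintf("  posterior means: sigma2_u = %.4g, sigma2_e = %.4g, genetic variance = %.4g\n",
              x$post_mean_sigma2_u, x$post_mean_sigma2_e,
              x$post_mean_genetic_variance))
  invisible(x)
}

#' Tidy per-marker posterior summaries
#'
#' @param x A `bayes_fit`.
#' @param ... Unused.
#' @return Tibble with `marker`, `freq`, `effect` (posterior mean),
#'   `inclusion_prob`.
#' @export
tidy.bayes_fit <- function(x, ...) x$markers

#' One-row model-level summary of a fit
#'
#' @param x A `bayes_fit`.
#' @param ... Unused.
#' @return One-row tibble with the method, dimensions, posterior-mean
#'   variance components, and genetic variance.
#' @export
glance.bayes_fit <- function(x, ...) {
  tibble(
    method = x$config$method, pi = x$config$pi, n = x$n,
    n_markers = nrow(x$markers), mu = x$mu,
    sigma2_u = x$post_mean_sigma2_u, sigma2_e = x$post_mean_sigma2_e,
    genetic_variance = x$post_mean_genetic_variance,
    n_samples = nrow(x$samples_u)
  )
}

#' Predict molecular breeding values for new animals
#'
#' @param object A `bayes_fit`.
#' @param geno Genotype matrix covering the fitted markers; centered with the
#'   training-set allele frequencies stored in the fit (no leakage from the
#'   prediction set).
#' @param ... Unused.
#' @return Tibble with `animal` (rownames of `geno`) and `mbv`.
#' @export
predict.bayes_fit <- function(object, geno, ...) {
  molecular_breeding_values(geno, effects = setNames(object$markers$effect,
                                                     object$markers$marker),
                            p = setNames(object$p[object$polymorphic],
                                         object$markers$marker))
}

#' Compare posterior-mean variances across chain lengths
#'
#' Runs one chain per requested length (same seed and settings otherwise) and
#' reports the pairwise absolute differences in the posterior means of the
#' genetic and residual variances -- a pragmatic convergence check: with an
#' adequate chain the differences are negligible.
#'
#' @inheritParams run_chain
#' @param lengths Integer vector of chain lengths, all greater than the
#'   configured burn-in.
#' @return A list with `by_length` (tibble of posterior means per length) and
#'   `differences` (tibble of pairwise absolute differences).
#' @export
convergence_compare <- function(y, geno, weights = NULL,
                                config = bayes_config(), lengths) {
  if (any(lengths <= config$burn_in)) {
    stop_input("all chain lengths must exceed the burn-in (",
               config$burn_in, ")")
  }
  fits <- purrr::map(lengths, function(L) {
    cfg <- config
    cfg$chain_length <- as.integer(L)
    run_chain(y, geno, weights, cfg)
  })
  by_length <- purrr::map2_dfr(lengths, fits, function(L, f) {
    tibble(chain_length = L,
           genetic_variance = f$post_mean_genetic_variance,
           sigma2_u = f$post_mean_sigma2_u,
           sigma2_e = f$post_mean_sigma2_e)
  })
  pairs <- utils::combn(seq_along(lengths), 2L)
  differences <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble(
      length_a = lengths[i], length_b = lengths[j],
      d_genetic_variance = abs(by_length$genetic_variance[i] -
                               by_length$genetic_variance[j]),
      d_sigma2_e = abs(by_length$sigma2_e[i] - by_length$sigma2_e[j])
    )
  })
  list(by_length = by_length, differences = differences)
}
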