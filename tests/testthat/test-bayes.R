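# Small fixed regression problem reused across sampler tests
sampler_fixture <- function(n = 50, m = 30, h2 = 0.5, seed = 42) {
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2L, 0.3), n, m,
              dimnames = list(seq_len(n), paste0("m", seq_len(m))))
  Z <- center_genotypes(G)
  b <- rnorm(m, 0, sqrt(h2 / m))
  g <- drop(Z %*% b)
  y <- g + rnorm(n, 0, sd(g) * sqrt((1 - h2) / h2))
  list(G = G, Z = Z, y = y)
}

test_that("chains are reproducible given a seed", {
  fx <- sampler_fixture()
  cfg <- bayes_config("BayesC", pi = 0.9, chain_length = 500, burn_in = 100,
                      thin = 2, seed = 7)
  f1 <- run_chain(fx$y, fx$G, config = cfg)
  f2 <- run_chain(fx$y, fx$G, config = cfg)
  expect_identical(f1$markers, f2$markers)
  expect_identical(f1$samples_u, f2$samples_u)
  f3 <- run_chain(fx$y, fx$G, config = bayes_config("BayesC", pi = 0.9,
                  chain_length = 500, burn_in = 100, thin = 2, seed = 8))
  expect_false(identical(f1$markers$effect, f3$markers$effect))
})

test_that("BayesC at pi = 0 matches the closed-form ridge oracle", {
  fx <- sampler_fixture()
  s2u <- 0.02; s2e <- 0.5
  cfg <- bayes_config("BayesC", pi = 0, chain_length = 6000, burn_in = 1000,
                      thin = 5, seed = 3, fix_variances = TRUE,
                      sigma2_a_prior = s2u * sum(apply(fx$Z, 2, var)),
                      sigma2_e_prior = s2e)
  # with fixed variances the prior-mean bookkeeping must yield exactly s2u
  cfg$sigma2_a_prior <- s2u * (1 - cfg$pi) * sum(2 * allele_freq(fx$G) *
                                                   (1 - allele_freq(fx$G)))
  fit <- run_chain(fx$y, fx$G, config = cfg)

  # oracle: posterior mean of u in the linear model with known variances is
  # the ridge/GBLUP solution (Z'Z + lambda I)^-1 Z' (y - mean adjustments);
  # include the intercept by augmenting with a flat column
  n <- length(fx$y); m <- ncol(fx$Z)
  lambda <- s2e / s2u
  W <- cbind(1, fx$Z)
  P <- crossprod(W) + diag(c(0, rep(lambda, m)))
  sol <- solve(P, crossprod(W, fx$y))
  ridge_u <- sol[-1]
  post_sd <- apply(fit$samples_u, 2, sd)
  expect_true(all(abs(fit$markers$effect - ridge_u) <= 3 * post_sd))
  expect_gt(cor(fit$markers$effect, ridge_u), 0.99)
  expect_true(all(fit$markers$inclusion_prob == 1))
})

test_that("pure-noise data returns the prior inclusion rate and residual variance", {
  set.seed(10)
  n <- 1000; m <- 200
  G <- matrix(rbinom(n * m, 2L, 0.4), n, m,
              dimnames = list(seq_len(n), paste0("m", seq_len(m))))
  y <- rnorm(n, 0, 2)                      # sigma2_e = 4, no genetic signal
  cfg <- bayes_config("BayesC", pi = 0.99, chain_length = 3000,
                      burn_in = 500, thin = 5, seed = 11)
  fit <- run_chain(y, G, config = cfg)
  expect_equal(mean(fit$markers$inclusion_prob), 0.01, tolerance = 0.5)
  expect_lt(abs(mean(fit$markers$inclusion_prob) - 0.01), 0.01)
  expect_equal(fit$post_mean_sigma2_e, 4, tolerance = 0.10)
})

test_that("BayesB and BayesC agree under a normal-effects architecture", {
  fx <- sampler_fixture(n = 150, m = 80, seed = 9)
  cfg <- function(m) bayes_config(m, pi = 0.5, chain_length = 3000,
                                  burn_in = 500, thin = 5, seed = 5)
  fb <- run_chain(fx$y, fx$G, config = cfg("BayesB"))
  fc <- run_chain(fx$y, fx$G, config = cfg("BayesC"))
  expect_gt(cor(fb$markers$effect, fc$markers$effect), 0.9)
})

test_that("posterior breeding values are invariant to genotype-coding shifts", {
  fx <- sampler_fixture(n = 80, m = 40, seed = 13)
  # adding a constant to a genotype column is absorbed by the centering + mu;
  # hold the effect-variance prior fixed across codings (the shifted coding
  # changes sum 2pq, which would otherwise rescale the prior)
  pi <- 0.9
  mean_u <- 0.01
  s2pq <- function(G) { p <- allele_freq(G); sum(2 * p * (1 - p)) }
  cfg_for <- function(G) bayes_config("BayesC", pi = pi, chain_length = 2000,
                                      burn_in = 400, thin = 4, seed = 2,
                                      sigma2_a_prior = mean_u * (1 - pi) * s2pq(G))
  f1 <- run_chain(fx$y, fx$G, config = cfg_for(fx$G))
  G2 <- fx$G
  G2[, 3] <- G2[, 3] + 1L
  f2 <- run_chain(fx$y, G2, config = cfg_for(G2))
  mbv1 <- predict(f1, fx$G)$mbv
  mbv2 <- predict(f2, G2)$mbv
  expect_equal(mbv1, mbv2, tolerance = 1e-10)
})

test_that("sampler recovers simulated genetic variance within 20%", {
  ped <- simulate_pedigree(100, 2, litters_per_generation = 25,
                           litter_size = 8, seed = 31)
  map <- make_marker_map(500, block_size = 5)
  set.seed(32)
  G <- simulate_genotypes(ped, map, runif(500, 0.1, 0.5), seed = 32,
                          ld_rho = 0.9)
  arch <- make_architecture(20, sigma2_p = 10, h2 = 0.4)
  tr <- simulate_trait(G, arch, seed = 33)
  cfg <- bayes_config("BayesC", pi = 0.99, chain_length = 4000,
                      burn_in = 1000, thin = 5, seed = 34)
  fit <- run_chain(tr$phenotypes$value, G, config = cfg)
  expect_equal(fit$post_mean_genetic_variance, 4, tolerance = 0.2)
})

test_that("input validation catches malformed sampler calls", {
  fx <- sampler_fixture()
  expect_error(bayes_config(pi = 1), "pi")
  expect_error(bayes_config(chain_length = 100, burn_in = 100), "burn_in")
  expect_error(run_chain(fx$y, fx$G, weights = rep(0, length(fx$y))),
               "weights")
  yy <- fx$y; yy[1] <- NA
  expect_error(run_chain(yy, fx$G), "non-finite")
  expect_error(run_chain(fx$y[-1], fx$G), "length")
})

test_that("convergence comparison across chain lengths is stable and validated", {
  fx <- sampler_fixture(n = 120, m = 60, seed = 17)
  cfg <- bayes_config("BayesC", pi = 0.9, burn_in = 1000, thin = 10, seed = 6,
                      chain_length = 16000)
  res <- convergence_compare(fx$y, fx$G, config = cfg,
                             lengths = c(7500, 11000, 15000))
  expect_equal(nrow(res$by_length), 3)
  rel <- res$differences$d_genetic_variance /
    mean(res$by_length$genetic_variance)
  expect_true(all(rel < 0.10))
  rel_e <- res$differences$d_sigma2_e / mean(res$by_length$sigma2_e)
  expect_true(all(rel_e < 0.10))

  # identical length, same seed: exactly zero difference
  res0 <- convergence_compare(fx$y, fx$G, config = cfg,
                              lengths = c(5000, 5000))
  expect_equal(res0$differences$d_genetic_variance, 0)
  expect_error(convergence_compare(fx$y, fx$G, config = cfg,
                                   lengths = c(500, 5000)), "burn-in")
})
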