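test_that("marker filtering applies rules in order with exact accounting", {
  mf <- make_defect_manifest(2000, unmapped = 100, sex_chromosome = 50,
                             low_call_rate = 30, duplicate_position = 5,
                             seed = 2)
  res <- filter_markers(marker_map = mf, call_rate_min = 0.90)
  rep <- res$report
  expect_equal(rep$n_retained, 2000 - 100 - 50 - 30 - 5)
  counts <- setNames(rep$excluded$n, rep$excluded$rule)
  expect_equal(unname(counts["unmapped"]), 100)
  expect_equal(unname(counts["sex_chromosome"]), 50)
  expect_equal(unname(counts["marker_call_rate"]), 30)
  expect_equal(unname(counts["duplicate_position"]), 5)
  # disjoint defects: exclusions + retained = input
  expect_equal(sum(rep$excluded$n) + rep$n_retained, rep$n_input)

  # idempotence: re-filtering removes nothing
  res2 <- filter_markers(marker_map = res$marker_map, call_rate_min = 0.90)
  expect_equal(res2$report$n_retained, rep$n_retained)
  expect_true(all(res2$report$excluded$n == 0))
})

test_that("all-clean panels pass untouched and duplicates keep higher call rate", {
  mf <- make_defect_manifest(100, seed = 3)
  res <- filter_markers(marker_map = mf)
  expect_equal(res$report$n_retained, 100)
  expect_true(all(res$report$excluded$n == 0))

  dup_map <- tibble::tibble(
    marker = c("snpA", "snpB", "snpC"),
    chr = c("1", "1", "2"), bp = c(500L, 500L, 900L),
    call_rate = c(0.95, 0.99, 0.97)
  )
  res <- filter_markers(marker_map = dup_map)
  expect_setequal(res$report$retained, c("snpB", "snpC"))  # 0.95 one excluded

  # tie on call rate: lexicographically first id survives
  tie_map <- dplyr::mutate(dup_map, call_rate = c(0.97, 0.97, 0.97))
  res_tie <- filter_markers(marker_map = tie_map)
  expect_true("snpA" %in% res_tie$report$retained)
  expect_false("snpB" %in% res_tie$report$retained)
})

test_that("marker call rates are computed from genotypes when supplied", {
  ped <- simulate_pedigree(40, 0, seed = 1)
  map <- make_marker_map(30)
  G <- simulate_genotypes(ped, map, 0.3, seed = 1)
  G <- sprinkle_missing(G, marker_rates = c(rep(0, 25), rep(0.5, 5)), seed = 2)
  res <- filter_markers(G, map, call_rate_min = 0.90)
  counts <- setNames(res$report$excluded$n, res$report$excluded$rule)
  expect_equal(unname(counts["marker_call_rate"]), 5)
  expect_equal(ncol(res$geno), 25)
})

test_that("animal filtering removes low call rate then unmatched animals", {
  ped <- simulate_pedigree(539, 0, seed = 4)
  map <- make_marker_map(60)
  G <- simulate_genotypes(ped, map, 0.3, seed = 4)
  low <- sample(539, 5)
  G <- sprinkle_missing(G, animal_rates = replace(rep(0, 539), low, 0.5),
                        seed = 5)
  with_pheno <- setdiff(seq_len(539), c(low, sample(setdiff(1:539, low), 34)))
  res <- filter_animals(G, with_pheno, call_rate_min = 0.90)
  counts <- setNames(res$report$excluded$n, res$report$excluded$rule)
  expect_equal(unname(counts["animal_call_rate"]), 5)
  expect_equal(unname(counts["phenotype_unmatched"]), 34)
  expect_equal(res$report$n_retained, 500)

  # no phenotypes at all: everything is unmatched
  res0 <- filter_animals(G, integer(0))
  expect_equal(res0$report$n_retained, 0)
  expect_equal(sum(res0$report$excluded$n), 539)
})

test_that("duplicate animals across platforms are detected by concordance", {
  ped <- simulate_pedigree(20, 0, seed = 6)
  map <- make_marker_map(100)
  G1 <- simulate_genotypes(ped, map, 0.4, seed = 6)
  G2 <- G1[1:5, , drop = FALSE]                      # same animals re-genotyped
  rownames(G2) <- paste0("dup", 1:5)
  set.seed(7)
  G_other <- simulate_genotypes(simulate_pedigree(3, 0, seed = 9), map, 0.4,
                                seed = 9)
  rownames(G_other) <- paste0("new", 1:3)
  dup <- find_duplicate_animals(G1, rbind(G2, G_other), threshold = 0.9)
  expect_setequal(dup$animal2, paste0("dup", 1:5))
  expect_true(all(dup$concordance == 1))
})

test_that("imputation concordance matches closed-form oracles by MAF bin", {
  ped <- simulate_pedigree(400, 0, seed = 8)
  map <- make_marker_map(60)
  set.seed(8)
  mafs <- runif(60, 0.05, 0.5)
  truth <- simulate_genotypes(ped, map, mafs, seed = 8)
  set.seed(9)
  mask <- matrix(runif(length(truth)) < 0.3, nrow(truth))

  # perfect imputation: every non-empty bin at 1
  tab <- imputation_concordance_by_maf(truth, truth, mask)
  expect_true(all(tab$concordance[tab$n_genotypes > 0] == 1))
  expect_true(all(is.na(tab$concordance[tab$n_genotypes == 0])))

  # flipped homozygotes: only heterozygotes still match; oracle = direct count
  flipped <- 2 - truth
  tab_f <- imputation_concordance_by_maf(truth, flipped, mask)
  oracle <- vapply(seq_len(nrow(tab_f)), function(k) {
    in_bin <- maf(truth) > tab_f$bin_low[k] & maf(truth) <= tab_f$bin_high[k]
    cells <- mask[, in_bin, drop = FALSE]
    if (!sum(cells)) return(NA_real_)
    sum(truth[, in_bin, drop = FALSE][cells] == 1) / sum(cells)
  }, numeric(1))
  expect_equal(tab_f$concordance, oracle)

  # random fill by HWE genotype frequencies: E[concordance] = sum_g f_g^2
  # at MAF 0.5: 0.25^2 + 0.5^2 + 0.25^2 = 0.375
  big <- simulate_genotypes(simulate_pedigree(3000, 0, seed = 10),
                            make_marker_map(30), 0.5, seed = 10)
  set.seed(11)
  mask_b <- matrix(TRUE, nrow(big), ncol(big))
  fill <- apply(big, 2, function(g) {
    f <- tabulate(g + 1L, 3L) / length(g)
    sample(0:2, length(g), replace = TRUE, prob = f)
  })
  tab_b <- imputation_concordance_by_maf(big, fill, mask_b)
  got <- tab_b$concordance[tab_b$bin_low == 0.45]
  expect_equal(got, 0.375, tolerance = 0.02)

  # permutation invariance within bins
  perm_a <- sample(nrow(truth)); perm_m <- sample(ncol(truth))
  tab_p <- imputation_concordance_by_maf(truth[perm_a, perm_m],
                                         flipped[perm_a, perm_m],
                                         mask[perm_a, perm_m])
  expect_equal(tab_p$concordance, tab_f$concordance)
})
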