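# Fixture builders shared across test files. Everything is generated in code;
# sizes are kept small so the full suite runs quickly.

# A pedigree of `n_fam` unrelated full-sib families: two founders per family,
# `n_off` offspring each. Families are mutually unrelated by construction.
family_pedigree <- function(n_fam = 4, n_off = 4) {
  recs <- list()
  id <- 0L
  for (f in seq_len(n_fam)) {
    s <- id + 1L; d <- id + 2L
    recs[[length(recs) + 1L]] <- tibble::tibble(
      animal = c(s, d), sire = 0L, dam = 0L, sex = c("M", "F"),
      generation = 0L, litter = 0L, birth_order = 1:2
    )
    off <- id + 2L + seq_len(n_off)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      animal = off, sire = s, dam = d,
      sex = rep(c("M", "F"), length.out = n_off),
      generation = 1L, litter = f, birth_order = seq_len(n_off)
    )
    id <- id + 2L + n_off
  }
  dplyr::bind_rows(recs)
}

# Brute-force additive relationship by the recursive definition:
#   a(i,i) = 1 + a(s_i, d_i)/2 ; a(i,j) = (a(s_i, j) + a(d_i, j))/2 for j < i.
# Independent of the tabular implementation in build_A().
oracle_A <- function(pedigree) {
  ids <- pedigree$animal
  s <- match(pedigree$sire, ids, nomatch = 0L)
  d <- match(pedigree$dam, ids, nomatch = 0L)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i == j) {
      return(1 + 0.5 * a(s[i], d[i]))
    }
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    0.5 * (a(s[i], j) + a(d[i], j))
  }
  n <- length(ids)
  M <- outer(seq_len(n), seq_len(n), Vectorize(a))
  dimnames(M) <- list(as.character(ids), as.character(ids))
  M
}

# Genotypes + phenotypes for a family-structured trait, used by the BLUP,
# deregression and cross-validation tests.
family_dataset <- function(n_fam = 10, n_off = 12, n_markers = 300,
                           block_size = 5, h2 = 0.4, sigma2_p = 10,
                           sigma2_c = 1, n_qtl = 15, seed = 1) {
  ped <- family_pedigree(n_fam, n_off)
  map <- swinegs::make_marker_map(n_markers, block_size)
  set.seed(seed)
  mafs <- runif(n_markers, 0.1, 0.5)
  geno <- swinegs::simulate_genotypes(ped, map, mafs, seed = seed + 1,
                                      ld_rho = 0.9)
  arch <- swinegs::make_architecture(n_qtl, sigma2_p = sigma2_p, h2 = h2,
                                     sigma2_c = sigma2_c)
  tr <- swinegs::simulate_trait(geno, arch, seed = seed + 2, pedigree = ped)
  list(ped = ped, map = map, geno = geno, arch = arch, trait = tr)
}
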