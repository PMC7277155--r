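#' Default trait variance components for a Duroc-like pig population
#'
#' Additive genetic and phenotypic variances (and the implied heritabilities)
#' for four growth and production traits commonly recorded in purebred pig
#' breeding programs: backfat thickness (BFAT, mm), days to 90 kg body weight
#' (DAYS, d), loin muscle area (LMA, cm2) and lean percent (PCL, %). These are
#' published pedigree-BLUP estimates for a Korean Duroc nucleus population and
#' are used as the simulator's default trait architectures.
#'
#' @return A tibble with columns `trait`, `sigma2_a`, `sigma2_p`, `h2`.
#' @export
trait_params <- function() {
  tibble(
    trait    = c("BFAT", "DAYS", "LMA", "PCL"),
    sigma2_a = c(1.21, 34.57, 1.14, 2.09),
    sigma2_p = c(3.42, 85.10, 7.15, 5.52),
    h2       = c(0.35, 0.41, 0.16, 0.38)
  )
}

#' Simulate a multi-generation pig pedigree with litters
#'
#' Founders (generation 0) have unknown parents (coded 0). Each subsequent
#' generation consists of `litters_per_generation` full-sib litters of
#' `litter_size` piglets; every litter has a single sire/dam pair drawn from
#' the previous generation. Sires may serve several litters; dams are used
#' without replacement within a generation when enough are available.
#'
#' @param n_founders Number of base-population animals (>= 2).
#' @param n_generations Number of offspring generations (>= 0).
#' @param litters_per_generation Litters produced per generation.
#' @param litter_size Piglets per litter.
#' @param seed Integer seed; the same seed reproduces the pedigree exactly.
#' @return A tibble with columns `animal`, `sire`, `dam`, `sex` ("M"/"F"),
#'   `generation`, `litter` (0 for founders), `birth_order`. Animals are
#'   numbered so that parents always precede offspring.
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              litters_per_generation = 1L, litter_size = 1L,
                              seed = 1L) {
  if (n_founders < 1) stop_input("`n_founders` must be >= 1")
  if (n_generations < 0) stop_input("`n_generations` must be >= 0")
  if (n_generations > 0 && (litters_per_generation < 1 || litter_size < 1)) {
    stop_input("`litters_per_generation` and `litter_size` must be >= 1")
  }
  if (n_generations > 0 && n_founders < 2) {
    stop_input("need at least 2 founders (one of each sex) to breed")
  }
  set.seed(seed)
  # guarantee both sexes among founders, then fill at random
  sex <- c("M", "F", sample(c("M", "F"), max(0, n_founders - 2), replace = TRUE))
  sex <- sample(sex)[seq_len(n_founders)]
  ped <- tibble(
    animal = seq_len(n_founders), sire = 0L, dam = 0L, sex = sex,
    generation = 0L, litter = 0L, birth_order = seq_len(n_founders)
  )
  next_id <- n_founders + 1L
  litter_id <- 0L
  for (g in seq_len(n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (length(males) == 0 || length(females) == 0) {
      stop_input("generation ", g - 1L, " has a single sex; cannot breed on")
    }
    sires <- sample(males, litters_per_generation, replace = TRUE)
    dams <- if (length(females) >= litters_per_generation) {
      sample(females, litters_per_generation, replace = FALSE)
    } else {
      sample(females, litters_per_generation, replace = TRUE)
    }
    for (l in seq_len(litters_per_generation)) {
      litter_id <- litter_id + 1L
      ids <- next_id + seq_len(litter_size) - 1L
      ped <- dplyr::bind_rows(ped, tibble(
        animal = ids, sire = sires[l], dam = dams[l],
        sex = sample(c("M", "F"), litter_size, replace = TRUE),
        generation = g, litter = litter_id,
        birth_order = seq_len(litter_size)
      ))
      next_id <- next_id + litter_size
    }
  }
  ped
}

#' Validate pedigree ordering and structure
#' @noRd
check_pedigree <- function(pedigree) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(pedigree)))
  ids <- pedigree$animal
  if (anyDuplicated(ids)) stop_input("pedigree animal ids are not unique")
  pos <- match(ids, ids)
  for (col in c("sire", "dam")) {
    p <- pedigree[[col]]
    known <- p != 0L
    idx <- match(p[known], ids)
    if (anyNA(idx)) stop_input("pedigree has a ", col, " that is not an animal")
    if (any(idx >= which(known))) {
      stop_input("pedigree is not sorted: some parents appear after offspring")
    }
  }
  invisible(pedigree)
}

#' Simulate genotypes down a pedigree by gene dropping
#'
#' Founder haplotypes are drawn at Hardy-Weinberg equilibrium from per-marker
#' founder allele frequencies; every non-founder inherits, per linkage block,
#' one intact haplotype from each parent (Mendelian transmission with free
#' recombination between blocks and none within). With the default map (each
#' marker its own block) all loci segregate independently. An optional
#' `ld_rho` > 0 correlates alleles within a block: each haplotype draws a
#' block "core" allele and each marker copies it with probability `ld_rho`,
#' producing the marker-QTL linkage disequilibrium that window-based
#' association scans rely on.
#'
#' @param pedigree A pedigree tibble (`animal`, `sire`, `dam`), parents before
#'   offspring, unknown parents coded 0.
#' @param marker_map Tibble with `marker` and optionally `block` (integer
#'   linkage-block id per marker; defaults to one block per marker).
#' @param founder_maf Founder minor allele frequency per marker, in `[0, 0.5]`
#'   (scalar recycled). A frequency of 0 yields a monomorphic marker.
#' @param seed Integer seed.
#' @param ld_rho Within-block allele correlation parameter in `[0, 1]`.
#' @return Integer matrix (animals x markers) of 0/1/2 allele counts with
#'   animal ids as rownames and marker ids as colnames.
#' @export
simulate_genotypes <- function(pedigree, marker_map, founder_maf, seed = 1L,
                               ld_rho = 0) {
  check_pedigree(pedigree)
  m <- nrow(marker_map)
  p <- rep_len(founder_maf, m)
  if (any(p < 0 | p > 0.5)) {
    stop_input("founder MAFs must lie in [0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho > 1) stop_input("`ld_rho` must be in [0, 1]")
  block <- marker_map$block %||% seq_len(m)
  blocks <- split(seq_len(m), block)
  n <- nrow(pedigree)
  set.seed(seed)

  draw_haplotype <- function() {
    # one gamete: per block, core allele then per-marker copy-or-independent
    h <- integer(m)
    for (b in blocks) {
      pb <- mean(p[b])
      core <- rbinom(1L, 1L, pb)
      use_core <- runif(length(b)) < ld_rho
      h[b] <- ifelse(use_core, core, rbinom(length(b), 1L, p[b]))
    }
    h
  }

  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  idx <- match(pedigree$animal, pedigree$animal)
  sire_row <- match(pedigree$sire, pedigree$animal)
  dam_row <- match(pedigree$dam, pedigree$animal)
  nb <- length(blocks)
  for (i in seq_len(n)) {
    if (pedigree$sire[i] == 0L || pedigree$dam[i] == 0L) {
      H1[i, ] <- draw_haplotype()
      H2[i, ] <- draw_haplotype()
    } else {
      s <- sire_row[i]; d <- dam_row[i]
      pick_s <- runif(nb) < 0.5
      pick_d <- runif(nb) < 0.5
      for (bi in seq_len(nb)) {
        b <- blocks[[bi]]
        H1[i, b] <- if (pick_s[bi]) H1[s, b] else H2[s, b]
        H2[i, b] <- if (pick_d[bi]) H1[d, b] else H2[d, b]
      }
    }
  }
  G <- H1 + H2
  dimnames(G) <- list(as.character(pedigree$animal),
                      as.character(marker_map$marker))
  G
}

#' Inject missing genotypes at given per-marker or per-animal rates
#'
#' Used to emulate call-rate defects for quality-control testing.
#'
#' @param geno Genotype matrix (0/1/2).
#' @param marker_rates Per-marker missing rate (scalar or vector), or NULL.
#' @param animal_rates Per-animal missing rate (scalar or vector), or NULL.
#' @param seed Integer seed.
#' @return The matrix with entries set to `NA` at the requested rates.
#' @export
sprinkle_missing <- function(geno, marker_rates = NULL, animal_rates = NULL,
                             seed = 1L) {
  set.seed(seed)
  if (!is.null(marker_rates)) {
    r <- rep_len(marker_rates, ncol(geno))
    for (j in seq_len(ncol(geno))) {
      if (r[j] > 0) geno[runif(nrow(geno)) < r[j], j] <- NA
    }
  }
  if (!is.null(animal_rates)) {
    r <- rep_len(animal_rates, nrow(geno))
    for (i in seq_len(nrow(geno))) {
      if (r[i] > 0) geno[i, runif(ncol(geno)) < r[i]] <- NA
    }
  }
  geno
}

#' Define a quantitative trait architecture
#'
#' Encapsulates the variance structure of a simulated trait: `n_qtl` additive
#' QTL (effects rescaled at simulation time so the realized additive variance
#' equals `sigma2_a`), a common-litter environmental variance `sigma2_c`, and
#' fixed contemporary-group effects. Residual variance is the remainder
#' `sigma2_p - sigma2_a - sigma2_c`.
#'
#' @param n_qtl Number of QTL (0 for a trait with no genetic signal).
#' @param sigma2_p Phenotypic variance (trait units squared).
#' @param h2 Heritability; exactly one of `h2`/`sigma2_a` must be given.
#' @param sigma2_a Additive genetic variance.
#' @param sigma2_c Common-litter environmental variance (default 0).
#' @param cg_effects Numeric vector of contemporary-group effects (trait
#'   units); animals are assigned groups at random. Default: one group, 0.
#' @param qtl Optional fixed marker indices for the QTL.
#' @param trait Trait label.
#' @return An object of class `trait_architecture` (a list).
#' @export
make_architecture <- function(n_qtl, sigma2_p, h2 = NULL, sigma2_a = NULL,
                              sigma2_c = 0, cg_effects = 0, qtl = NULL,
                              trait = "trait") {
  if (is.null(sigma2_a) && is.null(h2)) {
    stop_input("give one of `h2` or `sigma2_a`")
  }
  sigma2_a <- sigma2_a %||% (h2 * sigma2_p)
  if (n_qtl == 0 && sigma2_a > 0) {
    stop_input("`n_qtl` = 0 requires `sigma2_a` (or `h2`) = 0")
  }
  h2 <- sigma2_a / sigma2_p
  if (sigma2_p <= 0) stop_input("`sigma2_p` must be positive")
  if (sigma2_a < 0 || sigma2_c < 0) stop_input("variances must be >= 0")
  if (sigma2_a + sigma2_c > sigma2_p) {
    stop_input("sigma2_a + sigma2_c exceeds sigma2_p; no residual variance left")
  }
  structure(list(
    trait = trait, n_qtl = as.integer(n_qtl), qtl = qtl,
    sigma2_a = sigma2_a, sigma2_p = sigma2_p, h2 = h2,
    sigma2_c = sigma2_c, sigma2_e = sigma2_p - sigma2_a - sigma2_c,
    cg_effects = cg_effects
  ), class = "trait_architecture")
}

#' Simulate phenotypes and true breeding values for a trait
#'
#' QTL effects are drawn standard-normal at the chosen loci and rescaled so
#' the realized additive variance (variance of true breeding values across
#' phenotyped animals) equals `sigma2_a` exactly. The phenotype model is
#' `y = mu + CG effect + TBV + litter effect + residual`, with litter effects
#' `N(0, sigma2_c)` shared by littermates and residuals
#' `N(0, sigma2_p - sigma2_a - sigma2_c)`.
#'
#' @param geno Genotype matrix from [simulate_genotypes()].
#' @param architecture A [make_architecture()] object.
#' @param seed Integer seed.
#' @param pedigree Optional pedigree supplying `litter` codes (and used to
#'   restrict phenotypes to non-founders when `include_founders = FALSE`).
#' @param mu Overall trait mean.
#' @param include_founders Phenotype founders too? Default FALSE when a
#'   pedigree is supplied.
#' @return A list of class `sim_trait`: `phenotypes` (tibble `animal`,
#'   `trait`, `value`, `cg`, `litter`), `tbv` (tibble `animal`, `tbv`),
#'   `qtl` (tibble `marker`, `effect`), the architecture, and
#'   `var_a_realized`.
#' @export
simulate_trait <- function(geno, architecture, seed = 1L, pedigree = NULL,
                           mu = 0, include_founders = is.null(pedigree)) {
  stopifnot(inherits(architecture, "trait_architecture"))
  a <- architecture
  set.seed(seed)
  ids <- rownames(geno)
  keep <- rep(TRUE, nrow(geno))
  litter <- rep(seq_len(nrow(geno)), 1L)  # default: every animal its own litter
  if (!is.null(pedigree)) {
    ord <- match(ids, as.character(pedigree$animal))
    if (anyNA(ord)) stop_input("genotyped animals missing from pedigree")
    if (!include_founders) keep <- pedigree$sire[ord] != 0L | pedigree$dam[ord] != 0L
    litter <- pedigree$litter[ord]
  }

  p <- allele_freq(geno)
  poly <- which(p > 0 & p < 1)
  if (a$n_qtl > length(poly) && is.null(a$qtl)) {
    stop_input("fewer polymorphic markers than requested QTL")
  }
  qtl <- a$qtl %||% sort(sample(poly, a$n_qtl))
  if (length(qtl) && any(p[qtl] %in% c(0, 1))) {
    stop_input("QTL indices must point at polymorphic markers")
  }

  n <- nrow(geno)
  if (length(qtl) == 0L) {
    tbv <- rep(0, n)
    eff <- numeric(0)
  } else {
    eff <- rnorm(length(qtl))
    Zq <- center_genotypes(geno[, qtl, drop = FALSE], p[qtl])
    raw <- drop(Zq %*% eff)
    v <- var(raw[keep])
    if (v == 0) stop_input("QTL genotypes carry no variance among phenotyped animals")
    eff <- eff * sqrt(a$sigma2_a / v)
    tbv <- raw * sqrt(a$sigma2_a / v)
  }

  cg <- sample(seq_along(a$cg_effects), n, replace = TRUE)
  litter_eff <- if (a$sigma2_c > 0) {
    le <- rnorm(length(unique(litter)), 0, sqrt(a$sigma2_c))
    le[match(litter, unique(litter))]
  } else rep(0, n)
  resid <- rnorm(n, 0, sqrt(a$sigma2_e))
  y <- mu + a$cg_effects[cg] + tbv + litter_eff + resid

  structure(list(
    phenotypes = tibble(
      animal = as.integer(ids), trait = a$trait, value = y,
      cg = cg, litter = litter
    )[keep, ],
    tbv = tibble(animal = as.integer(ids), tbv = tbv),
    qtl = tibble(marker = colnames(geno)[qtl], index = qtl, effect = eff),
    architecture = a,
    var_a_realized = if (length(qtl)) var(tbv[keep]) else 0
  ), class = "sim_trait")
}

#' Build a marker manifest carrying panel defects
#'
#' Creates a marker map of `total` markers in which exactly the requested
#' numbers carry each defect: unmapped (no chromosome/position), located on a
#' sex chromosome, poor call rate (< 0.9), or duplicating another marker's
#' map position (the duplicate always has the lower call rate of the pair).
#' All remaining markers are clean, mapped to autosomes 1..18 with unique
#' positions and call rates >= 0.95. Defect categories are disjoint.
#'
#' @param total Total number of markers on the panel.
#' @param unmapped,sex_chromosome,low_call_rate,duplicate_position Counts of
#'   markers carrying each defect.
#' @param seed Integer seed.
#' @return A tibble with columns `marker`, `chr` (character, `NA` when
#'   unmapped), `bp`, `call_rate`, and logical defect flags `unmapped`,
#'   `sex_chromosome`, `low_call_rate`, `duplicate_position`.
#' @export
make_defect_manifest <- function(total, unmapped = 0, sex_chromosome = 0,
                                 low_call_rate = 0, duplicate_position = 0,
                                 seed = 1L) {
  n_defect <- unmapped + sex_chromosome + low_call_rate + duplicate_position
  if (any(c(unmapped, sex_chromosome, low_call_rate, duplicate_position) < 0)) {
    stop_input("defect counts must be >= 0")
  }
  if (n_defect > total) {
    stop_input("defect counts (", n_defect, ") exceed panel total (", total, ")")
  }
  n_clean <- total - n_defect
  if (duplicate_position > n_clean) {
    stop_input("more duplicate-position markers than clean markers to duplicate")
  }
  set.seed(seed)
  id <- sprintf("M%07d", seq_len(total))
  flag <- rep("clean", total)
  pool <- sample(total)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  i_unm <- take(unmapped); i_sex <- take(sex_chromosome)
  i_low <- take(low_call_rate); i_dup <- take(duplicate_position)
  flag[i_unm] <- "unmapped"; flag[i_sex] <- "sex_chromosome"
  flag[i_low] <- "low_call_rate"; flag[i_dup] <- "duplicate_position"

  chr <- rep(NA_character_, total)
  bp <- rep(NA_integer_, total)
  mapped <- which(!(seq_len(total) %in% i_unm) & flag != "sex_chromosome")
  chr[mapped] <- as.character(sample(1:18, length(mapped), replace = TRUE))
  # unique positions within chromosome for all mapped autosomal markers
  for (cc in unique(chr[mapped])) {
    at <- mapped[chr[mapped] == cc]
    bp[at] <- sample(150e6, length(at))
  }
  chr[i_sex] <- "X"
  bp[i_sex] <- sample(120e6, sex_chromosome)

  call_rate <- runif(total, 0.95, 1)
  call_rate[i_low] <- runif(low_call_rate, 0.50, 0.899)

  # duplicates copy a clean marker's position and sit strictly below its call rate
  i_clean <- which(flag == "clean")
  partner <- sample(i_clean, duplicate_position)
  chr[i_dup] <- chr[partner]
  bp[i_dup] <- bp[partner]
  call_rate[i_dup] <- pmax(0.90, call_rate[partner] - runif(duplicate_position, 0.01, 0.04))

  tibble(
    marker = id, chr = chr, bp = bp, call_rate = call_rate,
    unmapped = flag == "unmapped",
    sex_chromosome = flag == "sex_chromosome",
    low_call_rate = flag == "low_call_rate",
    duplicate_position = flag == "duplicate_position"
  )
}

#' Simple clean marker map for simulations
#'
#' Lays `n_markers` out in consecutive `block_size`-marker blocks, one block
#' per 1-Mb window, `windows_per_chr` windows per chromosome on autosomes
#' 1..18. Block ids are included so [simulate_genotypes()] treats each window
#' as one linkage unit.
#'
#' @param n_markers Number of markers.
#' @param block_size Markers per linkage block / window.
#' @param windows_per_chr 1-Mb windows per chromosome.
#' @return Tibble with `marker`, `chr`, `bp`, `block`.
#' @export
make_marker_map <- function(n_markers, block_size = 1L, windows_per_chr = 40L) {
  block <- (seq_len(n_markers) - 1L) %/% block_size
  within <- (seq_len(n_markers) - 1L) %% block_size
  win_per_chr <- windows_per_chr
  chr <- as.character((block %/% win_per_chr) %% 18L + 1L)
  mb <- block %% win_per_chr
  bp <- mb * 1e6 + (within + 1L) * floor(1e6 / (block_size + 1L))
  tibble(
    marker = sprintf("M%06d", seq_len(n_markers)),
    chr = chr, bp = as.integer(bp), block = block + 1L
  )
}
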