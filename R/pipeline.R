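#' Configuration for an end-to-end synthetic evaluation run
#'
#' Collects every stage's parameters with defaults at the values conventional
#' for moderate-density pig evaluations: marker/animal call-rate minimum
#' 0.90, deregression constant `c = 0.40` with reliability filter 0.10,
#' mixture proportion `pi = 0.99` with a 110,000 / 10,000 / 10 MCMC schedule,
#' window threshold 0.8% of genetic variance, and 10 cross-validation folds.
#' Desk-scale runs shrink the simulation and chain settings.
#'
#' @param seed Master seed; each stage derives its own stream from it.
#' @param n_founders,n_generations,litters_per_generation,litter_size
#'   Pedigree simulation settings.
#' @param n_markers,block_size Marker panel settings (one linkage block per
#'   1-Mb window).
#' @param maf_range Founder MAFs are drawn uniformly from this range.
#' @param ld_rho Within-block LD parameter.
#' @param n_qtl,trait Trait architecture: QTL count and which row of
#'   [trait_params()] supplies the variance components.
#' @param call_rate_min QC call-rate threshold.
#' @param c_value,min_r2 Deregression constant and reliability filter.
#' @param method,pi,chain_length,burn_in,thin MCMC settings.
#' @param gv_threshold_pct Window significance threshold.
#' @param k Cross-validation folds.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_founders = 60L, n_generations = 4L,
                            litters_per_generation = 12L, litter_size = 6L,
                            n_markers = 600L, block_size = 5L,
                            maf_range = c(0.1, 0.5), ld_rho = 0.9,
                            n_qtl = 20L, trait = "DAYS",
                            call_rate_min = 0.90,
                            c_value = 0.40, min_r2 = 0.10,
                            method = "BayesC", pi = 0.99,
                            chain_length = 2000L, burn_in = 500L, thin = 5L,
                            gv_threshold_pct = 0.8, k = 10L) {
  cfg <- as.list(environment())
  if (!trait %in% trait_params()$trait) {
    stop_input("`trait` must be one of ", paste(trait_params()$trait,
                                                collapse = ", "))
  }
  if (pi < 0 || pi >= 1) stop_input("`pi` must be in [0, 1)")
  if (burn_in >= chain_length) stop_input("`burn_in` must be < `chain_length`")
  if (call_rate_min <= 0 || call_rate_min > 1) {
    stop_input("`call_rate_min` must be in (0, 1]")
  }
  if (min_r2 < 0 || min_r2 > 1) stop_input("`min_r2` must be in [0, 1]")
  if (k < 2) stop_input("`k` must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic evaluation pipeline
#'
#' Executes, in order: pedigree/genotype/trait simulation, marker and animal
#' QC, relationship matrix and K-means folds, pedigree BLUP, deregression
#' with the reliability filter, whole-genome regression on DEBVincPA, window
#' GWAS with Bayes factors, and 10-fold cross-validated prediction for both
#' response variables. All stage outputs are written as CSV (plus a PLINK
#' .ped/.map pair for the genotypes) under `out_dir`, together with a
#' `manifest.json` recording the configuration, seeds, package version and
#' file digests; re-running with the same configuration reproduces the run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  sim <- stage("simulate", {
    ped <- simulate_pedigree(cfg$n_founders, cfg$n_generations,
                             cfg$litters_per_generation, cfg$litter_size,
                             seed = cfg$seed)
    map <- make_marker_map(cfg$n_markers, cfg$block_size)
    set.seed(cfg$seed + 1L)
    mafs <- runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
    geno <- simulate_genotypes(ped, map, mafs, seed = cfg$seed + 2L,
                               ld_rho = cfg$ld_rho)
    tp <- trait_params()[trait_params()$trait == cfg$trait, ]
    arch <- make_architecture(cfg$n_qtl, sigma2_p = tp$sigma2_p,
                              sigma2_a = tp$sigma2_a,
                              sigma2_c = 0.1 * tp$sigma2_p,
                              cg_effects = c(-1, 0, 1) * sqrt(tp$sigma2_p) / 4,
                              trait = cfg$trait)
    tr <- simulate_trait(geno, arch, seed = cfg$seed + 3L, pedigree = ped)
    list(pedigree = ped, marker_map = map, geno = geno, arch = arch,
         trait = tr)
  })

  qc <- stage("qc", {
    fm <- filter_markers(sim$geno, sim$marker_map, cfg$call_rate_min)
    fa <- filter_animals(fm$geno, sim$trait$phenotypes$animal,
                         cfg$call_rate_min)
    list(geno = fa$geno, marker_map = fm$marker_map,
         marker_report = fm$report, animal_report = fa$report)
  })

  rel <- stage("folds", {
    A <- build_A(sim$pedigree)
    folds <- kmeans_folds(A, rownames(qc$geno), k = cfg$k,
                          seed = cfg$seed + 4L, min_size = 3L)
    list(A = A, folds = folds,
         summary = fold_relationship_summary(A, folds))
  })

  ebv <- stage("ebv", {
    solve_animal_model(sim$trait$phenotypes, sim$pedigree,
                       list(sigma2_a = sim$arch$sigma2_a,
                            sigma2_c = sim$arch$sigma2_c,
                            sigma2_e = sim$arch$sigma2_e))
  })

  dereg <- stage("deregress", {
    genotyped <- rownames(qc$geno)
    d <- deregress(ebv[as.character(ebv$animal) %in% genotyped, ],
                   h2 = sim$arch$h2, c = cfg$c_value)
    filter_reliability(d, cfg$min_r2)
  })

  keep <- as.character(dereg$animal)
  geno_kept <- qc$geno[rownames(qc$geno) %in% keep, , drop = FALSE]
  folds_kept <- rel$folds[rel$folds$animal %in% keep, ]

  mcfg <- bayes_config(method = cfg$method, pi = cfg$pi,
                       chain_length = cfg$chain_length, burn_in = cfg$burn_in,
                       thin = cfg$thin, seed = cfg$seed + 5L)

  fit <- stage("train", {
    ord <- match(rownames(geno_kept), as.character(dereg$animal))
    run_chain(dereg$debv_inc[ord], geno_kept, dereg$weight[ord], mcfg)
  })

  gwas <- stage("gwas", {
    win <- window_variances(fit, geno_kept, qc$marker_map)
    list(windows = win,
         significant = significant_windows(win, cfg$gv_threshold_pct),
         snps = snp_bayes_factors(fit, qc$marker_map))
  })

  cv <- stage("cv", {
    ord <- match(rownames(geno_kept), as.character(dereg$animal))
    resp <- function(col) tibble(animal = dereg$animal[ord],
                                 value = dereg[[col]][ord])
    wts <- tibble(animal = dereg$animal[ord], weight = dereg$weight[ord])
    list(
      exc = cross_validate(geno_kept, resp("debv_exc"), wts, folds_kept,
                           mcfg, trait = cfg$trait, response = "DEBVexcPA"),
      inc = cross_validate(geno_kept, resp("debv_inc"), wts, folds_kept,
                           mcfg, trait = cfg$trait, response = "DEBVincPA")
    )
  })

  # ---- write stage outputs -------------------------------------------------
  wcsv <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  wcsv(sim$pedigree, "pedigree.csv")
  write_plink(sim$geno, sim$marker_map, file.path(out_dir, "genotypes"))
  wcsv(sim$trait$phenotypes, "phenotypes.csv")
  wcsv(tidy(qc$marker_report), "qc_markers.csv")
  wcsv(tidy(qc$animal_report), "qc_animals.csv")
  wcsv(as_tibble(rel$folds), "folds.csv")
  wcsv(rel$summary, "fold_summary.csv")
  wcsv(as_tibble(ebv), "ebv.csv")
  wcsv(as_tibble(dereg), "deregressed.csv")
  wcsv(tidy(fit), "marker_effects.csv")
  wcsv(as_tibble(gwas$windows), "windows.csv")
  wcsv(gwas$snps, "snp_bayes_factors.csv")
  wcsv(dplyr::bind_rows(tidy(cv$exc), tidy(cv$inc)), "cv_accuracy.csv")
  wcsv(summarize_accuracy(list(cv$exc, cv$inc))$grid, "cv_summary.csv")

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package = "swinegs",
    version = as.character(utils::packageVersion("swinegs")),
    created = format(Sys.time(), tz = "UTC"),
    config = unclass(cfg),
    digests = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sim = sim, qc = qc, rel = rel, ebv = ebv, dereg = dereg,
                 fit = fit, gwas = gwas, cv = cv, out_dir = out_dir))
}
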