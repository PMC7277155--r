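#' Marker quality control
#'
#' Applies the panel-editing rules in a fixed order so per-rule counts are
#' well defined when defects overlap: (1) unmapped markers (no chromosome or
#' position), (2) markers on sex chromosomes, (3) markers with call rate below
#' `call_rate_min`, (4) markers duplicating an already-seen map position --
#' within a duplicated chr:bp the marker with the highest call rate is kept
#' (ties broken by lexicographic marker id).
#'
#' @param geno Genotype matrix (animals x markers, 0/1/2, `NA` missing), or
#'   `NULL` to run map-only accounting (requires a `call_rate` column in the
#'   map).
#' @param marker_map Tibble with `marker`, `chr`, `bp`, and optionally
#'   `call_rate`. When `geno` is supplied, call rates are computed from it and
#'   any `call_rate` column is ignored.
#' @param call_rate_min Minimum marker call rate (default 0.90).
#' @return A list with `geno` (filtered matrix or `NULL`), `marker_map`
#'   (retained rows), and `report` (a `qc_report`; see [tidy.qc_report()]).
#' @export
filter_markers <- function(geno = NULL, marker_map, call_rate_min = 0.90) {
  if (call_rate_min <= 0 || call_rate_min > 1) {
    stop_input("`call_rate_min` must be in (0, 1]")
  }
  stopifnot(all(c("marker", "chr", "bp") %in% names(marker_map)))
  if (!is.null(geno)) {
    if (!identical(colnames(geno), marker_map$marker)) {
      if (is.null(colnames(geno)) || !setequal(colnames(geno), marker_map$marker)) {
        stop_input("genotype columns and marker map do not match")
      }
      marker_map <- marker_map[match(colnames(geno), marker_map$marker), ]
    }
    cr <- 1 - colMeans(is.na(geno))
  } else {
    if (!"call_rate" %in% names(marker_map)) {
      stop_input("map-only filtering needs a `call_rate` column in `marker_map`")
    }
    cr <- marker_map$call_rate
  }

  n_input <- nrow(marker_map)
  alive <- rep(TRUE, n_input)
  counts <- c(unmapped = 0L, sex_chromosome = 0L, marker_call_rate = 0L,
              duplicate_position = 0L)

  drop_rule <- function(alive, hit, rule) {
    hit <- hit & alive
    counts[rule] <<- sum(hit)
    alive & !hit
  }
  alive <- drop_rule(alive, is.na(marker_map$chr) | is.na(marker_map$bp),
                     "unmapped")
  alive <- drop_rule(alive, marker_map$chr %in% c("X", "Y", "XY", "MT"),
                     "sex_chromosome")
  alive <- drop_rule(alive, cr < call_rate_min, "marker_call_rate")
  # duplicate positions among survivors: keep highest call rate, ties by id
  pos <- paste(marker_map$chr, marker_map$bp, sep = ":")
  surv <- which(alive)
  ord <- surv[order(pos[surv], -cr[surv], marker_map$marker[surv])]
  dup <- ord[duplicated(pos[ord])]
  hit <- rep(FALSE, n_input); hit[dup] <- TRUE
  alive <- drop_rule(alive, hit, "duplicate_position")

  report <- new_qc_report(
    unit = "marker", n_input = n_input,
    excluded = tibble(rule = names(counts), n = unname(counts)),
    retained = marker_map$marker[alive]
  )
  list(
    geno = if (!is.null(geno)) geno[, alive, drop = FALSE] else NULL,
    marker_map = marker_map[alive, ],
    report = report
  )
}

#' Animal quality control
#'
#' Removes, in order: animals with genotype call rate below `call_rate_min`,
#' then animals that do not match a phenotype record.
#'
#' @param geno Genotype matrix with animal ids as rownames.
#' @param phenotype_ids Ids (coercible to character) of animals that have
#'   phenotypes.
#' @param call_rate_min Minimum animal call rate (default 0.90).
#' @return A list with `geno` (filtered) and `report` (a `qc_report`).
#' @export
filter_animals <- function(geno, phenotype_ids, call_rate_min = 0.90) {
  if (call_rate_min <= 0 || call_rate_min > 1) {
    stop_input("`call_rate_min` must be in (0, 1]")
  }
  ids <- rownames(geno)
  if (is.null(ids)) stop_input("genotype matrix needs animal ids as rownames")
  cr <- 1 - rowMeans(is.na(geno))
  alive <- cr >= call_rate_min
  n_low <- sum(!alive)
  matched <- ids %in% as.character(phenotype_ids)
  n_unmatched <- sum(alive & !matched)
  alive <- alive & matched
  report <- new_qc_report(
    unit = "animal", n_input = nrow(geno),
    excluded = tibble(rule = c("animal_call_rate", "phenotype_unmatched"),
                      n = c(n_low, n_unmatched)),
    retained = ids[alive]
  )
  list(geno = geno[alive, , drop = FALSE], report = report)
}

#' Detect duplicate animals across two genotyping platforms
#'
#' Flags pairs of animals whose genotype concordance on shared markers exceeds
#' `threshold` -- the same animal genotyped on both platforms.
#'
#' @param geno1,geno2 Genotype matrices with marker colnames and animal
#'   rownames.
#' @param threshold Concordance above which a pair is called a duplicate
#'   (default 0.9).
#' @return Tibble with `animal1`, `animal2`, `concordance`, `n_shared`.
#' @export
find_duplicate_animals <- function(geno1, geno2, threshold = 0.9) {
  shared <- intersect(colnames(geno1), colnames(geno2))
  if (length(shared) == 0) stop_input("no shared markers between platforms")
  g1 <- geno1[, shared, drop = FALSE]
  g2 <- geno2[, shared, drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(g1))) {
    eq <- sweep(g2, 2L, g1[i, ], `==`)
    n_ok <- rowSums(!is.na(eq))
    conc <- rowSums(eq, na.rm = TRUE) / pmax(n_ok, 1L)
    hit <- which(n_ok > 0 & conc > threshold)
    if (length(hit)) {
      out[[length(out) + 1L]] <- tibble(
        animal1 = rownames(g1)[i], animal2 = rownames(g2)[hit],
        concordance = conc[hit], n_shared = n_ok[hit]
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(animal1 = character(), animal2 = character(),
           concordance = double(), n_shared = integer())
}

#' @noRd
new_qc_report <- function(unit, n_input, excluded, retained) {
  structure(list(unit = unit, n_input = n_input, excluded = excluded,
                 retained = retained, n_retained = length(retained)),
            class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report (", x$unit, "s): ", x$n_input, " in, ",
      x$n_retained, " retained\n", sep = "")
  for (i in seq_len(nrow(x$excluded))) {
    cat(sprintf("  %-22s -%d\n", x$excluded$rule[i], x$excluded$n[i]))
  }
  invisible(x)
}

#' Tidy a QC report into one row per rule
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Tibble with `rule`, `n_excluded`, plus `retained` and `input`
#'   attributes rows appended via [glance.qc_report()] if needed.
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::rename(x$excluded, n_excluded = "n")
}

#' @rdname tidy.qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(unit = x$unit, n_input = x$n_input, n_retained = x$n_retained,
         n_excluded = sum(x$excluded$n))
}

#' Imputation concordance by minor-allele-frequency bin
#'
#' Evaluates an imputation run by masking known genotypes, imputing them, and
#' counting the proportion recovered exactly, stratified by the marker's true
#' MAF. MAF is computed from the `truth` matrix; markers are binned by
#' right-closed intervals over `(0, 0.5]`, so monomorphic markers are not
#' binned.
#'
#' @param truth,imputed Genotype matrices of identical shape.
#' @param mask Logical matrix marking the entries that were hidden and then
#'   imputed.
#' @param bin_edges Bin edges on MAF (default width 0.05 over `[0, 0.5]`).
#' @return A tibble of class `maf_bin_table`: `bin_low`, `bin_high`,
#'   `concordance` (`NA` for bins with no masked genotypes), `n_genotypes`,
#'   `n_markers`.
#' @export
imputation_concordance_by_maf <- function(truth, imputed, mask,
                                          bin_edges = seq(0, 0.5, by = 0.05)) {
  if (!all(dim(truth) == dim(imputed)) || !all(dim(truth) == dim(mask))) {
    stop_input("`truth`, `imputed` and `mask` must share dimensions")
  }
  m <- maf(truth)
  bin <- cut(m, bin_edges, include.lowest = FALSE, right = TRUE)
  match_mat <- (imputed == truth) & mask
  n_mask <- colSums(mask)
  n_match <- colSums(match_mat, na.rm = TRUE)
  per_bin <- tibble(bin = bin, n_mask = n_mask, n_match = n_match) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n_genotypes = sum(.data$n_mask),
      n_markers = dplyr::n(),
      concordance = ifelse(sum(.data$n_mask) > 0,
                           sum(.data$n_match) / sum(.data$n_mask), NA_real_),
      .groups = "drop"
    )
  lev <- levels(bin)
  out <- tibble(
    bin_low = bin_edges[-length(bin_edges)],
    bin_high = bin_edges[-1],
    concordance = per_bin$concordance[match(lev, per_bin$bin)],
    n_genotypes = per_bin$n_genotypes[match(lev, per_bin$bin)],
    n_markers = per_bin$n_markers[match(lev, per_bin$bin)]
  )
  out$n_genotypes[is.na(out$n_genotypes)] <- 0L
  out$n_markers[is.na(out$n_markers)] <- 0L
  class(out) <- c("maf_bin_table", class(out))
  out
}

#' Plot imputation concordance by MAF bin
#'
#' @param object A `maf_bin_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maf_bin_table <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$concordance))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                   y = .data$concordance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "minor allele frequency (bin midpoint)",
                  y = "proportion of correctly imputed genotypes") +
    ggplot2::theme_minimal()
}
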