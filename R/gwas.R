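#' Assign markers to 1-Mb genomic windows
#'
#' Window index is `floor(bp / (window_mb * 1e6))`; the window id is
#' `"chr_index"` (so a marker on chromosome 1 at 62,120,000 bp falls in
#' window `1_62`). The number of windows is a property of the supplied map,
#' not a constant of the method.
#'
#' @param marker_map Tibble with `marker`, `chr`, `bp`; all markers must be
#'   mapped.
#' @param window_mb Window width in megabases (default 1).
#' @return The map with added `window_index` and `window` columns.
#' @export
assign_windows <- function(marker_map, window_mb = 1) {
  if (any(is.na(marker_map$chr) | is.na(marker_map$bp))) {
    stop_input("unmapped markers cannot be assigned to windows; run QC first")
  }
  dplyr::mutate(marker_map,
    window_index = as.integer(floor(.data$bp / (window_mb * 1e6))),
    window = paste(.data$chr, .data$window_index, sep = "_")
  )
}

#' Posterior window genetic-variance percentages
#'
#' For every stored effect sample s and window w the genomic values
#' `g_w = Z_w u_w` are computed across the training animals, giving a
#' per-sample window variance `var(g_w)` and total variance
#' `var(sum_w g_w)`. The window's share is the ratio of posterior means,
#' `%GV_w = 100 * mean_s var_w / mean_s var_total` (a ratio of means, not a
#' mean of ratios, which would be unstable when a sample's total variance is
#' near zero).
#'
#' @param fit A `bayes_fit` from [run_chain()].
#' @param geno The training genotype matrix used for the fit.
#' @param marker_map Map covering the fitted markers (mapped markers only).
#' @param window_mb Window width in megabases.
#' @return A tibble of class `window_gv`: `window`, `chr`, `window_index`,
#'   `n_markers`, `gv_pct`, `rank` (1 = largest share).
#' @export
window_variances <- function(fit, geno, marker_map, window_mb = 1) {
  wm <- assign_windows(marker_map, window_mb)
  wm <- wm[match(fit$markers$marker, wm$marker), ]
  if (anyNA(wm$marker)) {
    stop_input("marker map does not cover all fitted markers")
  }
  Z <- center_genotypes(geno[, fit$markers$marker, drop = FALSE],
                        fit$p[fit$polymorphic])
  U <- fit$samples_u
  total <- Z %*% t(U)                      # n x S genomic values
  var_total <- apply(total, 2L, var)
  mean_total <- mean(var_total)

  windows <- split(seq_len(nrow(wm)), wm$window)
  res <- purrr::imap_dfr(windows, function(cols, id) {
    gw <- Z[, cols, drop = FALSE] %*% t(U[, cols, drop = FALSE])
    tibble(
      window = id,
      chr = wm$chr[cols[1]],
      window_index = wm$window_index[cols[1]],
      n_markers = length(cols),
      mean_var = mean(apply(gw, 2L, var))
    )
  })
  if (mean_total <= 0) {
    warning("total genetic variance of the chain is zero; %GV undefined")
    res$gv_pct <- NA_real_
  } else {
    res$gv_pct <- 100 * res$mean_var / mean_total
  }
  res <- dplyr::select(res, -"mean_var")
  res$rank <- rank(-res$gv_pct, ties.method = "first", na.last = "keep")
  res <- dplyr::arrange(res, .data$rank)
  class(res) <- c("window_gv", class(res))
  res
}

#' Windows above the genetic-variance threshold
#'
#' Keeps windows whose posterior genetic-variance share is strictly above
#' `threshold_pct`, ranked in decreasing order. The conventional threshold
#' for moderate-density panels is 0.8% -- twenty times the uniform
#' per-window share when roughly 2500 windows tile the autosomes
#' (100/2454 = 0.04%).
#'
#' @param windows A `window_gv` tibble from [window_variances()].
#' @param threshold_pct Threshold percentage (default 0.8).
#' @return The informative subset, ordered by decreasing `gv_pct`.
#' @export
significant_windows <- function(windows, threshold_pct = 0.8) {
  if (threshold_pct < 0) stop_input("`threshold_pct` must be >= 0")
  out <- dplyr::filter(windows, !is.na(.data$gv_pct),
                       .data$gv_pct > threshold_pct)
  dplyr::arrange(out, dplyr::desc(.data$gv_pct))
}

#' Uniform per-window genetic-variance share
#'
#' The theoretical share of the total genetic variance a single window would
#' carry if variance were spread evenly: `100 / n_windows` percent.
#'
#' @param n_windows Number of windows tiling the genome.
#' @return Percentage (e.g. about 0.04 for 2454 windows).
#' @export
theoretical_window_share <- function(n_windows) {
  if (n_windows < 1) stop_input("`n_windows` must be >= 1")
  100 / n_windows
}

#' Bayes factors for marker inclusion
#'
#' `BF = [p_hat / (1 - p_hat)] / [(1 - pi) / pi]`: the posterior odds that a
#' marker is in the model against its prior odds. Evidence categories follow
#' Kass-Raftery with strictly-greater boundaries: above 3.2 "suggestive",
#' above 20 "strong", above 100 "decisive". A posterior inclusion
#' probability of 1 yields `BF = Inf` (decisive).
#'
#' @param p_hat Posterior inclusion probabilities in `[0, 1]`.
#' @param pi Prior exclusion probability in `(0, 1)`.
#' @return Tibble with `p_hat`, `bf`, `category` (ordered factor
#'   none < suggestive < strong < decisive).
#' @export
bayes_factor <- function(p_hat, pi) {
  if (any(p_hat < 0 | p_hat > 1)) stop_input("`p_hat` must be in [0, 1]")
  if (pi <= 0 || pi >= 1) stop_input("`pi` must be in (0, 1)")
  prior_odds <- (1 - pi) / pi
  bf <- (p_hat / (1 - p_hat)) / prior_odds
  bf[p_hat == 1] <- Inf
  category <- cut(bf, c(-Inf, 3.2, 20, 100, Inf),
                  labels = c("none", "suggestive", "strong", "decisive"),
                  right = TRUE, ordered_result = TRUE)
  category[is.infinite(bf)] <- "decisive"
  tibble(p_hat = p_hat, bf = bf, category = category)
}

#' Per-marker Bayes factors from a fitted chain
#'
#' @param fit A `bayes_fit`.
#' @param marker_map Optional map to attach `chr`/`bp`/window columns.
#' @param window_mb Window width when a map is supplied.
#' @return Tibble with `marker`, `effect`, `p_hat`, `bf`, `category` (and map
#'   columns when available).
#' @export
snp_bayes_factors <- function(fit, marker_map = NULL, window_mb = 1) {
  bf <- bayes_factor(fit$markers$inclusion_prob, fit$config$pi)
  out <- dplyr::bind_cols(
    dplyr::select(fit$markers, "marker", "effect"), bf)
  if (!is.null(marker_map)) {
    wm <- assign_windows(marker_map, window_mb)
    out <- dplyr::left_join(out,
      dplyr::select(wm, "marker", "chr", "bp", "window"), by = "marker")
  }
  dplyr::arrange(out, dplyr::desc(.data$bf))
}

#' Manhattan-style plot of window genetic-variance shares
#'
#' @param object A `window_gv` tibble.
#' @param threshold_pct Horizontal reference line (default 0.8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_gv <- function(object, threshold_pct = 0.8, ...) {
  df <- as_tibble(object)
  df$chr <- factor(df$chr, levels = unique(df$chr[order(suppressWarnings(
    as.numeric(df$chr)), df$chr)]))
  df <- dplyr::arrange(df, .data$chr, .data$window_index)
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$gv_pct,
                                   colour = .data$chr)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "1-Mb window (ordered by chromosome)",
                  y = "window genetic variance (%)") +
    ggplot2::theme_minimal()
}
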