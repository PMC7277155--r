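#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: for animal i with parents s and d,
#' `a_ij = (a_sj + a_dj) / 2` for j < i and `a_ii = 1 + a_sd / 2`, unknown
#' parents contributing zero. Founders are assumed unrelated and non-inbred.
#'
#' @param pedigree Tibble with `animal`, `sire`, `dam`; parents before
#'   offspring, unknown parents coded 0.
#' @return A symmetric numeric matrix with animal ids as dimnames; the
#'   diagonal is `1 + F` (F = inbreeding coefficient).
#' @export
build_A <- function(pedigree) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  s <- match(pedigree$sire, pedigree$animal, nomatch = 0L)
  d <- match(pedigree$dam, pedigree$animal, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row_s <- if (s[i] > 0L) A[s[i], prev] else numeric(i - 1L)
      row_d <- if (d[i] > 0L) A[d[i], prev] else numeric(i - 1L)
      A[i, prev] <- 0.5 * (row_s + row_d)
      A[prev, i] <- A[i, prev]
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(as.character(pedigree$animal),
                      as.character(pedigree$animal))
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @inheritParams build_A
#' @return Tibble with `animal` and `f` (inbreeding coefficient).
#' @export
inbreeding <- function(pedigree) {
  A <- build_A(pedigree)
  tibble(animal = pedigree$animal, f = unname(diag(A)) - 1)
}

#' Sparse inverse of the relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from the pedigree, accounting for inbreeding.
#' The Mendelian-sampling variance of animal i is
#' `0.5 - 0.25 (F_s + F_d)` with both parents known, `0.75 - 0.25 F_p` with
#' one, and 1 with none.
#'
#' @inheritParams build_A
#' @param f Optional precomputed inbreeding coefficients (vector aligned with
#'   the pedigree); computed via [inbreeding()] when missing.
#' @return A sparse symmetric [Matrix::Matrix] with animal ids as dimnames.
#' @export
build_A_inverse <- function(pedigree, f = NULL) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  f <- f %||% inbreeding(pedigree)$f
  s <- match(pedigree$sire, pedigree$animal, nomatch = 0L)
  d <- match(pedigree$dam, pedigree$animal, nomatch = 0L)
  ii <- integer(0); jj <- integer(0); xx <- double(0)
  add <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else NA_real_
    fd <- if (d[i] > 0L) f[d[i]] else NA_real_
    di <- if (s[i] > 0L && d[i] > 0L) 0.5 - 0.25 * (fs + fd)
          else if (s[i] > 0L) 0.75 - 0.25 * fs
          else if (d[i] > 0L) 0.75 - 0.25 * fd
          else 1
    m <- 1 / di
    add(i, i, m)
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        add(i, p, -m / 2); add(p, i, -m / 2)
      }
    }
    par <- c(s[i], d[i])[c(s[i], d[i]) > 0L]
    for (p1 in par) for (p2 in par) add(p1, p2, m / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(as.character(pedigree$animal),
                                               as.character(pedigree$animal)))
  Matrix::forceSymmetric(Ainv)
}

#' K-means cross-validation folds that respect family structure
#'
#' Clusters genotyped animals on the rows of the genotyped submatrix of the
#' relationship matrix A (each animal's vector of relationships to all other
#' genotyped animals), so animals in the same fold are related and folds are
#' mutually unrelated -- maximising within-fold and minimising between-fold
#' relatedness for cross-validation.
#'
#' @param A Relationship matrix from [build_A()].
#' @param genotyped_ids Ids (subset of A's dimnames) to assign to folds.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; clustering is deterministic given the seed.
#' @param n_restarts Random restarts; the solution with the lowest
#'   within-cluster sum of squares is kept (default 25).
#' @param min_size Minimum animals per fold (default 1, i.e. no constraint).
#'   Clusters smaller than this are dissolved and their animals reassigned to
#'   the nearest remaining centroid, so folds stay usable for
#'   cross-validation statistics.
#' @return A tibble of class `fold_assignment` with `animal` and `fold`,
#'   carrying `k`, `seed` and `sizes` attributes.
#' @export
kmeans_folds <- function(A, genotyped_ids, k, seed = 1L, n_restarts = 25L,
                         min_size = 1L) {
  ids <- as.character(genotyped_ids)
  if (!all(ids %in% rownames(A))) {
    stop_input("some genotyped ids are absent from the relationship matrix")
  }
  if (k < 2) stop_input("`k` must be >= 2")
  if (k > length(ids)) stop_input("`k` exceeds the number of genotyped animals")
  X <- A[ids, ids, drop = FALSE]
  set.seed(seed)
  if (k == length(ids)) {
    # degenerate request: singleton clusters, zero within-cluster scatter
    cluster <- seq_along(ids)
    sizes <- rep(1L, k)
    wss <- 0
  } else {
    # identical full-sib rows can trip kmeans' Quick-TRANSfer/empty-cluster
    # warnings; restarts and the min_size pass below absorb those cases
    km <- suppressWarnings(
      kmeans(X, centers = k, nstart = n_restarts, iter.max = 200L))
    cluster <- km$cluster
    centers <- km$centers
    # dissolve undersized clusters into the nearest surviving centroid
    repeat {
      sizes_now <- tabulate(cluster, k)
      small <- which(sizes_now > 0 & sizes_now < min_size)
      if (!length(small)) break
      victim <- small[which.min(sizes_now[small])]
      keepers <- setdiff(which(sizes_now > 0), victim)
      for (i in which(cluster == victim)) {
        d2 <- colSums((t(centers[keepers, , drop = FALSE]) - X[i, ])^2)
        cluster[i] <- keepers[which.min(d2)]
      }
    }
    # renumber folds consecutively after any dissolution
    cluster <- match(cluster, sort(unique(cluster)))
    sizes <- tabulate(cluster, max(cluster))
    wss <- km$tot.withinss
  }
  out <- tibble(animal = ids, fold = as.integer(cluster))
  attr(out, "k") <- length(sizes)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sizes") <- as.integer(sizes)
  attr(out, "tot_withinss") <- wss
  class(out) <- c("fold_assignment", class(out))
  out
}

#' Within- and between-fold relationship summary
#'
#' For each fold reports: size, mean inbreeding coefficient, the per-animal
#' maximum relationship to any animal in the same fold (`a_max_within`,
#' mean and sd over animals) and to any animal in other folds
#' (`a_max_between`), and the mean pairwise relationship over pairs within
#' the fold (`a_ij_within`) and over pairs crossing to other folds
#' (`a_ij_between`).
#'
#' @param A Relationship matrix.
#' @param folds A `fold_assignment` (or tibble with `animal`, `fold`).
#' @return A tibble with one row per fold.
#' @export
fold_relationship_summary <- function(A, folds) {
  ids <- as.character(folds$animal)
  if (!all(ids %in% rownames(A))) {
    stop_input("fold animals missing from the relationship matrix")
  }
  X <- A[ids, ids, drop = FALSE]
  fo <- folds$fold
  purrr::map_dfr(sort(unique(fo)), function(cl) {
    inside <- which(fo == cl)
    outside <- which(fo != cl)
    Xin <- X[inside, inside, drop = FALSE]
    off <- Xin[upper.tri(Xin)]
    max_w <- if (length(inside) > 1) {
      apply(Xin - diag(Inf, length(inside)), 1L, max)
    } else rep(NA_real_, 1L)
    max_b <- if (length(outside) > 0) {
      apply(X[inside, outside, drop = FALSE], 1L, max)
    } else rep(NA_real_, length(inside))
    between <- as.vector(X[inside, outside])
    tibble(
      fold = cl, n = length(inside),
      inbreeding = mean(diag(Xin) - 1),
      a_max_within = mean(max_w), a_max_within_sd = sd(max_w),
      a_max_between = mean(max_b), a_max_between_sd = sd(max_b),
      a_ij_within = if (length(off)) mean(off) else NA_real_,
      a_ij_within_sd = if (length(off) > 1) sd(off) else NA_real_,
      a_ij_between = if (length(between)) mean(between) else NA_real_,
      a_ij_between_sd = if (length(between) > 1) sd(between) else NA_real_
    )
  })
}
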