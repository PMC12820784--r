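# Niche discovery: neighborhood cell-type composition, silhouette-selected
# k-means clustering of composition vectors, and per-niche cell-type
# enrichment via standardized residuals of a chi-squared independence test.

#' Neighborhood cell-type composition matrix
#'
#' For every cell, counts the cells of each type within Euclidean distance
#' `r_um` (closed predicate, `d <= r`) in the same sample; samples never
#' share neighbors. The focal cell is counted in its own neighborhood by
#' default, so an isolated cell has a total neighbor count of 1.
#'
#' Uses a per-sample grid index of bin width `r_um` (each cell is compared
#' only against the 9 surrounding bins); results are identical to the
#' all-pairs computation.
#'
#' @param cells a [cell_table()].
#' @param r_um neighborhood radius in micrometres (default 30).
#' @param include_self count the focal cell itself (default TRUE).
#' @return integer matrix, one row per cell (aligned to `cells`), one column
#'   per cell type (columns in sorted type order, recorded in dimnames),
#'   with attributes `r_um` and `include_self`.
#' @export
neighborhood_composition <- function(cells, r_um = 30, include_self = TRUE) {
  stopifnot(inherits(cells, "cell_table"))
  if (nrow(cells) == 0) stop("empty cell table", call. = FALSE)
  if (r_um <= 0) stop("r_um must be > 0", call. = FALSE)
  types <- sort(unique(cells$cell_type))
  type_int <- match(cells$cell_type, types)
  n <- nrow(cells)
  comp <- matrix(0L, n, length(types), dimnames = list(NULL, types))

  for (sid in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == sid)
    x <- cells$x_um[idx]; y <- cells$y_um[idx]
    pairs <- radius_pairs(x, y, r_um)
    i <- pairs$i; j <- pairs$j
    if (!include_self) {
      keep <- i != j
      i <- i[keep]; j <- j[keep]
    }
    tj <- type_int[idx][j]
    flat <- (tj - 1L) * length(idx) + i
    tab <- tabulate(flat, nbins = length(idx) * length(types))
    comp[idx, ] <- comp[idx, ] +
      matrix(tab, nrow = length(idx), ncol = length(types))
  }
  storage.mode(comp) <- "integer"
  attr(comp, "r_um") <- r_um
  attr(comp, "include_self") <- include_self
  attr(comp, "cell_id") <- cells$cell_id
  comp
}

# all (i, j) index pairs with distance <= r, including i == j,
# via a grid spatial index of bin width r
radius_pairs <- function(x, y, r) {
  n <- length(x)
  bx <- floor(x / r); by <- floor(y / r)
  key <- paste(bx, by, sep = ",")
  groups <- split(seq_len(n), key)
  gkeys <- names(groups)
  i_all <- vector("list", 9L); j_all <- vector("list", 9L)
  off <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    nkey <- paste(bx + dx, by + dy, sep = ",")
    gid <- match(nkey, gkeys)
    has <- which(!is.na(gid))
    if (!length(has)) { off <- off + 1L; next }
    cand <- groups[gid[has]]
    lens <- lengths(cand)
    off <- off + 1L
    i_all[[off]] <- rep.int(has, lens)
    j_all[[off]] <- unlist(cand, use.names = FALSE)
  }
  i <- unlist(i_all, use.names = FALSE)
  j <- unlist(j_all, use.names = FALSE)
  keep <- (x[i] - x[j])^2 + (y[i] - y[j])^2 <= r * r
  list(i = i[keep], j = j[keep])
}

#' Fit multicellular niches by silhouette-selected k-means
#'
#' Runs k-means (multiple seeded restarts, best within-cluster sum of
#' squares; ties keep the lowest restart index) on neighborhood composition
#' rows for each `k` in `k_range`, scores each clustering by the mean
#' silhouette width on a uniformly subsampled subset of rows (distance
#' matrix computed once), and returns the model at the silhouette argmax
#' (ties broken toward the smallest k).
#'
#' @param comp composition matrix from [neighborhood_composition()].
#' @param k_range candidate niche counts (default 5:35).
#' @param seed integer seed driving subsampling and all restarts.
#' @param restarts k-means restarts per k (default 10).
#' @param sil_cap maximum rows used for silhouette evaluation (default
#'   10000); full silhouette is quadratic in rows.
#' @param proportions cluster on row-proportions instead of raw counts
#'   (default FALSE: raw counts preserve density-driven niches).
#' @return a `niche_model`: list with `k_selected`, `centroids`, `labels`
#'   (1..k per cell), `silhouette_by_k`, `k_range`, `seed`.
#' @export
fit_niches <- function(comp, k_range = 5:35, seed = 1L, restarts = 10,
                       sil_cap = 10000, proportions = FALSE) {
  x <- as.matrix(comp)
  storage.mode(x) <- "double"
  if (proportions) {
    rs <- rowSums(x)
    rs[rs == 0] <- 1
    x <- x / rs
  }
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n_cells - 1]", call. = FALSE)
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct == 1) {
    stop("degenerate input: all composition rows identical", call. = FALSE)
  }
  seeds <- seed_stream(seed, 1 + length(k_range) * restarts)
  sub <- if (n > sil_cap) {
    with_seed(seeds[1], sort(sample.int(n, sil_cap)))
  } else seq_len(n)
  d_sub <- stats::dist(x[sub, , drop = FALSE])

  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  si <- 1L
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (k > n_distinct) { si <- si + restarts; next }
    best <- NULL
    for (r in seq_len(restarts)) {
      si <- si + 1L
      fit <- with_seed(seeds[si], try(
        stats::kmeans(x, centers = k, iter.max = 100, nstart = 1),
        silent = TRUE))
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) next
    fits[[ki]] <- best
    lab_sub <- best$cluster[sub]
    if (length(unique(lab_sub)) < 2) next
    sw <- cluster::silhouette(lab_sub, d_sub)
    sil[ki] <- mean(sw[, "sil_width"])
  }
  if (all(is.na(sil))) stop("no k in k_range produced a valid clustering",
                            call. = FALSE)
  best_k <- which(sil == max(sil, na.rm = TRUE))[1]  # ties -> smallest k
  model <- fits[[best_k]]
  structure(list(k_selected = k_range[best_k],
                 centroids = model$centers,
                 labels = unname(model$cluster),
                 silhouette_by_k = sil,
                 k_range = k_range,
                 proportions = proportions,
                 seed = as.integer(seed)),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat("niche_model: k =", x$k_selected, "selected from {",
      paste(range(x$k_range), collapse = "-"), "} by silhouette (",
      format(max(x$silhouette_by_k, na.rm = TRUE), digits = 3), ");",
      length(x$labels), "cells\n")
  invisible(x)
}

#' Cell-type enrichment per niche by standardized residuals
#'
#' Builds the niches x cell-types contingency table, computes the
#' chi-squared independence test, and converts each cell's standardized
#' residual `(obs - exp) / sqrt(exp (1 - row/n) (1 - col/n))` to a two-sided
#' normal-tail p-value, Bonferroni-corrected over all N x C table cells. A
#' (niche, type) pair is flagged enriched when the corrected p is below
#' `alpha` and the residual is positive.
#'
#' @param labels per-cell niche identifiers.
#' @param types per-cell cell-type labels (same length).
#' @param alpha family-wise significance level (default 0.05).
#' @return an `enrichment_table` data.frame with columns `niche`,
#'   `cell_type`, `observed`, `expected`, `std_residual`, `p_raw`,
#'   `p_bonferroni`, `enriched`; attributes `chi2_total`, `dof`.
#' @export
niche_enrichment <- function(labels, types, alpha = 0.05) {
  stopifnot(length(labels) == length(types))
  if (!is.factor(labels)) labels <- factor(as.character(labels))
  if (!is.factor(types)) types <- factor(as.character(types))
  tab <- table(niche = labels, cell_type = types)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " empty niche(s) and ", sum(zc),
            " empty type(s); dof recomputed")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least 2 niches and 2 cell types with nonzero totals",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- ct$stdres
  p_raw <- 2 * stats::pnorm(-abs(res))
  m <- nrow(tab) * ncol(tab)
  p_bonf <- pmin(1, p_raw * m)
  out <- data.frame(
    niche = rep(rownames(tab), ncol(tab)),
    cell_type = rep(colnames(tab), each = nrow(tab)),
    observed = as.vector(tab),
    expected = as.vector(ct$expected),
    std_residual = as.vector(res),
    p_raw = as.vector(p_raw),
    p_bonferroni = as.vector(p_bonf),
    stringsAsFactors = FALSE)
  out$enriched <- out$p_bonferroni < alpha & out$std_residual > 0
  attr(out, "chi2_total") <- unname(ct$statistic)
  attr(out, "dof") <- unname(ct$parameter)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
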