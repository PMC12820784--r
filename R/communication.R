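# Cell-cell communication: marker detection, ligand-receptor interaction
# scoring under expression-fraction thresholds, spatial-niche constraint,
# weighted network assembly and proximity-expression profiling.

#' Library-size normalization to (log) transcripts-per-10k
#'
#' @param expr an [expression_matrix()] of raw counts.
#' @param log1p apply `log1p` after scaling (default TRUE: logTP10K).
#' @return a normalized `expression_matrix`.
#' @export
normalize_tp10k <- function(expr, log1p = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$normalized) return(expr)
  libs <- Matrix::colSums(expr$counts)
  libs[libs == 0] <- 1
  m <- expr$counts %*% Matrix::Diagonal(x = 1e4 / libs)
  if (log1p) m@x <- log1p(m@x)
  dimnames(m) <- dimnames(expr$counts)
  expression_matrix(m, normalized = TRUE)
}

ensure_normalized <- function(expr) {
  if (expr$normalized) expr else normalize_tp10k(expr)
}

#' Marker thresholds for specificity and relevance filtering
#'
#' Defaults follow the strictest specificity filter used for
#' disease-fibroblast markers: rank-sum p below 0.05, log fold change above
#' 3, expressed in more than 25% of the foreground type and fewer than 10%
#' of the background; the relevance threshold `tau_expr` (5%) is the
#' expression fraction a gene must exceed before it can participate in an
#' interaction.
#'
#' @param p_max,min_lfc,min_frac_fg,max_frac_bg specificity thresholds.
#' @param tau_expr interaction-relevance expression fraction.
#' @return a `marker_config` list.
#' @export
marker_config <- function(p_max = 0.05, min_lfc = 3, min_frac_fg = 0.25,
                          max_frac_bg = 0.10, tau_expr = 0.05) {
  stopifnot(min_frac_fg >= 0, min_frac_fg <= 1,
            max_frac_bg >= 0, max_frac_bg <= 1,
            tau_expr >= 0, tau_expr <= 1)
  structure(list(p_max = p_max, min_lfc = min_lfc,
                 min_frac_fg = min_frac_fg, max_frac_bg = max_frac_bg,
                 tau_expr = tau_expr), class = "marker_config")
}

#' One-vs-rest Wilcoxon rank-sum marker detection
#'
#' For every (gene, cell type): rank-sum test of the type's cells against
#' all other cells on normalized expression, BH adjustment within type, log
#' fold change of pseudocounted means, and expressing-cell fractions. All
#' rows are retained; filtering is a separate step ([filter_markers()]).
#'
#' @param expr an [expression_matrix()]; raw counts are logTP10K-normalized
#'   internally.
#' @param labels per-cell type labels aligned with `expr` columns.
#' @return a [de_table()] with one row per (gene, type).
#' @export
detect_markers <- function(expr, labels) {
  stopifnot(inherits(expr, "expression_matrix"))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expr$counts))
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  norm <- ensure_normalized(expr)$counts
  genes <- rownames(norm)
  rows <- vector("list", length(types))
  for (ti in seq_along(types)) {
    fg <- labels == types[ti]
    if (sum(fg) < 2 || sum(!fg) < 2) {
      stop("need at least 2 cells per compared group", call. = FALSE)
    }
    mfg <- as.matrix(norm[, fg, drop = FALSE])
    mbg <- as.matrix(norm[, !fg, drop = FALSE])
    p <- vapply(seq_along(genes), function(g) {
      suppressWarnings(
        stats::wilcox.test(mfg[g, ], mbg[g, ], exact = FALSE)$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1  # constant gene across both groups
    mean_fg <- rowMeans(expm1(mfg))
    mean_bg <- rowMeans(expm1(mbg))
    rows[[ti]] <- data.frame(
      gene = genes, group = types[ti],
      log_fold_change = log((mean_fg + 1) / (mean_bg + 1)),
      p_value = p,
      adjusted_p = stats::p.adjust(p, method = "BH"),
      frac_fg = rowMeans(mfg > 0),
      frac_bg = rowMeans(mbg > 0),
      stringsAsFactors = FALSE)
  }
  de_table(do.call(rbind, rows))
}

#' Apply a specificity filter to a DE table
#'
#' @param de a [de_table()].
#' @param cfg a [marker_config()]; rows pass when `p_value < p_max`,
#'   `log_fold_change > min_lfc`, `frac_fg > min_frac_fg` and
#'   `frac_bg < max_frac_bg`.
#' @return the passing subset of `de`.
#' @export
filter_markers <- function(de, cfg = marker_config()) {
  stopifnot(inherits(de, "de_table"), inherits(cfg, "marker_config"))
  keep <- de$p_value < cfg$p_max &
    de$log_fold_change > cfg$min_lfc &
    de$frac_fg > cfg$min_frac_fg &
    de$frac_bg < cfg$max_frac_bg
  de[keep, , drop = FALSE]
}

# upregulated-gene sets per type from a DE table
de_up_sets <- function(de, p_max = 0.05) {
  up <- de[!is.na(de$adjusted_p) & de$adjusted_p < p_max &
             de$log_fold_change > 0, ]
  split(up$gene, up$group)
}

#' Score ligand-receptor interactions between all cell-type pairs
#'
#' For each LR pair and each ordered (sender, receiver) type pair, the
#' interaction is *relevant* when the ligand is expressed in more than
#' `tau_expr` of sender cells and the receptor in more than `tau_expr` of
#' receiver cells; it is *significant* when additionally the ligand is a
#' DE-upregulated gene of the sender or the receptor of the receiver. The
#' score is the product of the two genes' mean normalized expressions after
#' per-gene min-max scaling across cell types, so it lies in [0, 1] and is
#' monotone in both partners.
#'
#' @param expr an [expression_matrix()].
#' @param labels per-cell type labels.
#' @param de a [de_table()] supplying upregulated genes per type.
#' @param lrdb an [lr_database()]. Pairs whose genes are absent from the
#'   matrix are skipped with a warning.
#' @param tau_expr relevance expression-fraction threshold (default 0.05).
#' @param de_p_max adjusted-p cut defining DE support (default 0.05).
#' @return data.frame of interaction scores with columns `sender`, `ligand`,
#'   `receiver`, `receptor`, `score`, `relevant`, `significant`.
#' @export
score_interactions <- function(expr, labels, de, lrdb, tau_expr = 0.05,
                               de_p_max = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(lrdb, "lr_database"))
  labels <- as.character(labels)
  norm <- ensure_normalized(expr)$counts
  types <- sort(unique(labels))
  genes_used <- unique(c(lrdb$ligand, lrdb$receptor))
  absent <- setdiff(genes_used, rownames(norm))
  if (length(absent)) {
    warning("LR genes absent from expression matrix, pairs skipped: ",
            paste(absent, collapse = ", "))
  }
  keep <- lrdb$ligand %in% rownames(norm) & lrdb$receptor %in% rownames(norm)
  pairs <- lrdb[keep, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  if (!nrow(pairs)) {
    return(data.frame(sender = character(), ligand = character(),
                      receiver = character(), receptor = character(),
                      score = numeric(), relevant = logical(),
                      significant = logical()))
  }
  sub <- norm[genes, , drop = FALSE]
  mean_by_type <- do.call(cbind, lapply(types, function(t) {
    Matrix::rowMeans(sub[, labels == t, drop = FALSE])
  }))
  frac_by_type <- do.call(cbind, lapply(types, function(t) {
    Matrix::rowMeans(sub[, labels == t, drop = FALSE] > 0)
  }))
  dimnames(mean_by_type) <- dimnames(frac_by_type) <- list(genes, types)
  rng <- apply(mean_by_type, 1, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- (mean_by_type - rng[1, ]) / ifelse(span > 0, span, 1)
  scaled[span == 0, ] <- 0

  up <- de_up_sets(de, de_p_max)
  grid <- expand.grid(pair = seq_len(nrow(pairs)),
                      sender = types, receiver = types,
                      stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]
  rec <- pairs$receptor[grid$pair]
  relevant <- frac_by_type[cbind(lig, grid$sender)] > tau_expr &
    frac_by_type[cbind(rec, grid$receiver)] > tau_expr
  de_sup <- mapply(function(l, s, r, rv) {
    (l %in% up[[s]]) || (r %in% up[[rv]])
  }, lig, grid$sender, rec, grid$receiver)
  out <- data.frame(sender = grid$sender, ligand = lig,
                    receiver = grid$receiver, receptor = rec,
                    score = scaled[cbind(lig, grid$sender)] *
                      scaled[cbind(rec, grid$receiver)],
                    relevant = relevant,
                    significant = relevant & de_sup,
                    stringsAsFactors = FALSE)
  out[out$relevant, , drop = FALSE]
}

#' Constrain interactions to niche co-membership
#'
#' Retains an interaction only when its sender and receiver types are both
#' flagged as enriched in at least one common niche.
#'
#' @param scores interaction data.frame from [score_interactions()].
#' @param enr an `enrichment_table` from [niche_enrichment()].
#' @return the retained subset of `scores`.
#' @export
constrain_by_niche <- function(scores, enr) {
  stopifnot(inherits(enr, "enrichment_table"))
  flagged <- enr[enr$enriched, c("niche", "cell_type")]
  niches_of <- split(flagged$niche, flagged$cell_type)
  used <- unique(c(scores$sender, scores$receiver))
  missing <- setdiff(used, enr$cell_type)
  if (length(missing)) {
    warning("cell types absent from enrichment table are enriched nowhere: ",
            paste(missing, collapse = ", "))
  }
  co <- mapply(function(s, r) {
    length(intersect(niches_of[[s]], niches_of[[r]])) > 0
  }, scores$sender, scores$receiver)
  scores[as.logical(co), , drop = FALSE]
}

#' Assemble the weighted directed communication network
#'
#' Edge weight for sender -> receiver is the sum of the scores of its
#' significant interactions; non-significant interactions contribute
#' nothing, and an edge exists only when at least one significant
#' interaction supports it.
#'
#' @param scores interaction data.frame (typically niche-constrained).
#' @return an `interaction_network`: list with `edges` (data.frame `sender`,
#'   `receiver`, `weight`, `n_significant_interactions`) and `nodes`.
#' @export
build_network <- function(scores) {
  sig <- scores[scores$significant, , drop = FALSE]
  if (!nrow(sig)) {
    edges <- data.frame(sender = character(), receiver = character(),
                        weight = numeric(),
                        n_significant_interactions = integer())
  } else {
    key <- paste(sig$sender, sig$receiver, sep = "\r")
    w <- tapply(sig$score, key, sum)
    n <- tapply(sig$score, key, length)
    sr <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(sender = sr[, 1], receiver = sr[, 2],
                        weight = as.numeric(w),
                        n_significant_interactions = as.integer(n),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$sender, edges$receiver), ]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(scores$sender, scores$receiver)))),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$nodes), "cell types,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Expression of a gene in target cells as a function of sender proximity
#'
#' For every target-type cell, the distance to the nearest source-type cell
#' in the same sample is computed and binned; each bin reports the number of
#' target cells, the mean normalized expression of `gene` and the fraction
#' expressing it. Samples without source cells are excluded with a warning.
#'
#' @param cells a [cell_table()].
#' @param expr an [expression_matrix()] aligned to `cells`.
#' @param source_type,target_type cell types.
#' @param gene query gene.
#' @param bin_edges left-closed distance bin edges in micrometres
#'   (default `c(0, 30, 60, 100, 200, Inf)`).
#' @return a `proximity_profile` data.frame (`bin`, `d_min`, `d_max`, `n`,
#'   `mean_expr`, `frac_expr`) with per-cell distances and expressions in
#'   attribute `cell_data`.
#' @export
proximity_profile <- function(cells, expr, source_type, target_type, gene,
                              bin_edges = c(0, 30, 60, 100, 200, Inf)) {
  stopifnot(inherits(cells, "cell_table"), inherits(expr, "expression_matrix"))
  if (!gene %in% rownames(expr$counts)) {
    stop("gene '", gene, "' absent from expression matrix", call. = FALSE)
  }
  norm <- ensure_normalized(expr)$counts
  ev <- as.numeric(norm[gene, match(cells$cell_id, colnames(norm))])
  d_all <- rep(NA_real_, nrow(cells))
  any_source <- FALSE
  for (sid in unique(cells$sample_id)) {
    in_s <- cells$sample_id == sid
    src <- in_s & cells$cell_type == source_type
    tgt <- which(in_s & cells$cell_type == target_type)
    if (!any(src)) {
      if (length(tgt)) warning("sample '", sid,
                               "' has no source cells; excluded")
      next
    }
    any_source <- TRUE
    if (length(tgt)) {
      d_all[tgt] <- nearest_distance(cells$x_um[tgt], cells$y_um[tgt],
                                     cells$x_um[src], cells$y_um[src])
    }
  }
  if (!any_source) stop("no source cells in any sample", call. = FALSE)
  keep <- !is.na(d_all)
  d <- d_all[keep]; e <- ev[keep]
  if (!length(d)) stop("no target cells in samples with source cells",
                       call. = FALSE)
  bin <- cut(d, breaks = bin_edges, right = FALSE, include.lowest = FALSE)
  out <- data.frame(
    bin = levels(bin),
    d_min = bin_edges[-length(bin_edges)],
    d_max = bin_edges[-1],
    n = as.integer(table(bin)),
    mean_expr = as.numeric(tapply(e, bin, mean)),
    frac_expr = as.numeric(tapply(e, bin, function(v) mean(v > 0))),
    stringsAsFactors = FALSE)
  attr(out, "cell_data") <- data.frame(distance = d, expression = e)
  attr(out, "gene") <- gene
  class(out) <- c("proximity_profile", "data.frame")
  out
}
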