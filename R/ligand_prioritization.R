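# TF-to-ligand prioritization funnel: TFs active in the target population
# are selected by two routes (marker expression and inferred activity), each
# selected TF votes for its top ligands by regulatory potential, and the
# shortlist is restricted to ligands with an expressed receptor.

#' Select target-population transcription factors by two routes
#'
#' Expression route: target-type marker genes intersected with the TF
#' universe (rank-sum `p_value < p_expr`, positive log fold change).
#' Activity route: TFs whose mean activity in target cells exceeds the
#' background mean by more than `min_activity_diff` with rank-sum
#' `p < p_activity`. The returned selection carries both routes and their
#' union.
#'
#' @param markers a [de_table()] of per-type markers.
#' @param activity cells x TFs activity matrix.
#' @param activity_labels per-cell labels aligned to `activity` rows.
#' @param target_type label of the target population.
#' @param tf_universe character vector of known TF symbols.
#' @param min_activity_diff activity-route mean-difference threshold
#'   (default 0.75).
#' @param p_activity activity-route p threshold (default 0.01).
#' @param p_expr expression-route p threshold (default 0.05).
#' @return a `tf_selection` list with `expression_route`, `activity_route`,
#'   `union` and the thresholds used.
#' @export
select_tfs <- function(markers, activity, activity_labels, target_type,
                       tf_universe, min_activity_diff = 0.75,
                       p_activity = 0.01, p_expr = 0.05) {
  stopifnot(inherits(markers, "de_table"))
  if (!length(tf_universe)) stop("empty TF universe", call. = FALSE)
  m <- markers[markers$group == target_type &
                 markers$gene %in% tf_universe &
                 markers$p_value < p_expr &
                 markers$log_fold_change > 0, ]
  expression_route <- sort(unique(m$gene))

  labels <- as.character(activity_labels)
  stopifnot(length(labels) == nrow(activity))
  fg <- labels == target_type
  if (!any(fg) || all(fg)) {
    stop("target type must be present with a non-empty background",
         call. = FALSE)
  }
  tfs <- colnames(activity)
  diff <- colMeans(activity[fg, , drop = FALSE]) -
    colMeans(activity[!fg, , drop = FALSE])
  p <- vapply(tfs, function(tf) {
    suppressWarnings(stats::wilcox.test(activity[fg, tf], activity[!fg, tf],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  activity_route <- sort(tfs[diff > min_activity_diff & p < p_activity])

  structure(list(expression_route = expression_route,
                 activity_route = activity_route,
                 union = sort(unique(c(expression_route, activity_route))),
                 thresholds = list(min_activity_diff = min_activity_diff,
                                   p_activity = p_activity,
                                   p_expr = p_expr)),
            class = "tf_selection")
}

#' @export
print.tf_selection <- function(x, ...) {
  cat("tf_selection:", length(x$expression_route), "by expression,",
      length(x$activity_route), "by activity,",
      length(x$union), "unique TFs\n")
  invisible(x)
}

#' Vote ligands through a regulatory-potential matrix
#'
#' Each selected TF contributes one vote to each of its `top_n` ligands by
#' regulatory-potential score (ties broken by ligand label so vote counts
#' are reproducible); ligands with at least `min_votes` votes are retained,
#' sorted by votes descending then label ascending.
#'
#' @param tfs a `tf_selection` or character vector of TF names.
#' @param rp ligands x TFs regulatory-potential matrix.
#' @param top_n ligands voted per TF (default 10).
#' @param min_votes retention threshold (default 5).
#' @return data.frame with columns `ligand`, `votes`.
#' @export
vote_ligands <- function(tfs, rp, top_n = 10, min_votes = 5) {
  if (inherits(tfs, "tf_selection")) tfs <- tfs$union
  if (nrow(rp) < top_n) {
    stop("regulatory-potential matrix has fewer than top_n (", top_n,
         ") ligands", call. = FALSE)
  }
  absent <- setdiff(tfs, colnames(rp))
  if (length(absent)) {
    warning("TFs absent from regulatory-potential matrix dropped: ",
            paste(absent, collapse = ", "))
    tfs <- setdiff(tfs, absent)
  }
  ligands <- rownames(rp)
  votes <- integer(length(ligands))
  names(votes) <- ligands
  for (tf in tfs) {
    ord <- order(-rp[, tf], ligands)
    votes[ligands[ord[seq_len(top_n)]]] <-
      votes[ligands[ord[seq_len(top_n)]]] + 1L
  }
  keep <- votes >= min_votes
  out <- data.frame(ligand = names(votes)[keep], votes = unname(votes[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$votes, out$ligand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top_n") <- top_n
  attr(out, "min_votes") <- min_votes
  out
}

#' Restrict voted ligands to those with an expressed receptor
#'
#' A ligand is kept when at least one cognate receptor (from the LR
#' database) is expressed in more than `tau` of the target-type cells.
#' Ligands with no receptor entry are dropped with a warning.
#'
#' @param ligands data.frame from [vote_ligands()] (columns `ligand`,
#'   `votes`) or a character vector.
#' @param lrdb an [lr_database()].
#' @param expr an [expression_matrix()].
#' @param labels per-cell type labels aligned to `expr` columns.
#' @param target_type receiver population whose receptor expression gates
#'   the ligand.
#' @param tau receptor expression-fraction threshold (default 0.05).
#' @return a `ligand_shortlist` data.frame with `ligand`, `votes`,
#'   `receptors` (comma-joined expressed receptors); parameters in
#'   attributes.
#' @export
filter_by_receptor <- function(ligands, lrdb, expr, labels, target_type,
                               tau = 0.05) {
  stopifnot(inherits(lrdb, "lr_database"), inherits(expr, "expression_matrix"))
  if (is.character(ligands)) {
    ligands <- data.frame(ligand = ligands, votes = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  labels <- as.character(labels)
  if (!target_type %in% labels) {
    stop("target type '", target_type, "' not present in labels",
         call. = FALSE)
  }
  tgt <- expr$counts[, labels == target_type, drop = FALSE]
  frac <- Matrix::rowMeans(tgt > 0)
  keep <- logical(nrow(ligands))
  receptors <- character(nrow(ligands))
  for (i in seq_len(nrow(ligands))) {
    rec <- lrdb$receptor[lrdb$ligand == ligands$ligand[i]]
    if (!length(rec)) {
      warning("ligand '", ligands$ligand[i],
              "' has no receptor in the LR database; dropped")
      next
    }
    expressed <- rec[rec %in% names(frac) & frac[rec] > tau]
    if (length(expressed)) {
      keep[i] <- TRUE
      receptors[i] <- paste(sort(expressed), collapse = ",")
    }
  }
  out <- ligands[keep, , drop = FALSE]
  out$receptors <- receptors[keep]
  rownames(out) <- NULL
  attr(out, "tau") <- tau
  attr(out, "target_type") <- target_type
  class(out) <- c("ligand_shortlist", "data.frame")
  out
}

#' Expand a ligand shortlist by family membership
#'
#' Optional final step: joins a user-supplied two-column family table
#' (`ligand`, `family`) and returns all family members of shortlisted
#' ligands.
#'
#' @param shortlist a `ligand_shortlist`.
#' @param families data.frame with columns `ligand`, `family`.
#' @return character vector of expanded ligand symbols.
#' @export
expand_by_family <- function(shortlist, families) {
  stopifnot(all(c("ligand", "family") %in% names(families)))
  fams <- unique(families$family[families$ligand %in% shortlist$ligand])
  sort(unique(c(shortlist$ligand,
                families$ligand[families$family %in% fams])))
}
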