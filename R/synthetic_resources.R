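# Synthetic ligand-receptor / regulatory-potential / TF-activity resources
# with planted support, emulating the inputs of the TF-to-ligand funnel.

#' Build a configuration for synthetic prioritization resources
#'
#' @param tfs transcription-factor names (columns of the regulatory
#'   potential matrix and of the activity matrix).
#' @param n_decoy_ligands exchangeable decoy ligands. The default 150 keeps
#'   the chance that any decoy reaches 5 votes in a top-10-of-8-TFs funnel
#'   far below 5% (union bound ~1%).
#' @param planted_support named list: planted ligand -> character vector of
#'   TFs in whose top-`top_n` list it must appear. May be empty (pure null).
#' @param top_n funnel depth the construction guarantees ranks against.
#' @param active_tfs TFs given a planted activity shift in the target cells.
#' @param expression_route_tfs TFs planted as expression-route markers of
#'   the target cells (emitted as a ready-made marker DE table).
#' @param activity_diff planted mean activity difference (target minus
#'   background) for `active_tfs`.
#' @param n_target_cells,n_background_cells cells in the activity matrix.
#' @param activity_sd cell-level activity noise.
#' @param seed master seed.
#' @return an `lr_resource_config` list.
#' @export
lr_resource_config <- function(tfs = paste0("TF", 1:8),
                               n_decoy_ligands = 150,
                               planted_support = list(
                                 TGFB1 = paste0("TF", 1:6),
                                 IL1B = paste0("TF", 1:5)),
                               top_n = 10,
                               active_tfs = tfs,
                               expression_route_tfs = tfs[1:2],
                               activity_diff = 1.0,
                               n_target_cells = 100,
                               n_background_cells = 300,
                               activity_sd = 0.5,
                               seed = 1L) {
  if (n_decoy_ligands < top_n) {
    stop_config("need at least top_n (", top_n, ") decoy ligands")
  }
  bad <- setdiff(unlist(planted_support), tfs)
  if (length(bad)) stop_config("planted support names unknown TFs: ",
                               paste(bad, collapse = ", "))
  structure(list(tfs = tfs, n_decoy_ligands = n_decoy_ligands,
                 planted_support = planted_support, top_n = top_n,
                 active_tfs = active_tfs,
                 expression_route_tfs = expression_route_tfs,
                 activity_diff = activity_diff,
                 n_target_cells = n_target_cells,
                 n_background_cells = n_background_cells,
                 activity_sd = activity_sd, seed = as.integer(seed)),
            class = "lr_resource_config")
}

#' Generate synthetic prioritization resources with planted ground truth
#'
#' Produces (i) a ligand-receptor database covering planted and decoy
#' ligands, (ii) a ligand x TF regulatory-potential matrix in which each
#' planted ligand ranks inside the top-`top_n` for exactly its supporting
#' TFs (scores 1.5-2 versus decoys on 0.01-1, and 0 elsewhere), and (iii) a
#' cells x TF activity matrix with a planted mean shift in target cells.
#'
#' @param config an [lr_resource_config()].
#' @return list with `lrdb` ([lr_database()]), `rp` (ligands x TFs matrix),
#'   `activity` (cells x TFs matrix), `activity_labels` (cell labels,
#'   `"target"`/`"background"`), `tf_markers` (a [de_table()] planting the
#'   expression route), `receptor_expr` (receptors x cells
#'   [expression_matrix()] in which planted receptors are expressed in
#'   roughly half the target cells and decoy receptors in ~1%) and `truth`
#'   (planted support pattern).
#' @export
generate_lr_resources <- function(config) {
  stopifnot(inherits(config, "lr_resource_config"))
  seeds <- seed_stream(config$seed, 3)
  planted <- names(config$planted_support)
  decoys <- sprintf("LGND%03d", seq_len(config$n_decoy_ligands))
  ligands <- c(planted, decoys)
  tfs <- config$tfs

  rp <- with_seed(seeds[1], {
    m <- matrix(stats::runif(length(decoys) * length(tfs), 0.01, 1),
                nrow = length(decoys),
                dimnames = list(decoys, tfs))
    if (length(planted)) {
      pm <- matrix(0, length(planted), length(tfs),
                   dimnames = list(planted, tfs))
      for (lg in planted) {
        sup <- config$planted_support[[lg]]
        pm[lg, sup] <- stats::runif(length(sup), 1.5, 2)
      }
      m <- rbind(pm, m)
    }
    m
  })

  receptors <- c(if (length(planted)) stats::setNames(paste0(planted, "_R"), planted),
                 stats::setNames(sub("LGND", "RCPT", decoys), decoys))
  # keep the field's names for the canonical planted agonists
  receptors[names(receptors) == "TGFB1"] <- "TGFBR1"
  receptors[names(receptors) == "IL1B"] <- "IL1R1"
  lrdb <- lr_database(data.frame(ligand = ligands,
                                 receptor = unname(receptors[ligands]),
                                 stringsAsFactors = FALSE))

  n_cells <- config$n_target_cells + config$n_background_cells
  labels <- rep(c("target", "background"),
                c(config$n_target_cells, config$n_background_cells))
  activity <- with_seed(seeds[2], {
    a <- matrix(stats::rnorm(n_cells * length(tfs), 0, config$activity_sd),
                nrow = n_cells,
                dimnames = list(sprintf("cell%04d", seq_len(n_cells)), tfs))
    a[labels == "target", config$active_tfs] <-
      a[labels == "target", config$active_tfs] + config$activity_diff
    a
  })

  expr_tfs <- config$expression_route_tfs
  tf_markers <- de_table(data.frame(
    gene = tfs, group = "target",
    log_fold_change = ifelse(tfs %in% expr_tfs, 2, 0),
    p_value = ifelse(tfs %in% expr_tfs, 1e-6, 0.9),
    adjusted_p = ifelse(tfs %in% expr_tfs, 1e-5, 0.95),
    frac_fg = ifelse(tfs %in% expr_tfs, 0.6, 0.1),
    frac_bg = 0.05, stringsAsFactors = FALSE))

  planted_rec <- receptors[planted]
  receptor_expr <- with_seed(seeds[3], {
    recs <- unname(receptors)
    m <- matrix(0, length(recs), n_cells,
                dimnames = list(recs, rownames(activity)))
    is_t <- labels == "target"
    for (r in recs) {
      p_expr <- if (r %in% planted_rec) 0.5 else 0.01
      on <- stats::runif(n_cells) < ifelse(is_t, p_expr, 0.02)
      m[r, on] <- stats::rpois(sum(on), 3) + 1
    }
    expression_matrix(m, normalized = FALSE)
  })

  list(lrdb = lrdb, rp = rp, activity = activity, activity_labels = labels,
       tf_markers = tf_markers, receptor_expr = receptor_expr,
       truth = list(planted_support = config$planted_support,
                    active_tfs = config$active_tfs,
                    expression_route_tfs = expr_tfs))
}
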