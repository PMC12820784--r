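# End-to-end orchestration: plain files between stages, a single seed tree,
# dry-run dependency validation, and a digest manifest so identical
# config + inputs yield identical outputs.

#' Build a pipeline run configuration
#'
#' @param out_dir directory for all stage outputs.
#' @param seed master seed for every stage.
#' @param stages named logical vector toggling `simulate`, `niches`,
#'   `enrichment`, `abundance`, `communication`, `prioritization`,
#'   `scoring`.
#' @param params list of analysis parameters: `r_um` (neighborhood radius),
#'   `k_range` (length-2 min/max candidate niche counts), `sil_cap`
#'   (silhouette subsample), `tau_expr`, `top_n`, `min_votes`, `fdr`,
#'   `reference_type` (abundance reference category), `source_type`,
#'   `target_type`, `circuit_gene` (proximity profile query), and
#'   `n_per_condition` for the simulated atlas.
#' @param inputs named list of input paths; every path a stage needs must
#'   either exist or be produced by an earlier enabled stage. Defaults point
#'   into `out_dir` (where the simulate stage writes them).
#' @return a `run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c(simulate = TRUE, niches = TRUE,
                                       enrichment = TRUE, abundance = TRUE,
                                       communication = TRUE,
                                       prioritization = TRUE,
                                       scoring = TRUE),
                            params = list(), inputs = list()) {
  defaults <- list(r_um = 30, k_range = c(5, 35), sil_cap = 10000,
                   restarts = 10, tau_expr = 0.05, top_n = 10, min_votes = 5,
                   fdr = 0.20, reference_type = "SMC",
                   source_type = "ActMac", target_type = "IAF",
                   circuit_gene = "IL11", n_per_condition = 2,
                   ssgsea_alpha = 0.25)
  params <- utils::modifyList(defaults, params)
  all_stages <- c("simulate", "niches", "enrichment", "abundance",
                  "communication", "prioritization", "scoring")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  file_defaults <- list(
    cells = "cells.tsv", expr_mtx = "expr.mtx", expr_genes = "genes.tsv",
    expr_cells = "barcodes.tsv", lr = "lr.tsv", rp = "rp.tsv",
    activity = "activity.tsv", tf_markers = "tf_markers.tsv",
    receptor_expr = "receptor_expr.tsv", profiles = "profiles.tsv",
    severity = "severity.tsv", signature = "signature.txt")
  paths <- lapply(file_defaults, function(f) file.path(out_dir, f))
  paths[names(inputs)] <- inputs
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = st,
                 params = params, inputs = paths),
            class = "run_config")
}

stage_io <- function(cfg) {
  p <- cfg$inputs
  o <- function(f) file.path(cfg$out_dir, f)
  list(
    simulate = list(
      needs = character(0),
      makes = c(p$cells, p$expr_mtx, p$expr_genes, p$expr_cells, p$lr,
                p$rp, p$activity, p$tf_markers, p$receptor_expr,
                p$profiles, p$severity, p$signature)),
    niches = list(needs = p$cells,
                  makes = c(o("niche_labels.tsv"), o("silhouette.tsv"))),
    enrichment = list(needs = o("niche_labels.tsv"),
                      makes = o("enrichment.tsv")),
    abundance = list(needs = p$cells, makes = o("abundance.tsv")),
    communication = list(
      needs = c(p$cells, p$expr_mtx, p$expr_genes, p$expr_cells, p$lr,
                o("enrichment.tsv")),
      makes = c(o("markers_de.tsv"), o("network.tsv"), o("proximity.tsv"))),
    prioritization = list(
      needs = c(p$tf_markers, p$activity, p$rp, p$lr, p$receptor_expr),
      makes = o("shortlist.tsv")),
    scoring = list(
      needs = c(p$profiles, p$severity, p$signature),
      makes = c(o("ssgsea_scores.tsv"), o("severity_fit.tsv"))))
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate, niches,
#' enrichment, abundance, communication, prioritization, scoring) with all
#' randomness derived from the config seed. Inputs of every enabled stage
#' are validated before any compute; a missing upstream file raises a
#' dependency error. Writes `manifest.json` (package version, seed, input
#' and output digests) and `run_log.txt` (stage timings); identical
#' config + inputs yield identical manifest digest tables.
#'
#' @param config a [pipeline_config()] or path to a JSON file with the same
#'   fields.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- pipeline_config(
      out_dir = raw$out_dir, seed = raw$seed %||% 1L,
      stages = unlist(raw$stages %||% list()),
      params = raw$params %||% list(), inputs = raw$inputs %||% list())
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  io <- stage_io(config)
  enabled <- names(config$stages)[config$stages]

  # dry-run dependency validation before any compute
  available <- character(0)
  for (st in names(io)) {
    if (!st %in% enabled) next
    missing <- setdiff(io[[st]]$needs,
                       c(available, io[[st]]$needs[file.exists(io[[st]]$needs)]))
    if (length(missing)) {
      stop("dependency error: stage '", st, "' needs missing input(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    available <- c(available, io[[st]]$makes)
  }

  seeds <- seed_stream(config$seed, length(io))
  names(seeds) <- names(io)
  log_lines <- c(paste("seed:", config$seed))
  t_all <- proc.time()[["elapsed"]]
  for (st in enabled) {
    t0 <- proc.time()[["elapsed"]]
    switch(st,
           simulate = stage_simulate(config, seeds[st]),
           niches = stage_niches(config, seeds[st]),
           enrichment = stage_enrichment(config),
           abundance = stage_abundance(config),
           communication = stage_communication(config),
           prioritization = stage_prioritization(config),
           scoring = stage_scoring(config))
    log_lines <- c(log_lines, sprintf("stage %s: %.2f s", st,
                                      proc.time()[["elapsed"]] - t0))
  }
  log_lines <- c(log_lines, sprintf("total: %.2f s",
                                    proc.time()[["elapsed"]] - t_all))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  outputs <- unlist(lapply(io[enabled], `[[`, "makes"), use.names = FALSE)
  outputs <- outputs[file.exists(outputs)]
  digests <- as.list(tools::md5sum(sort(outputs)))
  names(digests) <- basename(names(digests))
  input_files <- setdiff(unlist(lapply(io[enabled], `[[`, "needs"),
                                use.names = FALSE), outputs)
  input_digests <- as.list(tools::md5sum(sort(input_files[file.exists(input_files)])))
  if (length(input_digests)) names(input_digests) <- basename(names(input_digests))
  manifest <- list(
    package = "nichecircuit",
    version = as.character(utils::packageVersion("nichecircuit")),
    seed = config$seed,
    stages = as.list(config$stages),
    params = config$params,
    inputs = input_digests,
    outputs = digests)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(cfg, seed) {
  p <- cfg$inputs
  seeds <- seed_stream(seed, 3)
  tis <- generate_tissue(config_atlas(seed = seeds[1],
                                      n_per_condition = cfg$params$n_per_condition))
  write_cell_table(tis$cells, p$cells)
  write_expression(tis$expr, p$expr_mtx, p$expr_genes, p$expr_cells)

  cc <- tis$truth$circuit
  tissue_pairs <- data.frame(
    ligand = c(cc$ligand, "TCell.mk1", "HK1", "HK3"),
    receptor = c(cc$receptor, "Epithelial.mk1", "HK2", "HK4"),
    stringsAsFactors = FALSE)

  res <- generate_lr_resources(lr_resource_config(seed = seeds[2]))
  combined <- unique(rbind(as.data.frame(res$lrdb)[, c("ligand", "receptor")],
                           tissue_pairs))
  write_tsv_file(as.data.frame(lr_database(combined)), p$lr)
  write_tsv_file(data.frame(ligand = rownames(res$rp), res$rp,
                            check.names = FALSE), p$rp)
  write_tsv_file(data.frame(cell = rownames(res$activity),
                            label = res$activity_labels, res$activity,
                            check.names = FALSE), p$activity)
  write_tsv_file(as.data.frame(res$tf_markers), p$tf_markers)
  write_tsv_file(data.frame(cell = colnames(res$receptor_expr$counts),
                            label = res$activity_labels,
                            as.matrix(Matrix::t(res$receptor_expr$counts)),
                            check.names = FALSE), p$receptor_expr)

  coh <- generate_cohort(cohort_config(seed = seeds[3]))
  write_tsv_file(data.frame(gene = rownames(coh$profiles), coh$profiles,
                            check.names = FALSE), p$profiles)
  write_tsv_file(data.frame(subject = colnames(coh$profiles),
                            severity = as.integer(coh$severity)), p$severity)
  writeLines(coh$truth$signature, p$signature)
  invisible(NULL)
}

stage_niches <- function(cfg, seed) {
  cells <- read_cell_table(cfg$inputs$cells)
  comp <- neighborhood_composition(cells, r_um = cfg$params$r_um)
  kr <- cfg$params$k_range
  model <- fit_niches(comp, k_range = seq(kr[1], kr[2]), seed = seed,
                      restarts = cfg$params$restarts,
                      sil_cap = cfg$params$sil_cap)
  write_tsv_file(data.frame(cell_id = cells$cell_id,
                            niche = paste0("N", model$labels)),
                 file.path(cfg$out_dir, "niche_labels.tsv"))
  write_tsv_file(data.frame(k = as.integer(names(model$silhouette_by_k)),
                            silhouette = unname(model$silhouette_by_k)),
                 file.path(cfg$out_dir, "silhouette.tsv"))
  invisible(NULL)
}

stage_enrichment <- function(cfg) {
  cells <- read_cell_table(cfg$inputs$cells)
  lab <- read_tsv_file(file.path(cfg$out_dir, "niche_labels.tsv"))
  enr <- niche_enrichment(lab$niche[match(cells$cell_id, lab$cell_id)],
                          cells$cell_type)
  out <- as.data.frame(enr)
  write_tsv_file(out, file.path(cfg$out_dir, "enrichment.tsv"))
  invisible(NULL)
}

stage_abundance <- function(cfg) {
  cells <- read_cell_table(cfg$inputs$cells)
  counts <- as.matrix(unclass(table(cells$sample_id, cells$cell_type)))
  cond <- cells$condition[match(rownames(counts), cells$sample_id)]
  tab <- count_table(counts, factor(cond, levels = unique(
    cells$condition[order(cells$sample_id)])),
    reference = cfg$params$reference_type)
  res <- test_abundance(tab, fdr = cfg$params$fdr)
  write_tsv_file(as.data.frame(res), file.path(cfg$out_dir, "abundance.tsv"))
  invisible(NULL)
}

stage_communication <- function(cfg) {
  cells <- read_cell_table(cfg$inputs$cells)
  expr <- read_expression(cfg$inputs$expr_mtx, cfg$inputs$expr_genes,
                          cfg$inputs$expr_cells)
  lrdb <- read_lr_database(cfg$inputs$lr)
  labels <- cells$cell_type[match(colnames(expr$counts), cells$cell_id)]
  de <- detect_markers(expr, labels)
  write_tsv_file(as.data.frame(de), file.path(cfg$out_dir, "markers_de.tsv"))
  enr_df <- read_tsv_file(file.path(cfg$out_dir, "enrichment.tsv"))
  class(enr_df) <- c("enrichment_table", "data.frame")
  scores <- suppressWarnings(
    score_interactions(expr, labels, de, lrdb,
                       tau_expr = cfg$params$tau_expr))
  scores <- suppressWarnings(constrain_by_niche(scores, enr_df))
  net <- build_network(scores)
  write_network(net, file.path(cfg$out_dir, "network.tsv"))
  prof <- proximity_profile(cells, expr, cfg$params$source_type,
                            cfg$params$target_type, cfg$params$circuit_gene)
  write_tsv_file(as.data.frame(prof), file.path(cfg$out_dir, "proximity.tsv"))
  invisible(NULL)
}

stage_prioritization <- function(cfg) {
  mk <- de_table(read_tsv_file(cfg$inputs$tf_markers))
  act <- read_tsv_file(cfg$inputs$activity)
  activity <- as.matrix(act[, !(names(act) %in% c("cell", "label")),
                            drop = FALSE])
  rownames(activity) <- act$cell
  rp_df <- read_tsv_file(cfg$inputs$rp)
  rp <- as.matrix(rp_df[, -1, drop = FALSE])
  rownames(rp) <- rp_df[[1]]
  lrdb <- read_lr_database(cfg$inputs$lr)
  rx <- read_tsv_file(cfg$inputs$receptor_expr)
  rex <- t(as.matrix(rx[, !(names(rx) %in% c("cell", "label")), drop = FALSE]))
  colnames(rex) <- rx$cell
  rexpr <- expression_matrix(rex, normalized = FALSE)

  tfs <- select_tfs(mk, activity, act$label, target_type = "target",
                    tf_universe = colnames(activity))
  votes <- vote_ligands(tfs, rp, top_n = cfg$params$top_n,
                        min_votes = cfg$params$min_votes)
  shortlist <- suppressWarnings(
    filter_by_receptor(votes, lrdb, rexpr, rx$label, "target",
                       tau = cfg$params$tau_expr))
  write_tsv_file(as.data.frame(shortlist),
                 file.path(cfg$out_dir, "shortlist.tsv"))
  invisible(NULL)
}

stage_scoring <- function(cfg) {
  prof_df <- read_tsv_file(cfg$inputs$profiles)
  profiles <- as.matrix(prof_df[, -1, drop = FALSE])
  rownames(profiles) <- prof_df[[1]]
  sev <- read_tsv_file(cfg$inputs$severity)
  severity <- factor(sev$severity[match(colnames(profiles), sev$subject)],
                     ordered = TRUE)
  signature <- readLines(cfg$inputs$signature)
  scores <- ssgsea_matrix(profiles, signature,
                          alpha = cfg$params$ssgsea_alpha)
  fit <- ordered_probit(scores, severity)
  write_tsv_file(data.frame(subject = names(scores), score = unname(scores),
                            severity = as.integer(severity)),
                 file.path(cfg$out_dir, "ssgsea_scores.tsv"))
  write_tsv_file(data.frame(beta = fit$beta, se_beta = fit$se_beta,
                            p_one_sided = fit$p_one_sided,
                            loglik = fit$loglik, n = fit$n),
                 file.path(cfg$out_dir, "severity_fit.tsv"))
  invisible(NULL)
}
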