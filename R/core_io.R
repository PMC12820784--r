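# Shared data model and readers/writers for the external formats the
# pipeline touches: per-cell spatial tables, sparse expression matrices,
# ligand-receptor databases, DE tables and interaction-network edge lists.

CELL_TABLE_COLS <- c("cell_id", "x_um", "y_um", "cell_type", "sample_id", "condition")

#' Construct and validate a per-cell spatial table
#'
#' A cell table holds one row per segmented cell: an identifier, planar
#' coordinates in micrometres (origin arbitrary per sample; all distance
#' logic in the package is within-sample), a cell-type label, a sample
#' identifier and a condition label.
#'
#' @param df data.frame with columns `cell_id`, `x_um`, `y_um`, `cell_type`,
#'   `sample_id`, `condition`.
#' @return validated `cell_table` (a data.frame subclass); row order preserved.
#' @export
cell_table <- function(df) {
  missing <- setdiff(CELL_TABLE_COLS, names(df))
  if (length(missing)) {
    stop_schema("missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, CELL_TABLE_COLS]
  for (col in c("x_um", "y_um")) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        stop_parse("non-numeric coordinate in column '", col,
                   "' at row ", bad[1])
      }
      v <- conv
    }
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop_parse("non-finite coordinate in column '", col, "'")
    }
    df[[col]] <- as.numeric(v)
  }
  df$cell_id <- as.character(df$cell_id)
  df$cell_type <- as.character(df$cell_type)
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  dup <- tapply(df$cell_id, df$sample_id, anyDuplicated)
  if (any(dup > 0)) {
    stop_integrity("duplicate cell_id within sample '",
                   names(dup)[which(dup > 0)[1]], "'")
  }
  rownames(df) <- NULL
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Read a cell table from TSV
#'
#' @param path TSV path with header columns `cell_id`, `x_um`, `y_um`,
#'   `cell_type`, `sample_id`, `condition`.
#' @return a validated [cell_table()].
#' @export
read_cell_table <- function(path) {
  df <- read_tsv_file(path)
  cell_table(df)
}

#' Write a cell table to TSV
#' @param cells a `cell_table`.
#' @param path output path.
#' @export
write_cell_table <- function(cells, path) {
  write_tsv_file(as.data.frame(cells), path)
}

#' Construct a sparse gene-by-cell expression matrix
#'
#' @param counts matrix or sparse Matrix, genes in rows, cells in columns.
#' @param genes,cells row/column labels; taken from dimnames when missing.
#' @param normalized logical flag: FALSE for raw counts, TRUE when values
#'   are normalized (e.g. logTP10K); the state is carried explicitly so no
#'   downstream step has to guess.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(counts, genes = rownames(counts),
                              cells = colnames(counts), normalized = FALSE) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(cells)) {
    stop_schema("gene and cell labels are required")
  }
  if (length(genes) != nrow(counts) || length(cells) != ncol(counts)) {
    stop_integrity("label lengths (", length(genes), " genes, ",
                   length(cells), " cells) do not match matrix dims ",
                   nrow(counts), "x", ncol(counts))
  }
  if (any(counts@x < 0)) stop_integrity("negative entries in counts")
  dimnames(counts) <- list(as.character(genes), as.character(cells))
  structure(list(counts = counts, normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' Read a sparse expression matrix from MatrixMarket + label files
#'
#' The MTX file is coordinate-format; duplicate coordinate entries are
#' summed. Orientation is normalized internally to genes x cells: the file
#' is accepted either way round as long as exactly one orientation matches
#' the two label files.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param genes_path,cells_path one-column header-less TSVs of labels.
#' @param normalized logical; see [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
read_expression <- function(mtx_path, genes_path, cells_path,
                            normalized = FALSE) {
  m <- Matrix::readMM(mtx_path)
  # collapse duplicate (i, j) entries by summation
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells) & !startsWith(cells, "#")]
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    # genes x cells as stored
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop_integrity("MTX dims ", nrow(m), "x", ncol(m),
                   " match neither genes (", length(genes),
                   ") x cells (", length(cells), ") nor its transpose")
  }
  expression_matrix(m, genes, cells, normalized = normalized)
}

#' Write an expression matrix as MatrixMarket + label files
#' @param expr an `expression_matrix`.
#' @param mtx_path,genes_path,cells_path output paths.
#' @export
write_expression <- function(expr, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  Matrix::writeMM(expr$counts, mtx_path)
  writeLines(rownames(expr$counts), genes_path)
  writeLines(colnames(expr$counts), cells_path)
  invisible(mtx_path)
}

#' Construct / read a ligand-receptor pair database
#'
#' Single-subunit pairs only; gene symbols are case-preserved and matched
#' exactly throughout the package.
#'
#' @param df data.frame with columns `ligand`, `receptor` and optionally
#'   `pathway`.
#' @return an `lr_database` data.frame.
#' @export
lr_database <- function(df) {
  need <- c("ligand", "receptor")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_schema("missing column(s): ",
                                   paste(missing, collapse = ", "))
  keep <- intersect(c("ligand", "receptor", "pathway"), names(df))
  df <- df[, keep, drop = FALSE]
  key <- paste(df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    stop_integrity("duplicate (ligand, receptor) pair: ",
                   sub("\r", " -> ", key[duplicated(key)][1]))
  }
  rownames(df) <- NULL
  class(df) <- c("lr_database", "data.frame")
  df
}

#' @rdname lr_database
#' @param path TSV path.
#' @export
read_lr_database <- function(path) lr_database(read_tsv_file(path))

DE_TABLE_COLS <- c("gene", "group", "log_fold_change", "p_value",
                   "adjusted_p", "frac_fg", "frac_bg")

#' Construct / read a differential-expression result table
#'
#' One row per (gene, group) where group is a cell type or contrast label.
#' Fractions are the proportion of cells expressing the gene in the
#' foreground (the group) and the background (everything else).
#'
#' @param df data.frame with columns `gene`, `group`, `log_fold_change`,
#'   `p_value`, `adjusted_p`, `frac_fg`, `frac_bg`.
#' @return a `de_table` data.frame.
#' @export
de_table <- function(df) {
  missing <- setdiff(DE_TABLE_COLS, names(df))
  if (length(missing)) stop_schema("missing column(s): ",
                                   paste(missing, collapse = ", "))
  df <- df[, DE_TABLE_COLS]
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE)) {
    stop_integrity("p_value outside [0, 1]")
  }
  if (any(df$frac_fg < 0 | df$frac_fg > 1 | df$frac_bg < 0 | df$frac_bg > 1,
          na.rm = TRUE)) {
    stop_integrity("expression fraction outside [0, 1]")
  }
  rownames(df) <- NULL
  class(df) <- c("de_table", "data.frame")
  df
}

#' @rdname de_table
#' @param path TSV path.
#' @export
read_de_table <- function(path) de_table(read_tsv_file(path))

#' Write an interaction network as a TSV edge list
#'
#' Rows are ordered lexicographically by (sender, receiver) so repeated
#' writes of the same network are byte-identical. Optionally also writes
#' GraphML when igraph is available.
#'
#' @param net an `interaction_network` (see [build_network()]).
#' @param path edge-list TSV path.
#' @param graphml_path optional GraphML output path.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  e <- net$edges
  if (nrow(e)) e <- e[order(e$sender, e$receiver), , drop = FALSE]
  write_tsv_file(e, path)
  if (!is.null(graphml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      warning("igraph not available; skipping GraphML output")
    } else {
      g <- igraph::graph_from_data_frame(
        e[, c("sender", "receiver", "weight", "n_significant_interactions")],
        directed = TRUE)
      igraph::write_graph(g, graphml_path, format = "graphml")
    }
  }
  invisible(path)
}

#' Read an interaction network edge list written by [write_network()]
#' @param path edge-list TSV path.
#' @return an `interaction_network`.
#' @export
read_network <- function(path) {
  e <- read_tsv_file(path)
  need <- c("sender", "receiver", "weight", "n_significant_interactions")
  missing <- setdiff(need, names(e))
  if (length(missing)) stop_schema("missing column(s): ",
                                   paste(missing, collapse = ", "))
  if (nrow(e)) {
    e$sender <- as.character(e$sender)
    e$receiver <- as.character(e$receiver)
  } else {
    e <- data.frame(sender = character(), receiver = character(),
                    weight = numeric(),
                    n_significant_interactions = integer())
  }
  structure(list(edges = e, nodes = sort(unique(c(e$sender, e$receiver)))),
            class = "interaction_network")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", if (x$normalized) "normalized" else "raw counts", "\n")
  invisible(x)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table:", nrow(x), "cells,",
      length(unique(x$cell_type)), "types,",
      length(unique(x$sample_id)), "samples\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
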