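# Shared fixture builders: small deterministic objects assembled in code.

toy_cells <- function() {
  cell_table(data.frame(
    cell_id = c("c1", "c2", "c3"),
    x_um = c(0, 10, 200),
    y_um = c(0, 0, 200),
    cell_type = c("A", "B", "A"),
    sample_id = "s1",
    condition = "control",
    stringsAsFactors = FALSE))
}

random_cells <- function(n, n_types = 5, n_samples = 1, seed = 1) {
  set.seed(seed)
  cell_table(data.frame(
    cell_id = paste0("c", seq_len(n)),
    x_um = runif(n, 0, 300),
    y_um = runif(n, 0, 300),
    cell_type = sample(LETTERS[seq_len(n_types)], n, replace = TRUE),
    sample_id = sample(paste0("s", seq_len(n_samples)), n, replace = TRUE),
    condition = "control",
    stringsAsFactors = FALSE))
}

# O(n^2) all-pairs reference for the neighborhood composition matrix
brute_force_composition <- function(cells, r_um, include_self = TRUE) {
  types <- sort(unique(cells$cell_type))
  n <- nrow(cells)
  out <- matrix(0L, n, length(types), dimnames = list(NULL, types))
  for (i in seq_len(n)) {
    same <- cells$sample_id == cells$sample_id[i]
    d2 <- (cells$x_um - cells$x_um[i])^2 + (cells$y_um - cells$y_um[i])^2
    nb <- same & d2 <= r_um^2
    if (!include_self) nb[i] <- FALSE
    out[i, ] <- as.integer(table(factor(cells$cell_type[nb], levels = types)))
  }
  out
}

# deterministic small expression matrix where per-type means are easy to
# compute by hand: each listed cell expresses exactly the stated counts
toy_expression <- function(counts, genes, cells) {
  expression_matrix(Matrix::Matrix(counts, nrow = length(genes), sparse = TRUE),
                    genes = genes, cells = cells)
}

make_de_rows <- function(gene, group, lfc, p, adj = p, fg = 0.5, bg = 0.05) {
  data.frame(gene = gene, group = group, log_fold_change = lfc,
             p_value = p, adjusted_p = adj, frac_fg = fg, frac_bg = bg,
             stringsAsFactors = FALSE)
}
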