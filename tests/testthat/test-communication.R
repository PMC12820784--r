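# 12-cell, 3-type toy expression used for the interaction-score oracle;
# values are treated as already normalized so per-type means are exact.
toy_comm <- function() {
  types <- rep(c("A", "B", "C"), each = 4)
  counts <- rbind(
    L1 = rep(c(2, 1, 0), each = 4),
    R1 = rep(c(0, 4, 2), each = 4),
    L2 = rep(c(1, 0, 3), each = 4),
    R2 = rep(2, 12))
  expr <- expression_matrix(counts, rownames(counts), paste0("c", 1:12),
                            normalized = TRUE)
  de <- de_table(rbind(
    make_de_rows("L1", "A", lfc = 2, p = 1e-4),
    make_de_rows("R1", "B", lfc = 2, p = 1e-4),
    make_de_rows("L2", "C", lfc = 2, p = 1e-4)))
  lrdb <- lr_database(data.frame(ligand = c("L1", "L2"),
                                 receptor = c("R1", "R2")))
  list(expr = expr, labels = types, de = de, lrdb = lrdb)
}

test_that("a type-exclusive gene is its top marker with clean fractions", {
  set.seed(1)
  counts <- matrix(rpois(20 * 40, 1), nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:40)))
  labels <- rep(c("A", "B"), each = 20)
  counts["g1", ] <- c(rep(8, 20), rep(0, 20))  # exclusive to A
  expr <- expression_matrix(counts, rownames(counts), colnames(counts))
  de <- detect_markers(expr, labels)
  a <- de[de$group == "A", ]
  top <- a[order(a$p_value, -a$log_fold_change), ][1, ]
  expect_equal(top$gene, "g1")
  expect_equal(top$frac_fg, 1)
  expect_equal(top$frac_bg, 0)
  expect_error(detect_markers(expr, rep("A", 40)), "2 cell types")
})

test_that("permuted labels yield roughly uniform marker p-values", {
  set.seed(2)
  counts <- matrix(rpois(50 * 200, 2), nrow = 50,
                   dimnames = list(paste0("g", 1:50), paste0("c", 1:200)))
  expr <- expression_matrix(counts, rownames(counts), colnames(counts))
  rates <- vapply(1:20, function(i) {
    labels <- sample(rep(c("A", "B"), each = 100))
    de <- detect_markers(expr, labels)
    mean(de$p_value[de$group == "A"] < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.08)
})

test_that("the strict specificity filter keeps exactly the genes built to pass", {
  de <- de_table(rbind(
    make_de_rows("pass1", "IAF", lfc = 4.0, p = 0.001, fg = 0.60, bg = 0.05),
    make_de_rows("pass2", "IAF", lfc = 3.5, p = 0.010, fg = 0.30, bg = 0.02),
    make_de_rows("low_lfc", "IAF", lfc = 2.0, p = 0.001, fg = 0.60, bg = 0.05),
    make_de_rows("high_p", "IAF", lfc = 4.0, p = 0.200, fg = 0.60, bg = 0.05),
    make_de_rows("low_fg", "IAF", lfc = 4.0, p = 0.001, fg = 0.20, bg = 0.05),
    make_de_rows("high_bg", "IAF", lfc = 4.0, p = 0.001, fg = 0.60, bg = 0.30)))
  kept <- filter_markers(de, marker_config())
  expect_equal(sort(kept$gene), c("pass1", "pass2"))
})

test_that("interaction scores match the hand-computed toy table", {
  tc <- toy_comm()
  sc <- score_interactions(tc$expr, tc$labels, tc$de, tc$lrdb)
  key <- paste(sc$ligand, sc$sender, sc$receiver)
  # scaled means: L1 A=1 B=.5 C=0; R1 A=0 B=1 C=.5; L2 A=1/3 B=0 C=1; R2 all 0
  expected <- c("L1 A B" = 1, "L1 A C" = 0.5, "L1 B B" = 0.5,
                "L1 B C" = 0.25)
  for (k in names(expected)) {
    expect_equal(sc$score[key == k], unname(expected[k]), tolerance = 1e-12)
  }
  # zero-fraction sender: L1 in C is expressed by no cell -> not relevant
  expect_false(any(sc$ligand == "L1" & sc$sender == "C"))
  # DE support: L1 up in A and R1 up in B drive significance
  expect_true(sc$significant[key == "L1 A B"])
  expect_true(sc$significant[key == "L1 B B"])
  expect_false(sc$significant[key == "L1 B C"])
  # constant gene min-max scales to zero, not to noise amplification
  expect_true(all(sc$score[sc$receptor == "R2"] == 0))
  # maximal-mean sender ligand x maximal-mean receiver receptor scores 1
  expect_equal(sc$score[key == "L1 A B"], 1)
})

test_that("missing LR genes are skipped with a warning", {
  tc <- toy_comm()
  lrdb <- lr_database(data.frame(ligand = c("L1", "GHOST"),
                                 receptor = c("R1", "R2")))
  expect_warning(sc <- score_interactions(tc$expr, tc$labels, tc$de, lrdb),
                 "GHOST")
  expect_false(any(sc$ligand == "GHOST"))
})

test_that("raising the relevance threshold never adds interactions", {
  tc <- toy_comm()
  lo <- score_interactions(tc$expr, tc$labels, tc$de, tc$lrdb, tau_expr = 0.05)
  hi <- score_interactions(tc$expr, tc$labels, tc$de, tc$lrdb, tau_expr = 0.5)
  key <- function(x) paste(x$ligand, x$sender, x$receiver)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("the niche constraint equals a set co-membership oracle", {
  enr <- structure(data.frame(
    niche = rep(paste0("N", 1:3), each = 3),
    cell_type = rep(c("A", "B", "C"), 3),
    enriched = c(TRUE, TRUE, FALSE,  FALSE, FALSE, TRUE,  TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE), class = c("enrichment_table", "data.frame"))
  # direct cases: A,B share N1; B,C share nothing
  sc <- data.frame(sender = c("A", "B"), ligand = "L",
                   receiver = c("B", "C"), receptor = "R",
                   score = 1, relevant = TRUE, significant = TRUE)
  kept <- constrain_by_niche(sc, enr)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$sender, "A")

  # randomized flag matrices vs brute-force oracle
  set.seed(4)
  for (rep_i in 1:5) {
    flags <- matrix(runif(12) < 0.4, 4, 3,
                    dimnames = list(paste0("N", 1:4), c("A", "B", "C")))
    enr_r <- structure(data.frame(
      niche = rep(rownames(flags), 3),
      cell_type = rep(colnames(flags), each = 4),
      enriched = as.vector(flags), stringsAsFactors = FALSE),
      class = c("enrichment_table", "data.frame"))
    sc_r <- data.frame(sender = sample(c("A", "B", "C"), 50, TRUE),
                       ligand = "L",
                       receiver = sample(c("A", "B", "C"), 50, TRUE),
                       receptor = "R", score = runif(50),
                       relevant = TRUE, significant = TRUE)
    kept_r <- constrain_by_niche(sc_r, enr_r)
    oracle <- vapply(seq_len(50), function(i) {
      any(flags[, sc_r$sender[i]] & flags[, sc_r$receiver[i]])
    }, logical(1))
    expect_equal(nrow(kept_r), sum(oracle))
    expect_equal(kept_r$score, sc_r$score[oracle])
  }
})

test_that("network weights add significant scores and nothing else", {
  sc <- data.frame(sender = c("S", "S", "S"), ligand = c("l1", "l2", "l3"),
                   receiver = "R", receptor = c("r1", "r2", "r3"),
                   score = c(0.4, 0.25, 0.9),
                   relevant = TRUE,
                   significant = c(TRUE, TRUE, FALSE))
  net <- build_network(sc)
  expect_equal(net$edges$weight, 0.65)
  expect_equal(net$edges$n_significant_interactions, 2L)
  # permutation invariance
  net2 <- build_network(sc[c(3, 1, 2), ])
  expect_equal(net$edges, net2$edges)
  # empty network
  sc$significant <- FALSE
  expect_equal(nrow(build_network(sc)$edges), 0)
})

test_that("dropping the niche constraint never decreases an edge weight", {
  tis <- generate_tissue(config_circuit(seed = 31))
  labels <- tis$cells$cell_type
  de <- detect_markers(tis$expr, labels)
  lrdb <- lr_database(data.frame(ligand = c("IL1B", "HK1"),
                                 receptor = c("IL1R1", "HK2")))
  sc <- score_interactions(tis$expr, labels, de, lrdb)
  comp <- neighborhood_composition(tis$cells, 30)
  model <- fit_niches(comp, k_range = 2:3, seed = 2, sil_cap = 1000)
  enr <- niche_enrichment(model$labels, labels)
  unconstrained <- build_network(sc)$edges
  constrained <- build_network(constrain_by_niche(sc, enr))$edges
  for (i in seq_len(nrow(constrained))) {
    j <- which(unconstrained$sender == constrained$sender[i] &
                 unconstrained$receiver == constrained$receiver[i])
    expect_gte(unconstrained$weight[j], constrained$weight[i])
  }
})

test_that("proximity profile bins, counts and edge cases behave", {
  cells <- cell_table(data.frame(
    cell_id = paste0("c", 1:5),
    x_um = c(0, 5, 10, 15, 20), y_um = 0,
    cell_type = c("S", "T", "T", "T", "T"),
    sample_id = "s1", condition = "x"))
  counts <- matrix(1:5, 1, 5, dimnames = list("G", paste0("c", 1:5)))
  expr <- expression_matrix(counts, "G", paste0("c", 1:5), normalized = TRUE)
  pp <- proximity_profile(cells, expr, "S", "T", "G")
  expect_equal(pp$n, c(4L, 0L, 0L, 0L, 0L))  # all targets inside first bin
  expect_equal(sum(pp$n), 4)

  no_src <- cells
  no_src$cell_type <- "T"
  expect_error(suppressWarnings(
    proximity_profile(cell_table(as.data.frame(no_src)), expr, "S", "T", "G")),
    "no source cells")
  expect_error(proximity_profile(cells, expr, "S", "T", "NOPE"), "absent")
})
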