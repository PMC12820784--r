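test_that("TF selection routes follow their thresholds and union", {
  set.seed(5)
  n_t <- 80; n_b <- 240
  labels <- rep(c("IAF", "other"), c(n_t, n_b))
  tfs <- paste0("TF", 1:6)
  activity <- matrix(rnorm((n_t + n_b) * 6, sd = 0.4), n_t + n_b, 6,
                     dimnames = list(NULL, tfs))
  # TF1: large shift (in); TF2: shift 0.5 (out: diff below 0.75);
  # TF3: tiny shift (out: p too large)
  activity[labels == "IAF", "TF1"] <- activity[labels == "IAF", "TF1"] + 1.2
  activity[labels == "IAF", "TF2"] <- activity[labels == "IAF", "TF2"] + 0.5
  activity[labels == "IAF", "TF3"] <- activity[labels == "IAF", "TF3"] + 0.02
  markers <- de_table(rbind(
    make_de_rows(c("TF4", "TF5"), "IAF", lfc = 2, p = 1e-5),
    make_de_rows("TF1", "IAF", lfc = 2, p = 1e-5),     # shared with activity
    make_de_rows("NOTATF", "IAF", lfc = 2, p = 1e-5),  # not in universe
    make_de_rows("TF6", "IAF", lfc = 2, p = 0.20)))    # p too large
  sel <- select_tfs(markers, activity, labels, "IAF", tf_universe = tfs)
  expect_equal(sel$activity_route, "TF1")
  expect_equal(sel$expression_route, c("TF1", "TF4", "TF5"))
  expect_equal(sel$union, c("TF1", "TF4", "TF5"))

  # independent oracle: recompute the activity route directly
  oracle <- tfs[vapply(tfs, function(tf) {
    d <- mean(activity[labels == "IAF", tf]) -
      mean(activity[labels != "IAF", tf])
    p <- wilcox.test(activity[labels == "IAF", tf],
                     activity[labels != "IAF", tf], exact = FALSE)$p.value
    d > 0.75 && p < 0.01
  }, logical(1))]
  expect_equal(sel$activity_route, sort(oracle))
  expect_error(select_tfs(markers, activity, labels, "IAF", character(0)),
               "universe")
})

test_that("disjoint routes of 3 and 4 TFs with one shared give a union of 6", {
  labels <- rep(c("IAF", "other"), c(50, 50))
  tfs <- paste0("TF", 1:7)
  set.seed(6)
  activity <- matrix(rnorm(100 * 7, sd = 0.2), 100, 7,
                     dimnames = list(NULL, tfs))
  for (tf in c("TF1", "TF2", "TF3", "TF4")) {
    activity[labels == "IAF", tf] <- activity[labels == "IAF", tf] + 1.5
  }
  markers <- de_table(make_de_rows(c("TF4", "TF5", "TF6"), "IAF",
                                   lfc = 2, p = 1e-6))
  sel <- select_tfs(markers, activity, labels, "IAF", tf_universe = tfs)
  expect_equal(length(sel$expression_route), 3)
  expect_equal(length(sel$activity_route), 4)
  expect_equal(length(sel$union), 6)
})

test_that("ligand voting follows top-n membership with deterministic ties", {
  rp <- matrix(0, 12, 2, dimnames = list(paste0("L", sprintf("%02d", 1:12)),
                                         c("TF1", "TF2")))
  rp[, "TF1"] <- c(12:1)         # L01 strongest
  rp[, "TF2"] <- 1               # all tied: lexicographic top-10
  v <- vote_ligands(c("TF1", "TF2"), rp, top_n = 10, min_votes = 1)
  expect_equal(v$votes[v$ligand == "L01"], 2)   # top by score and by label
  # under full ties TF2 votes L01..L10 lexicographically; TF1 by score
  expect_false("L11" %in% v$ligand)
  expect_false("L12" %in% v$ligand)
  expect_equal(sum(v$votes), 20)

  # single TF can never reach the default 5-vote threshold
  expect_equal(nrow(vote_ligands("TF1", rp, top_n = 10, min_votes = 5)), 0)
  expect_error(vote_ligands("TF1", rp[1:5, , drop = FALSE], top_n = 10),
               "fewer than top_n")
  expect_warning(vote_ligands(c("TF1", "GHOST"), rp, min_votes = 1), "GHOST")
})

test_that("voting defaults are top 10 and at least 5 votes", {
  expect_equal(eval(formals(vote_ligands)$top_n), 10)
  expect_equal(eval(formals(vote_ligands)$min_votes), 5)
})

test_that("a ligand planted in 6 of 8 TF top-10 lists is retained with 6 votes", {
  res <- generate_lr_resources(
    lr_resource_config(planted_support = list(TGFB1 = paste0("TF", 1:6)),
                       seed = 10))
  v <- vote_ligands(colnames(res$rp), res$rp)
  expect_equal(v$votes[v$ligand == "TGFB1"], 6)
})

test_that("the funnel is monotone in TF set and vote threshold", {
  res <- generate_lr_resources(lr_resource_config(seed = 12))
  v_small <- vote_ligands(paste0("TF", 1:4), res$rp, min_votes = 1)
  v_big <- vote_ligands(paste0("TF", 1:8), res$rp, min_votes = 1)
  shared <- intersect(v_small$ligand, v_big$ligand)
  expect_true(all(v_big$votes[match(shared, v_big$ligand)] >=
                    v_small$votes[match(shared, v_small$ligand)]))
  v5 <- vote_ligands(paste0("TF", 1:8), res$rp, min_votes = 5)
  v3 <- vote_ligands(paste0("TF", 1:8), res$rp, min_votes = 3)
  expect_true(all(v5$ligand %in% v3$ligand))
})

test_that("receptor expression gating keeps and drops ligands at the 5% boundary", {
  # 100 target cells; receptor RA expressed in 4 (4% <= tau), RB in all
  counts <- rbind(RA = c(rep(1, 4), rep(0, 96)), RB = rep(2, 100))
  expr <- expression_matrix(counts, c("RA", "RB"), paste0("c", 1:100))
  labels <- rep("IAF", 100)
  lrdb <- lr_database(data.frame(ligand = c("LA", "LB", "LC"),
                                 receptor = c("RA", "RB", "RC")))
  lg <- data.frame(ligand = c("LA", "LB"), votes = c(6L, 5L))
  sl <- filter_by_receptor(lg, lrdb, expr, labels, "IAF", tau = 0.05)
  expect_equal(sl$ligand, "LB")
  expect_equal(sl$receptors, "RB")
  expect_warning(
    filter_by_receptor(data.frame(ligand = "LX", votes = 5L), lrdb, expr,
                       labels, "IAF"), "no receptor")
  expect_error(filter_by_receptor(lg, lrdb, expr, labels, "Missing"),
               "not present")
})

test_that("a mixed 6-ligand construction survives exactly as the hand filter says", {
  set.seed(7)
  recs <- paste0("R", 1:6)
  frac <- c(0.5, 0.04, 0.30, 0.00, 0.06, 0.049)  # per-receptor target fraction
  n <- 1000
  counts <- do.call(rbind, lapply(frac, function(f) {
    v <- numeric(n); if (f > 0) v[seq_len(round(f * n))] <- 1; v
  }))
  expr <- expression_matrix(counts, recs, paste0("c", 1:n))
  lrdb <- lr_database(data.frame(ligand = paste0("L", 1:6), receptor = recs))
  lg <- data.frame(ligand = paste0("L", 1:6), votes = 5L)
  sl <- filter_by_receptor(lg, lrdb, expr, rep("IAF", n), "IAF", tau = 0.05)
  expect_equal(sl$ligand, paste0("L", c(1, 3, 5)))  # fractions > 0.05 only
})

test_that("family expansion joins shortlisted ligands to their families", {
  sl <- structure(data.frame(ligand = "TGFB1", votes = 6L),
                  class = c("ligand_shortlist", "data.frame"))
  fam <- data.frame(ligand = c("TGFB1", "TGFB2", "TGFB3", "IL6"),
                    family = c("TGFB", "TGFB", "TGFB", "IL6"))
  expect_equal(expand_by_family(sl, fam), c("TGFB1", "TGFB2", "TGFB3"))
})
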