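test_that("synergy expectations match the forced arithmetic", {
  s <- synergy_statistic(100, 200, 100, observed_dual = 650)
  expect_equal(s$e_additive, 400)
  expect_equal(s$e_synergistic, 600)
  expect_equal(s$gap, 200)              # = dA * dB / X
  expect_equal(s$classification, "synergistic")
  expect_equal(synergy_statistic(100, 200, 100,
                                 observed_dual = 405)$classification,
               "additive")
  expect_equal(synergy_statistic(100, 200, 100,
                                 observed_dual = 100)$classification,
               "sub-additive")
  expect_error(synergy_statistic(0, 1, 1), "x_baseline")
  expect_error(synergy_statistic(10, -20, 5), "below zero")
})

test_that("a zero increment collapses the synergistic onto the additive expectation", {
  for (db in c(0, 1, 50, 1000)) {
    s <- synergy_statistic(37.5, 0, db)
    expect_equal(s$e_synergistic, s$e_additive)
  }
})

test_that("the product and expanded synergy forms agree to machine precision", {
  set.seed(3)
  for (i in 1:200) {
    x <- runif(1, 0.1, 1000)
    da <- runif(1, -x, 1000)
    db <- runif(1, -x, 1000)
    s <- synergy_statistic(x, da, db)
    expanded <- x + da + db + da * db / x
    expect_equal(s$e_synergistic, expanded, tolerance = 1e-12)
    expect_equal(s$e_synergistic - s$e_additive, da * db / x,
                 tolerance = 1e-9)
  }
})

test_that("signature derivation is a three-way set intersection", {
  ko <- de_table(rbind(make_de_rows("g1", "ko", -2, 0.01, adj = 0.01),
                       make_de_rows("g2", "ko", -2, 0.01, adj = 0.01),
                       make_de_rows("g3", "ko", 2, 0.01, adj = 0.01),
                       make_de_rows("g4", "ko", -2, 0.01, adj = 0.30)))
  act <- de_table(rbind(make_de_rows("g1", "act", 2, 0.03, adj = 0.03),
                        make_de_rows("g2", "act", -1, 0.03, adj = 0.03),
                        make_de_rows("g3", "act", 2, 0.01, adj = 0.01),
                        make_de_rows("g4", "act", 2, 0.01, adj = 0.01)))
  sig <- derive_signature(ko, act, bound_genes = c("g1", "g9"),
                          specific_genes = c("g1", "g2"))
  expect_equal(sig$effector, "g1")  # down-in-KO and up-in-activation only
  expect_equal(sig$core, "g1")

  disjoint <- derive_signature(ko, act, bound_genes = "g9",
                               specific_genes = "g9")
  expect_equal(disjoint$core, character(0))
})

test_that("randomized signature tables equal a brute-force intersection oracle", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:500)
  for (rep_i in 1:3) {
    ko <- de_table(make_de_rows(genes, "ko", lfc = rnorm(500),
                                p = runif(500), adj = runif(500)))
    act <- de_table(make_de_rows(genes, "act", lfc = rnorm(500),
                                 p = runif(500), adj = runif(500)))
    bound <- sample(genes, 150)
    spec <- sample(genes, 150)
    sig <- derive_signature(ko, act, bound, spec)
    oracle_eff <- character(0)
    for (g in genes) {
      kd <- ko[ko$gene == g, ]
      au <- act[act$gene == g, ]
      if (kd$adjusted_p < 0.05 && kd$log_fold_change < 0 &&
          au$adjusted_p < 0.05 && au$log_fold_change > 0) {
        oracle_eff <- c(oracle_eff, g)
      }
    }
    expect_equal(sig$effector, sort(oracle_eff))
    expect_equal(sig$core, sort(intersect(intersect(oracle_eff, bound), spec)))
    expect_true(all(sig$core %in% sig$effector))
  }
})

test_that("ssGSEA matches a step-by-step running-sum oracle on a small profile", {
  prof <- c(a = 9, b = 7, c = 5, d = 3, e = 2, f = 1)
  set1 <- c("b", "e")
  # independent oracle: explicit per-position loop
  oracle <- function(profile, gset, alpha = 0.25) {
    ord <- names(sort(profile, decreasing = TRUE))
    N <- length(ord)
    win <- cumsum(ifelse(ord %in% gset, (N - seq_len(N) + 1)^alpha, 0))
    win <- win / win[N]
    wout <- cumsum(!(ord %in% gset)) / (N - length(intersect(gset, ord)))
    sum(win - wout)
  }
  expect_equal(ssgsea_score(prof, set1), oracle(prof, set1))
  set2 <- c("a", "b", "f")
  expect_equal(ssgsea_score(prof, set2), oracle(prof, set2))
  expect_error(ssgsea_score(prof, character(0)), "proper subset")
  expect_error(ssgsea_score(prof, names(prof)), "proper subset")
})

test_that("a set occupying the top ranks maximizes ssGSEA over all same-size sets", {
  prof <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:10))
  sets <- combn(names(prof), 3, simplify = FALSE)
  scores <- vapply(sets, function(s) ssgsea_score(prof, s), numeric(1))
  expect_equal(sort(sets[[which.max(scores)]]), sort(paste0("g", 1:3)))
  expect_equal(length(scores), 120)
})

test_that("ssGSEA is invariant under strictly monotone transforms", {
  set.seed(9)
  prof <- setNames(rnorm(40), paste0("g", 1:40))
  gset <- sample(names(prof), 8)
  base <- ssgsea_score(prof, gset)
  expect_equal(ssgsea_score(2 * prof + 5, gset), base)
  expect_equal(ssgsea_score(exp(prof), gset), base)
  expect_equal(ssgsea_score(rank(prof), gset), base)
})

test_that("ordered probit recovers a planted slope and matches a binary oracle", {
  set.seed(10)
  z <- rnorm(400)
  u <- 1.2 * z + rnorm(400)
  y <- cut(u, c(-Inf, -1, 0.5, 1.5, Inf), labels = FALSE)
  fit <- ordered_probit(z, y)
  expect_lt(abs(fit$beta - 1.2), 0.25)
  expect_true(all(diff(fit$cutpoints) > 0))
  expect_lt(fit$p_one_sided, 1e-10)

  # J = 2 reduces to binary probit: compare against glm as the oracle
  y2 <- as.integer(u > 0.2) + 1L
  f2 <- ordered_probit(z, y2)
  g <- glm(I(y2 == 2) ~ z, family = binomial(link = "probit"))
  expect_lt(abs(f2$beta - unname(coef(g)[2])), 1e-4)
  expect_lt(abs(f2$cutpoints[1] - unname(-coef(g)[1])), 1e-4)
})

test_that("ordered probit rejects degenerate inputs", {
  expect_error(ordered_probit(rnorm(10), rep(1, 10)), "2 response")
  z <- c(1:50, 101:150)
  y <- rep(1:2, each = 50)
  expect_error(ordered_probit(z, y), "separation")
})

test_that("signature refinement keeps only severity-predictive genes, within core", {
  coh <- generate_cohort(cohort_config(n_subjects = 300, beta_true = 2,
                                       seed = 15))
  core <- c(coh$truth$signature[1:10], "BG001", "BG002")
  refined <- refine_signature(coh$profiles, coh$severity, core)
  expect_true(all(refined %in% core))
  expect_true(all(startsWith(refined, "SIG")))  # background genes never pass
  expect_gte(length(refined), 5)
  # a non-binding threshold returns the core unchanged
  expect_equal(refine_signature(coh$profiles, coh$severity, core, alpha = 2),
               sort(intersect(core, rownames(coh$profiles))))
})

test_that("deconvolution marker selection applies the three printed thresholds", {
  de <- de_table(rbind(
    make_de_rows("keep1", "T1", lfc = 0.80, p = 1e-9, bg = 0.10),
    make_de_rows("keep2", "T1", lfc = 0.75, p = 1e-10, bg = 0.19),
    make_de_rows("bad_p", "T1", lfc = 0.80, p = 1e-7, bg = 0.10),
    make_de_rows("bad_lfc", "T1", lfc = 0.74, p = 1e-9, bg = 0.10),
    make_de_rows("bad_bg", "T1", lfc = 0.80, p = 1e-9, bg = 0.50),
    make_de_rows("bad_bg2", "T1", lfc = 5.00, p = 1e-30, bg = 0.20),
    make_de_rows("keep3", "T2", lfc = 2.00, p = 1e-12, bg = 0.01),
    make_de_rows("bad_all", "T2", lfc = 0.10, p = 0.5, bg = 0.90)))
  mk <- select_deconv_markers(de)
  expect_equal(mk$T1, c("keep1", "keep2"))
  expect_equal(mk$T2, "keep3")
})
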