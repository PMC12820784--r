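#!/usr/bin/env Rscript
# Stage 2: build the 30-um neighborhood composition matrix, select the
# number of niches by silhouette over k-means fits, and test per-niche
# cell-type enrichment (standardized residuals, Bonferroni).

suppressPackageStartupMessages(library(nichecircuit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/pipeline"

cfg <- pipeline_config(
  out, seed = seed,
  stages = c(simulate = FALSE, niches = TRUE, enrichment = TRUE,
             abundance = FALSE, communication = FALSE,
             prioritization = FALSE, scoring = FALSE),
  params = list(k_range = c(3, 8), sil_cap = 2000))
run_pipeline(cfg)

sil <- read_tsv_file(file.path(out, "silhouette.tsv"))
k_best <- sil$k[which.max(sil$silhouette)]
cat("silhouette trace:\n")
print(sil, row.names = FALSE)
cat("selected k =", k_best, "\n")

enr <- read_tsv_file(file.path(out, "enrichment.tsv"))
cat("chi-squared enrichment:", sum(enr$enriched), "of", nrow(enr),
    "(niche, type) pairs flagged at Bonferroni 0.05\n")
flagged <- enr[enr$enriched, c("niche", "cell_type", "std_residual")]
print(flagged[order(-flagged$std_residual), ][1:min(8, nrow(flagged)), ],
      row.names = FALSE)
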