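#!/usr/bin/env Rscript
# Stage 5: the TF-to-ligand funnel. TFs active in the target population are
# selected by marker expression and by inferred activity (mean difference
# > 0.75, p < 0.01); each selected TF votes for its top-10 ligands by
# regulatory potential; ligands with >= 5 votes and a receptor expressed in
# > 5% of target cells make the shortlist.

suppressPackageStartupMessages(library(nichecircuit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/pipeline"

cfg <- pipeline_config(
  out, seed = seed,
  stages = c(simulate = FALSE, niches = FALSE, enrichment = FALSE,
             abundance = FALSE, communication = FALSE,
             prioritization = TRUE, scoring = FALSE))
run_pipeline(cfg)

sl <- read_tsv_file(file.path(out, "shortlist.tsv"))
cat("ligand shortlist (top-10 votes across selected TFs, >= 5 votes,",
    "receptor expressed in > 5% of target cells):\n")
print(sl, row.names = FALSE)
cat("planted agonists (TGFB1, IL1B) recovered:",
    all(c("TGFB1", "IL1B") %in% sl$ligand), "\n")
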