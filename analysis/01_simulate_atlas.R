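#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic spatial atlas, prioritization resources and
# severity cohort that the downstream analyses consume.
#
# The atlas plants: four niche regions per sample; an ActMac -> IAF circuit
# (IL1B/IL1R1, target IL11, 50 um decay, 8-fold induction); a 3-fold
# disease expansion of IAFs; and a 50-gene severity signature in the cohort.

suppressPackageStartupMessages(library(nichecircuit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/pipeline"

cfg <- pipeline_config(
  out, seed = seed,
  stages = c(simulate = TRUE, niches = FALSE, enrichment = FALSE,
             abundance = FALSE, communication = FALSE,
             prioritization = FALSE, scoring = FALSE),
  params = list(n_per_condition = 6))
run_pipeline(cfg)

cells <- read_cell_table(file.path(out, "cells.tsv"))
cat("simulated atlas:", nrow(cells), "cells across",
    length(unique(cells$sample_id)), "samples (",
    paste(names(table(cells$condition)), table(cells$condition) / 1,
          collapse = " / "), "cells )\n")
cat("cell types:", paste(sort(unique(cells$cell_type)), collapse = ", "),
    "\n")
cat("outputs under", out, "\n")
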