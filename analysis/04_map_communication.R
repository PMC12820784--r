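#!/usr/bin/env Rscript
# Stage 4: marker detection, LR interaction scoring under the 5% expression
# threshold, spatial niche constraint, network assembly, and the
# distance-to-sender expression profile of the circuit target gene.

suppressPackageStartupMessages(library(nichecircuit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/pipeline"

cfg <- pipeline_config(
  out, seed = seed,
  stages = c(simulate = FALSE, niches = FALSE, enrichment = FALSE,
             abundance = FALSE, communication = TRUE,
             prioritization = FALSE, scoring = FALSE))
run_pipeline(cfg)

net <- read_network(file.path(out, "network.tsv"))
cat("niche-constrained communication network:", nrow(net$edges), "edges\n")
print(net$edges[order(-net$edges$weight), ], row.names = FALSE, digits = 3)
inc <- net$edges[net$edges$receiver == "IAF", ]
cat("top incoming edge for IAF:",
    inc$sender[which.max(inc$weight)], "->",
    sprintf("IAF (weight %.3f)\n", max(inc$weight)))

pp <- read_tsv_file(file.path(out, "proximity.tsv"))
cat("\nIL11 in IAFs vs distance to nearest activated macrophage:\n")
print(pp, row.names = FALSE, digits = 3)
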