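#!/usr/bin/env Rscript

# Step 4 — intersect the expression-retained genes with the flagged
# conservation categories into the candidate list, then append the eight
# known multiciliation genes.

suppressPackageStartupMessages(library(ciliascreen))
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)

retained <- readLines("results/expression/retained_genes.txt")
calls <- read.delim("results/conservation/calls.tsv")

ic <- integrate_candidates(retained, calls)
targets <- append_known(ic$candidates, known_multiciliation_genes())
write.table(targets, "results/integration/targets.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(paste0(
  "%d retained genes x %d flagged genes -> %d candidates ",
  "(%d absent, %d high, %d mild);\n  + %d known genes -> %d targets\n"),
  length(retained), sum(calls$category %in%
    c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE")),
  length(ic$candidates), ic$counts[["ABSENT"]],
  ic$counts[["HIGH_DIVERGENCE"]], ic$counts[["MILD_DIVERGENCE"]],
  length(known_multiciliation_genes()), nrow(targets)))
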