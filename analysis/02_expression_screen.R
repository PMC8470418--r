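#!/usr/bin/env Rscript

# Step 2 — per-experiment overexpression filter (logFC >= 1, p <= 0.05),
# binary gene x experiment matrix, Jaccard/Ward.D2/dynamic-hybrid
# clustering, removal of single-experiment genes and cluster signatures.

suppressPackageStartupMessages(library(ciliascreen))
dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)

paths <- sort(list.files("results/inputs", "^de_E[0-9]+\\.tsv$",
                         full.names = TRUE))
tables <- lapply(paths, read_de_table)
names(tables) <- sub("^de_(E[0-9]+)\\.tsv$", "\\1", basename(paths))

sets <- lapply(tables, filter_overexpressed, logfc_min = 1, p_max = 0.05)
# identifiers are already human-style symbols in the simulation
sets <- harmonize_ids(sets, stats::setNames(rep(list("identity"),
                                                length(sets)), names(sets)))
m <- build_binary_matrix(sets)
write_binary_matrix(m, "results/expression/binary_matrix.tsv")

d <- binary_profile_dist(m)
clusters <- dynamic_hybrid_cut(ward_linkage(d), d,
                               deep_split = 2, min_cluster_size = 20)
write_cluster_assignment(clusters, "results/expression/clusters.tsv")

dropped <- drop_single_experiment_genes(m, clusters)
writeLines(dropped$retained, "results/expression/retained_genes.txt")
sig <- cluster_signatures(m, clusters, signature_threshold = 0.5)
write.table(data.frame(cluster = rownames(sig$fractions),
                       round(sig$fractions, 3), check.names = FALSE),
            "results/expression/cluster_signatures.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sig$groups, "results/expression/signature_groups.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(paste0(
  "%d genes overexpressed in >= 1 of %d experiments; %d clusters; ",
  "%d single-experiment clusters dropped;\n  %d genes retained ",
  "(overexpressed in >= 2 experiments), %d removed\n"),
  nrow(m), ncol(m), max(clusters), length(dropped$removed_clusters),
  length(dropped$retained), length(dropped$removed)))
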