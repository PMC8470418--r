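#!/usr/bin/env Rscript

# Step 5 — expand the target list through the scored interaction network
# (list-list edges at 0.7, external genes needing two 0.9-score list
# partners), detect communities and test each community for term
# enrichment.

suppressPackageStartupMessages(library(ciliascreen))
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

targets <- read.delim("results/integration/targets.tsv")$gene
edges <- read_edge_list("results/inputs/edges.tsv")

graph <- expand_neighborhood(targets, edges, t_internal = 0.7,
                             t_external = 0.9, min_list_partners = 2L)
communities <- detect_communities(graph)
write_cluster_assignment(communities, "results/network/communities.tsv")
sm <- summarize_clusters(graph, communities, targets)
write.table(sm$table, "results/network/community_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ann <- annotation_map(read_annotation_table("results/inputs/annotations.tsv"))
enr <- do.call(rbind, lapply(sm$table$cluster, function(k) {
  study <- intersect(sm$members$gene[sm$members$cluster == k],
                     ann$population)
  if (length(study) == 0L) return(NULL)
  top <- utils::head(enrich(study, ann), 3L)
  if (nrow(top)) cbind(cluster = k, top) else NULL
}))
if (!is.null(enr)) {
  write.table(enr, "results/network/community_enrichment.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat(sprintf(paste0(
  "network of %d genes including %d targets, divided into %d communities\n"),
  sm$n_nodes, sm$n_list_in_network, nrow(sm$table)))
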