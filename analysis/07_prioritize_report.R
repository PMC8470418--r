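#!/usr/bin/env Rscript

# Step 7 — assemble the per-gene evidence table across all layers and
# select the promising shortlist: flagged conservation, ciliary-like
# profile cluster, and essentially no functional annotation.

suppressPackageStartupMessages(library(ciliascreen))
dir.create("results/report", showWarnings = FALSE, recursive = TRUE)

targets <- read.delim("results/integration/targets.tsv")
m <- read_binary_matrix("results/expression/binary_matrix.tsv")
expr_cl <- read_cluster_assignment("results/expression/clusters.tsv")
sig <- cluster_signatures(m, expr_cl)
calls <- read.delim("results/conservation/calls.tsv")
net_cl <- read_cluster_assignment("results/network/communities.tsv")
prof_cl <- read_cluster_assignment("results/profiles/clusters.tsv")
panel <- read_species_panel("results/inputs/species_panel.tsv")
pm <- build_profile_matrix(read_binary_matrix("results/inputs/profiles.tsv"),
                           panel)
prof_ann <- annotate_clusters(pm, prof_cl, panel)
ann <- annotation_map(read_annotation_table("results/inputs/annotations.tsv"))

evidence <- assemble_evidence(targets, m, expr_cl, sig, calls,
                              network_membership = net_cl,
                              profile_clusters = prof_cl,
                              profile_annotation = prof_ann,
                              annotations = ann)

# ciliary-like profile clusters: clade pattern linked to ciliation
ciliary <- as.integer(names(prof_ann$patterns))[vapply(
  prof_ann$patterns,
  function(p) any(p %in% c("ABSENT_FOCAL_CLADE", "ABSENT_NONCILIATED",
                           "CHORDATE_RESTRICTED", "METAZOA_RESTRICTED")),
  logical(1))]
promising <- prioritize(evidence, ciliary_profile_clusters = ciliary,
                        max_annotations = 0L)

scr_counts <- table(calls$category)
write_report(evidence, list(
  n_candidates = sum(targets$is_candidate),
  n_targets = nrow(targets),
  n_flagged = sum(calls$category %in%
    c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE")),
  conservation_counts = as.list(scr_counts),
  n_promising = nrow(promising)
), "results/report")
write.table(promising, "results/report/promising.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("evidence table: %d targets; promising shortlist: %d genes\n",
            nrow(evidence), nrow(promising)))
print(promising[, c("gene", "conservation_category", "profile_cluster",
                    "annotation_count", "rank")])
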