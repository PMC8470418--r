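#!/usr/bin/env Rscript

# Step 1 — generate every pipeline input as synthetic data with planted
# structure: ten DE experiment tables with five co-overexpression modules,
# a clade-contrast conservation table with planted losses and divergences,
# gene-by-species phylogenetic profiles with planted clade patterns, a
# scored interaction network with planted communities, and an annotation
# map. All downstream steps read only the TSV files written here.

suppressPackageStartupMessages(library(ciliascreen))

dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
cfg <- simulation_config(seed = 1452L)

de <- simulate_de_experiments(cfg)
for (e in names(de$tables)) {
  write_de_table(de$tables[[e]], sprintf("results/inputs/de_%s.tsv", e))
}
write.table(de$truth, "results/inputs/truth_modules.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ct <- simulate_clade_tables(cfg)
write_clade_table(ct$clade_table, "results/inputs/clade_table.tsv")
write.table(ct$truth, "results/inputs/truth_conservation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

pf <- simulate_profiles(cfg)
write_binary_matrix(pf$matrix, "results/inputs/profiles.tsv")
write_species_panel(pf$panel, "results/inputs/species_panel.tsv")
write.table(pf$truth, "results/inputs/truth_patterns.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

nw <- simulate_network(cfg)
write_edge_list(nw$edges, "results/inputs/edges.tsv")
write.table(nw$truth, "results/inputs/truth_communities.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ann <- simulate_annotations(cfg)
write_annotation_table(ann, "results/inputs/annotations.tsv")

cat(sprintf(paste0(
  "simulated %d genes: %d experiments, %d planted modules, ",
  "%d/%d/%d planted losses/high/mild divergences,\n",
  "  %d profile species, %d network communities, %d annotation terms\n"),
  cfg$n_genes, cfg$n_experiments, length(cfg$module_specs),
  cfg$planted_losses, cfg$planted_high_div, cfg$planted_mild_div,
  cfg$n_profile_species, length(cfg$community_sizes),
  length(unique(ann$term_id))))
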