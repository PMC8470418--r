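test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(n_genes = 50L), class = "ciliascreen_config_error")
  expect_error(simulation_config(background_overexpr_prob = 1.2),
               class = "ciliascreen_config_error")
  expect_error(simulation_config(n_genes = 200L, planted_losses = 150L,
                                 planted_high_div = 60L),
               class = "ciliascreen_config_error")
  expect_error(simulate_clade_tables(simulation_config(n_focal_species = 1L)),
               class = "ciliascreen_config_error")
  expect_error(simulate_network(simulation_config(intra_edge_prob = 0.1,
                                                  inter_edge_prob = 0.5)),
               class = "ciliascreen_config_error")
  expect_error(simulate_network(simulation_config(community_sizes = c(10L, 2L))),
               class = "ciliascreen_config_error")
})

test_that("generators are deterministic given the seed", {
  cfg <- simulation_config(seed = 77, n_genes = 250L)
  expect_identical(simulate_de_experiments(cfg), simulate_de_experiments(cfg))
  expect_identical(simulate_clade_tables(cfg), simulate_clade_tables(cfg))
  expect_identical(simulate_profiles(cfg), simulate_profiles(cfg))
  expect_identical(simulate_network(cfg), simulate_network(cfg))
  expect_identical(simulate_annotations(cfg), simulate_annotations(cfg))
  cfg2 <- simulation_config(seed = 78, n_genes = 250L)
  expect_false(identical(simulate_de_experiments(cfg)$tables,
                         simulate_de_experiments(cfg2)$tables))
})

test_that("deterministic planting at probability one hits exactly the active experiments", {
  cfg <- simulation_config(
    n_genes = 100L, n_experiments = 6L,
    module_specs = list(list(size = 20L, active = c(1L, 2L, 3L),
                             activation_prob = 1)),
    background_overexpr_prob = 0, seed = 4L
  )
  de <- simulate_de_experiments(cfg)
  sets <- lapply(de$tables, filter_overexpressed)
  planted <- de$truth$gene[de$truth$module == "M1"]
  for (e in 1:3) expect_setequal(sets[[e]], planted)
  for (e in 4:6) expect_length(sets[[e]], 0L)  # background never overexpressed
})

test_that("background genes exceed thresholds in at most one experiment", {
  cfg <- simulation_config(seed = 15, n_genes = 300L,
                           module_specs = list(),
                           background_overexpr_prob = 0.5)
  de <- simulate_de_experiments(cfg)
  hits <- Reduce(`+`, lapply(de$tables, function(t) {
    t$gene_id %in% filter_overexpressed(t)
  }))
  expect_true(all(hits <= 1L))
})

test_that("clade simulation plants margins that the classifier recovers exactly", {
  cfg <- simulation_config(seed = 23, n_genes = 150L, module_specs = list(),
                           planted_losses = 20L,
                           planted_high_div = 10L, planted_mild_div = 15L)
  sim <- simulate_clade_tables(cfg)
  scr <- screen_proteome(sim$clade_table)
  expect_identical(scr$calls$category, sim$truth$category)
  expect_equal(unname(scr$counts[c("ABSENT", "HIGH_DIVERGENCE",
                                   "MILD_DIVERGENCE")]),
               c(20L, 10L, 15L))
  # losses have full reference support and empty focal identity lists
  absent <- sim$clade_table[sim$truth$category == "ABSENT", ]
  expect_true(all(absent$focal_presence == 0L))
  expect_true(all(absent$ref_presence / absent$n_ref >= 0.8))
  expect_true(all(lengths(absent$focal_identities) == 0L))
  # single-gene derived check: focal 40 vs reference {90, 90, 92}-like spread
  one <- list(gene = "x", focal_presence = 2L, n_focal = 2L,
              ref_presence = 3L, n_ref = 3L,
              focal_identities = c(40, 40), ref_identities = c(90, 90, 92))
  expect_equal(classify_gene(one)$category, "HIGH_DIVERGENCE")
})

test_that("profile simulation carries clade masks and requested panel size", {
  cfg <- simulation_config(seed = 2, n_genes = 60L, module_specs = list(),
                           planted_losses = 5L, planted_high_div = 5L,
                           planted_mild_div = 5L, n_profile_species = 711L)
  pf <- simulate_profiles(cfg)
  expect_equal(ncol(pf$matrix), 711L)
  expect_identical(colnames(pf$matrix), pf$panel$species)
  expect_true(all(pf$matrix %in% 0:1))
  expect_true(any(pf$panel$focal) && any(!pf$panel$ciliated))
  expect_true(all(c("supergroup", "clade", "subclade") %in% names(pf$panel)))
  # every simulated gene appears exactly once in the ground truth
  expect_identical(sort(pf$truth$gene), sort(rownames(pf$matrix)))
  expect_false(any(duplicated(pf$truth$gene)))
})

test_that("network simulation respects block structure and score bounds", {
  cfg <- simulation_config(seed = 10, community_sizes = c(10L, 10L),
                           intra_edge_prob = 1, inter_edge_prob = 0)
  nw <- simulate_network(cfg)
  expect_true(all(nw$edges$score >= 0 & nw$edges$score <= 1))
  com <- stats::setNames(nw$truth$community, nw$truth$gene)
  expect_true(all(com[nw$edges$gene_a] == com[nw$edges$gene_b]))
  expect_equal(nrow(nw$edges), 2 * choose(10, 2))
  g <- expand_neighborhood(nw$truth$gene, nw$edges)
  cm <- detect_communities(g)
  expect_equal(unname(ari(cm[names(com)], com)), 1)
})

test_that("generated tables round-trip through the TSV writers", {
  cfg <- simulation_config(seed = 33, n_genes = 80L, module_specs = list(),
                           planted_losses = 8L, planted_high_div = 4L,
                           planted_mild_div = 8L,
                           community_sizes = c(12L, 10L))
  de <- simulate_de_experiments(cfg)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "de.tsv")
  write_de_table(de$tables[[1]], p)
  expect_equal(read_de_table(p), de$tables[[1]])
  ct <- simulate_clade_tables(cfg)$clade_table
  write_clade_table(ct, file.path(dir, "ct.tsv"))
  back <- read_clade_table(file.path(dir, "ct.tsv"))
  expect_equal(back$gene, ct$gene)
  expect_equal(back$focal_identities, ct$focal_identities)
  expect_equal(back$ref_identities, ct$ref_identities)
  pf <- simulate_profiles(cfg)
  write_binary_matrix(pf$matrix, file.path(dir, "m.tsv"))
  expect_equal(read_binary_matrix(file.path(dir, "m.tsv")), pf$matrix)
  write_species_panel(pf$panel, file.path(dir, "panel.tsv"))
  expect_equal(read_species_panel(file.path(dir, "panel.tsv")), pf$panel)
  nw <- simulate_network(cfg)
  write_edge_list(nw$edges, file.path(dir, "e.tsv"))
  expect_equal(read_edge_list(file.path(dir, "e.tsv")), nw$edges)
})
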