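make_table <- function(...) {
  rows <- list(...)
  data.frame(gene_id = vapply(rows, `[[`, character(1), 1),
             logfc = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
             pvalue = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
             stringsAsFactors = FALSE)
}

test_that("overexpression filter applies inclusive thresholds", {
  tab <- make_table(list("a", 1.2, 0.01),   # clearly overexpressed
                    list("b", 1.0, 0.05),   # exactly on both boundaries
                    list("c", 0.99, 0.001), # logFC below threshold
                    list("d", 1.5, 0.051))  # p above threshold
  expect_identical(filter_overexpressed(tab), c("a", "b"))
})

test_that("duplicate gene rows are resolved by smallest p-value", {
  tab <- make_table(list("a", 2.0, 0.01), list("a", 0.5, 0.001))
  expect_identical(filter_overexpressed(tab), character(0))
  tab2 <- make_table(list("a", 0.5, 0.01), list("a", 2.0, 0.001))
  expect_identical(filter_overexpressed(tab2), "a")
})

test_that("missing values are reported with the offending gene", {
  tab <- make_table(list("a", 1.2, 0.01))
  tab$logfc[1] <- NA
  expect_error(filter_overexpressed(tab), "a")
})

test_that("tightening either threshold never grows the filtered set", {
  set.seed(41)
  for (r in 1:30) {
    tab <- data.frame(gene_id = sprintf("g%02d", 1:30),
                      logfc = rnorm(30, 1, 1),
                      pvalue = runif(30), stringsAsFactors = FALSE)
    base <- filter_overexpressed(tab, 1, 0.05)
    expect_true(all(filter_overexpressed(tab, 1.5, 0.05) %in% base))
    expect_true(all(filter_overexpressed(tab, 1, 0.01) %in% base))
  }
})

test_that("identifier harmonization uses union semantics over co-orthologs", {
  sets <- list(mouse = c("Foxj1", "Unmapped1"), frog = "gene.x", human = "FOXJ1")
  maps <- list(
    mouse = data.frame(source_gene = "Foxj1", target_gene = "FOXJ1"),
    frog = data.frame(source_gene = c("gene.x", "gene.x"),
                      target_gene = c("COA", "COB")),
    human = "identity"
  )
  out <- suppressMessages(harmonize_ids(sets, maps))
  expect_identical(out$mouse, "FOXJ1")
  expect_identical(out$frog, c("COA", "COB"))     # both co-orthologs marked
  expect_identical(out$human, "FOXJ1")            # identity map unchanged
  expect_identical(attr(out, "n_unmapped")[["mouse"]], 1L)
  expect_error(harmonize_ids(sets, maps[-1]), "mouse")
})

test_that("binary matrix encodes membership with lexicographic rows", {
  sets <- list(E1 = c("b", "a"), E2 = "a", E3 = c("c", "a"), E4 = "c")
  m <- build_binary_matrix(sets)
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_identical(colnames(m), c("E1", "E2", "E3", "E4"))
  expect_equal(unname(m["b", ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(m["a", ]), c(1L, 1L, 1L, 0L))
  expect_true(all(rowSums(m) >= 1))
  expect_error(build_binary_matrix(sets[1]), ">= 2 experiments")
  expect_error(build_binary_matrix(list(E1 = character(0), E2 = character(0))),
               "no overexpressed genes")
})

test_that("single-experiment genes and clusters are dropped, partitioning rows", {
  m <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 1L), c = c(0L, 1L, 0L),
             d = c(0L, 0L, 1L), e = c(1L, 1L, 1L))
  colnames(m) <- c("E1", "E2", "E3")
  cl <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 1L)
  out <- drop_single_experiment_genes(m, cl)
  expect_identical(out$removed_clusters, 2L)     # all members row-sum 1
  expect_setequal(out$removed, c("c", "d"))
  expect_setequal(out$retained, c("a", "b", "e"))
  expect_equal(length(out$retained) + length(out$removed), nrow(m))
  # a single-profile gene inside a retained cluster is still excluded
  cl2 <- c(a = 1L, b = 1L, c = 1L, d = 1L, e = 1L)
  out2 <- drop_single_experiment_genes(m, cl2)
  expect_identical(out2$removed_clusters, integer(0))
  expect_setequal(out2$removed, c("c", "d"))
  expect_true(all(rowSums(m[out2$retained, ]) >= 2))
})

test_that("cluster signatures report per-experiment fractions and groups", {
  m <- rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L),
             c = c(1L, 0L, 1L, 0L), d = c(1L, 1L, 0L, 1L),
             e = c(0L, 0L, 1L, 1L), f = c(0L, 0L, 1L, 1L))
  colnames(m) <- c("EA", "EB", "EC", "ED")
  cl <- c(a = 1L, b = 1L, c = 1L, d = 1L, e = 2L, f = 2L)
  sig <- cluster_signatures(m, cl, signature_threshold = 0.5)
  expect_equal(unname(sig$fractions["1", ]), c(1, 0.75, 0.25, 0.25))
  expect_true(all(sig$fractions >= 0 & sig$fractions <= 1))
  expect_identical(sig$signature[["1"]], c("EA", "EB"))
  expect_identical(sig$signature[["2"]], c("EC", "ED"))
  # clusters with the same signature set share a group label
  cl3 <- c(a = 1L, b = 1L, c = 1L, d = 1L, e = 2L, f = 3L)
  sig3 <- cluster_signatures(m, cl3)
  grp <- sig3$groups
  expect_identical(grp$group[grp$cluster == 2L], grp$group[grp$cluster == 3L])
})
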