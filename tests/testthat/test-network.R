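edge_df <- function(...) {
  rows <- list(...)
  data.frame(gene_a = vapply(rows, `[[`, character(1), 1),
             gene_b = vapply(rows, `[[`, character(1), 2),
             score = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
             stringsAsFactors = FALSE)
}

test_that("neighborhood expansion applies the inclusive score thresholds", {
  lg <- c("L1", "L2", "L3")
  edges <- edge_df(
    list("L1", "L2", 0.70),   # list-list at exactly the internal threshold
    list("L1", "L3", 0.69),   # below: dropped
    list("X1", "L1", 0.95), list("X1", "L2", 0.90),  # admitted (2 partners)
    list("X2", "L1", 0.95),                          # one partner: excluded
    list("X3", "L1", 0.89), list("X3", "L2", 0.89),  # below external threshold
    list("X1", "X2", 0.99)    # external-external with X2 not admitted
  )
  g <- expand_neighborhood(lg, edges)
  nodes <- igraph::V(g)$name
  expect_setequal(nodes, c("L1", "L2", "L3", "X1"))
  ed <- igraph::as_data_frame(g)
  expect_true(any(ed$from == "L1" & ed$to == "L2" | ed$from == "L2" & ed$to == "L1"))
  expect_equal(igraph::ecount(g), 3L)  # L1-L2, X1-L1, X1-L2
  # L3 kept as isolated list node
  expect_equal(igraph::degree(g)["L3"][[1]], 0)
  expect_true(all(igraph::V(g)$is_list_member[match(lg, nodes)]))
})

test_that("external-external edges need both endpoints admitted", {
  lg <- c("L1", "L2")
  edges <- edge_df(
    list("X1", "L1", 0.95), list("X1", "L2", 0.95),
    list("X2", "L1", 0.95), list("X2", "L2", 0.95),
    list("X1", "X2", 0.92), list("X1", "X2", 0.40)  # duplicate pair collapses
  )
  g <- expand_neighborhood(lg, edges)
  ed <- igraph::as_data_frame(g)
  xx <- ed[ed$from %in% c("X1", "X2") & ed$to %in% c("X1", "X2"), ]
  expect_equal(nrow(xx), 1L)
  expect_equal(xx$score, 0.92)
})

test_that("expansion is order invariant and anti-monotone in thresholds", {
  set.seed(71)
  cfg <- simulation_config(seed = 71)
  nw <- simulate_network(cfg)
  lg <- nw$truth$gene[seq_len(30)]
  g1 <- expand_neighborhood(lg, nw$edges)
  g2 <- expand_neighborhood(lg, nw$edges[sample(nrow(nw$edges)), ])
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  e1 <- igraph::as_data_frame(g1); e2 <- igraph::as_data_frame(g2)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), e$score))
  expect_identical(key(e1), key(e2))
  # raising thresholds never adds nodes or edges
  g3 <- expand_neighborhood(lg, nw$edges, t_internal = 0.8, t_external = 0.95)
  expect_true(all(igraph::V(g3)$name %in% igraph::V(g1)$name))
  expect_lte(igraph::ecount(g3), igraph::ecount(g1))
  expect_error(expand_neighborhood(lg, nw$edges, t_internal = 0.95, t_external = 0.7),
               class = "ciliascreen_config_error")
})

test_that("integer 0-1000 scores are auto-normalized", {
  expect_equal(normalize_scores(c(700, 900)), c(0.7, 0.9))
  expect_equal(normalize_scores(c(0.7, 0.9)), c(0.7, 0.9))
  expect_equal(normalize_scores(c(0.7, 0.9), scale = "milli"), c(7e-4, 9e-4))
})

test_that("community detection recovers planted and trivial structures", {
  # two disconnected dense blocks
  edges <- do.call(rbind, lapply(list(letters[1:5], letters[6:10]), function(b) {
    p <- t(utils::combn(b, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], score = 0.95,
               stringsAsFactors = FALSE)
  }))
  g <- expand_neighborhood(letters[1:10], edges, 0.7, 0.9, 2)
  cm <- detect_communities(g)
  expect_equal(max(cm), 2L)
  expect_equal(unname(ari(cm, rep(1:2, each = 5)[match(names(cm), letters[1:10])])), 1)
  # complete graph: a single community
  p <- t(utils::combn(letters[1:6], 2))
  kg <- expand_neighborhood(letters[1:6],
                            data.frame(gene_a = p[, 1], gene_b = p[, 2],
                                       score = 0.9, stringsAsFactors = FALSE))
  expect_equal(max(detect_communities(kg)), 1L)
  # planted stochastic block model: exact recovery
  cfg <- simulation_config(seed = 5)   # intra 0.9 / inter 0.02
  nw <- simulate_network(cfg)
  gg <- expand_neighborhood(nw$truth$gene, nw$edges)
  cm2 <- detect_communities(gg)
  truth <- stats::setNames(nw$truth$community, nw$truth$gene)
  expect_equal(unname(ari(cm2[names(truth)], truth)), 1)
})

test_that("community summaries conserve node and list-member counts", {
  cfg <- simulation_config(seed = 9)
  nw <- simulate_network(cfg)
  lg <- nw$truth$gene[nw$truth$community %in% 1:2]
  g <- expand_neighborhood(nw$truth$gene, nw$edges)
  cm <- detect_communities(g)
  sm <- summarize_clusters(g, cm, lg)
  expect_equal(sum(sm$table$size), igraph::vcount(g))
  expect_true(all(sm$table$n_list_members <= sm$table$size))
  expect_equal(sm$n_list_in_network, sum(lg %in% igraph::V(g)$name))
  sm0 <- summarize_clusters(g, cm, character(0))
  expect_true(all(sm0$table$n_list_members == 0L))
})
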