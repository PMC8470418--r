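#' Normalize interaction scores to [0, 1]
#'
#' Interaction databases ship combined scores either as floats in `[0, 1]`
#' or as integers in `[0, 1000]`; the scale is auto-detected from the
#' maximum value unless given explicitly.
#'
#' @param score Numeric vector of edge scores.
#' @param scale `"auto"` (default), `"unit"` (already in `[0, 1]`) or
#'   `"milli"` (0--1000 integers, divided by 1000).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_scores <- function(score, scale = c("auto", "unit", "milli")) {
  scale <- match.arg(scale)
  if (any(!is.finite(score) | score < 0)) stop2("scores must be finite and >= 0")
  if (scale == "auto") scale <- if (max(score) > 1) "milli" else "unit"
  if (scale == "milli") score <- score / 1000
  if (any(score > 1)) stop2("scores exceed 1 after normalization")
  score
}

#' Expand a candidate list into its interaction neighborhood
#'
#' Builds the interaction subnetwork around a candidate gene list:
#' list--list edges are kept at score >= `t_internal`; an external gene is
#' admitted only if it interacts at score >= `t_external` with at least
#' `min_list_partners` distinct list genes (those qualifying edges are
#' kept); edges between two admitted external genes are kept at score >=
#' `t_external`. All thresholds are inclusive. List genes present in the
#' edge universe but left without edges remain as isolated nodes; list
#' genes absent from the universe are skipped with a warning.
#'
#' @param list_genes Character vector of candidate gene symbols.
#' @param edges Data frame `gene_a`, `gene_b`, `score` (undirected; repeated
#'   pairs are collapsed to their maximum score; self-loops dropped).
#' @param t_internal Score threshold for list--list edges. Default 0.7.
#' @param t_external Score threshold for edges involving external genes.
#'   Default 0.9.
#' @param min_list_partners Minimum distinct list partners an external gene
#'   needs. Default 2.
#' @param scale Passed to [normalize_scores()].
#' @return An [igraph] graph with vertex attribute `is_list_member` and edge
#'   attribute `score`.
#' @export
expand_neighborhood <- function(list_genes, edges, t_internal = 0.7,
                                t_external = 0.9, min_list_partners = 2L,
                                scale = "auto") {
  if (!(t_internal >= 0 && t_internal <= t_external && t_external <= 1)) {
    stop2("need 0 <= t_internal <= t_external <= 1",
          class = "ciliascreen_config_error")
  }
  edges <- data.frame(gene_a = as.character(edges$gene_a),
                      gene_b = as.character(edges$gene_b),
                      score = normalize_scores(edges$score, scale),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$gene_a != edges$gene_b, ]
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  edges <- edges[order(key, -edges$score), ]
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")), ]

  universe <- unique(c(edges$gene_a, edges$gene_b))
  unknown <- setdiff(list_genes, universe)
  if (length(unknown)) {
    warning("skipping ", length(unknown),
            " list gene(s) absent from the edge universe: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  lg <- intersect(list_genes, universe)

  in_a <- edges$gene_a %in% lg
  in_b <- edges$gene_b %in% lg
  ll <- edges[in_a & in_b & edges$score >= t_internal, ]
  # external candidates: count distinct list partners at >= t_external
  xl <- edges[xor(in_a, in_b) & edges$score >= t_external, ]
  if (nrow(xl)) {
    ext <- ifelse(xl$gene_a %in% lg, xl$gene_b, xl$gene_a)
    partner <- ifelse(xl$gene_a %in% lg, xl$gene_a, xl$gene_b)
    n_partners <- tapply(partner, ext, function(p) length(unique(p)))
    admitted <- names(n_partners)[n_partners >= min_list_partners]
  } else {
    ext <- character(0)
    admitted <- character(0)
  }
  xl_keep <- xl[ext %in% admitted, ]
  xx <- edges[!in_a & !in_b & edges$gene_a %in% admitted &
                edges$gene_b %in% admitted & edges$score >= t_external, ]

  kept <- rbind(ll, xl_keep, xx)
  nodes <- sort(unique(c(lg, admitted, kept$gene_a, kept$gene_b)))
  g <- igraph::graph_from_data_frame(
    d = kept[order(kept$gene_a, kept$gene_b),
             c("gene_a", "gene_b", "score")],
    directed = FALSE,
    vertices = data.frame(name = nodes, is_list_member = nodes %in% lg,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Detect communities in an interaction graph
#'
#' Greedy modularity maximization (fast-greedy agglomeration, weighted by
#' interaction score), as a deterministic surrogate for interactive network
#' community tools. Communities are renumbered largest-first (ties broken
#' by smallest member name).
#'
#' @param graph An [igraph] graph with edge attribute `score` (or no scores,
#'   in which case edges are unweighted).
#' @return Named integer vector: community id per node.
#' @export
detect_communities <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop2("empty graph")
  g <- igraph::simplify(graph, edge.attr.comb = list(score = "max", "ignore"))
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$score)
  # among modularity ties (exact ties drift by floating-point noise in the
  # greedy merge order), cut the merge tree at the fewest communities
  q <- cm$modularity
  n_comm <- igraph::vcount(g) - (seq_along(q) - 1L)
  best <- min(n_comm[q >= max(q) - 1e-10])
  mem <- if (best != length(unique(igraph::membership(cm)))) {
    tryCatch(igraph::cut_at(cm, no = best), error = function(e) {
      igraph::membership(cm)
    })
  } else {
    igraph::membership(cm)
  }
  out <- as.integer(mem)
  names(out) <- igraph::V(g)$name
  renumber_clusters(out)
}

#' Summarize network communities against the candidate list
#'
#' @param graph Graph from [expand_neighborhood()].
#' @param communities Named membership vector from [detect_communities()].
#' @param list_genes Candidate gene list.
#' @return List with `table` (data frame `cluster`, `size`,
#'   `n_list_members`), `members` (data frame `gene`, `cluster`,
#'   `is_list_member`), `n_nodes`, `n_list_in_network`.
#' @export
summarize_clusters <- function(graph, communities, list_genes) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(communities))) {
    stop2("communities must cover all graph nodes")
  }
  members <- data.frame(gene = nodes,
                        cluster = as.integer(communities[nodes]),
                        is_list_member = nodes %in% list_genes,
                        stringsAsFactors = FALSE)
  members <- members[order(members$cluster, members$gene), ]
  ids <- sort(unique(members$cluster))
  agg <- data.frame(
    cluster = ids,
    size = vapply(ids, function(i) sum(members$cluster == i), integer(1)),
    n_list_members = vapply(ids, function(i) {
      sum(members$is_list_member[members$cluster == i])
    }, integer(1))
  )
  stopifnot(sum(agg$size) == length(nodes))
  list(table = agg, members = members, n_nodes = length(nodes),
       n_list_in_network = sum(members$is_list_member))
}
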