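#' Ward.D2 agglomerative clustering with a deterministic tie rule
#'
#' Agglomerative hierarchical clustering under the Ward criterion in the
#' "D2" convention: the Lance--Williams update is applied to squared
#' dissimilarities and merge heights are reported back on the distance
#' scale, so clustering a Euclidean distance matrix minimises the increase
#' in within-cluster variance at every step.
#'
#' Ties in the merge criterion are broken deterministically: among all pairs
#' attaining the minimal Ward distance, the pair whose (smaller label,
#' larger label) is lexicographically smallest is merged, where a cluster's
#' label is the lexicographic minimum of its member labels. Because the rule
#' uses item names rather than row positions, the dendrogram is invariant
#' under row permutations of the input.
#'
#' @param d A [stats::dist] object or symmetric numeric matrix of pairwise
#'   dissimilarities with zero diagonal; all values finite.
#' @return An object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`, `method = "ward.D2"`), usable with [stats::cutree()] and
#'   [dynamic_hybrid_cut()].
#' @seealso [dynamic_hybrid_cut()] for extracting clusters.
#' @export
ward_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop2("need at least 2 items to cluster")
  if (any(!is.finite(dm))) stop2("non-finite dissimilarities")
  if (any(abs(dm - t(dm)) > 1e-12) || any(diag(dm) != 0)) {
    stop2("dissimilarity matrix must be symmetric with zero diagonal")
  }
  labs <- rownames(dm)
  if (is.null(labs)) labs <- as.character(seq_len(n))

  D2 <- dm^2
  diag(D2) <- Inf
  size <- rep(1L, n)
  cname <- labs              # lexicographic tie-break label per cluster
  node <- -seq_len(n)        # hclust id: negative leaf, positive merge row
  active <- rep(TRUE, n)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D2[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    tol <- 1e-9 * (1 + abs(m))
    cand <- which(sub <= m + tol, arr.ind = TRUE)
    ci <- idx[cand[, 1L]]
    cj <- idx[cand[, 2L]]
    lo <- pmin(cname[ci], cname[cj])
    hi <- pmax(cname[ci], cname[cj])
    pick <- order(lo, hi)[1L]
    i <- ci[pick]; j <- cj[pick]

    height[step] <- sqrt(D2[i, j])
    a <- node[i]; b <- node[j]
    # hclust convention: singletons (negative ids) listed first, else ascending
    merge[step, ] <- if (a < 0 && b >= 0) c(a, b) else if (b < 0 && a >= 0) {
      c(b, a)
    } else if (a <= b) c(a, b) else c(b, a)

    k <- setdiff(idx, c(i, j))
    if (length(k)) {
      tot <- size[i] + size[j] + size[k]
      upd <- ((size[i] + size[k]) * D2[k, i] +
              (size[j] + size[k]) * D2[k, j] -
               size[k] * D2[i, j]) / tot
      D2[k, i] <- upd
      D2[i, k] <- upd
    }
    size[i] <- size[i] + size[j]
    cname[i] <- min(cname[i], cname[j])
    node[i] <- step
    active[j] <- FALSE
    D2[j, ] <- Inf
    D2[, j] <- Inf
  }

  structure(
    list(merge = merge, height = height, order = dendrogram_order(merge),
         labels = labs, method = "ward.D2", call = match.call(),
         dist.method = attr(d, "method")),
    class = "hclust"
  )
}

# Leaf ordering by iterative left-to-right traversal of the merge tree.
dendrogram_order <- function(merge) {
  n <- nrow(merge) + 1L
  stack <- n - 1L          # root merge row
  out <- integer(0)
  while (length(stack)) {
    top <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (top < 0L) {
      out <- c(out, -top)
    } else {
      # push right child first so the left child is visited first
      stack <- c(stack, merge[top, 2L], merge[top, 1L])
    }
  }
  out
}

#' Dynamic hybrid cut of a dendrogram
#'
#' Extracts clusters from a dendrogram in two stages, following the dynamic
#' hybrid tree-cut idea: (1) candidate clusters are detected from the tree
#' shape -- the dendrogram is first cut just below its top joins, and each
#' branch is recursively split whenever both sub-branches are large enough
#' and separated from their join by a clear height gap, with the
#' `deep_split` parameter (0--4) controlling how small a gap still warrants
#' a split; (2) items left outside any candidate cluster are assigned to the
#' cluster of their nearest medoid, provided they fall within that cluster's
#' radius (maximal member-to-medoid distance). Items that still fit nowhere
#' are reported as unassigned (label 0).
#'
#' @param tree An `hclust` object (e.g. from [ward_linkage()]).
#' @param d The dissimilarities the tree was built from (`dist` or matrix),
#'   over the same items; used for medoid assignment in stage 2.
#' @param deep_split Integer 0--4; larger values split more aggressively and
#'   yield more, smaller clusters. Default 2.
#' @param min_cluster_size Minimum number of members a returned cluster may
#'   have. Default 20.
#' @return Named integer vector: cluster id per item (1 = largest cluster),
#'   0 for unassigned items. Attribute `params` records the parameters used.
#' @export
dynamic_hybrid_cut <- function(tree, d, deep_split = 2L, min_cluster_size = 20L) {
  if (min_cluster_size < 1L) stop2("min_cluster_size must be >= 1")
  if (!deep_split %in% 0:4) stop2("deep_split must be an integer in 0..4")
  dm <- as.matrix(d)
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(dm)))
  if (nrow(dm) != length(labs)) stop2("tree and dissimilarities disagree on item count")
  if (!is.null(rownames(dm))) dm <- dm[labs, labs, drop = FALSE]
  n <- length(labs)

  gap_frac <- c(0.45, 0.35, 0.25, 0.15, 0.05)[deep_split + 1L]
  cut_frac <- c(0.60, 0.40, 0.25, 0.15, 0.08)[deep_split + 1L]
  merge <- tree$merge
  h <- tree$height

  # leaf members of every internal node, bottom-up
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    get_m <- function(id) if (id < 0L) -id else members[[id]]
    members[[i]] <- c(get_m(merge[i, 1L]), get_m(merge[i, 2L]))
  }
  node_height <- function(id) if (id < 0L) 0 else h[id]
  node_size <- function(id) if (id < 0L) 1L else length(members[[id]])

  # forest after removing joins above the adaptive cut height: between-
  # cluster joins sit well above the bulk of the merge heights, so the cut
  # is placed between the median height and the top join, closer to the
  # median the deeper the requested split
  cut_height <- min(stats::median(h) + cut_frac * (max(h) - stats::median(h)),
                    0.99 * max(h))
  kept <- h <= cut_height
  is_child <- logical(n - 1L)       # internal node consumed by a kept merge
  leaf_child <- logical(n)          # leaf consumed by a kept merge
  for (i in which(kept)) {
    for (ch in merge[i, ]) {
      if (ch < 0L) leaf_child[-ch] <- TRUE else is_child[ch] <- TRUE
    }
  }
  roots <- c(which(kept & !is_child), -which(!leaf_child))

  clusters <- list()
  unlabeled <- integer(0)
  split_node <- function(id) {
    if (id < 0L) { unlabeled <<- c(unlabeled, -id); return(invisible()) }
    mem <- members[[id]]
    if (length(mem) < min_cluster_size) {
      unlabeled <<- c(unlabeled, mem); return(invisible())
    }
    a <- merge[id, 1L]; b <- merge[id, 2L]
    splittable <- h[id] > 0 &&
      node_size(a) >= min_cluster_size && node_size(b) >= min_cluster_size &&
      (h[id] - max(node_height(a), node_height(b))) >= gap_frac * h[id]
    if (splittable) {
      split_node(a); split_node(b)
    } else {
      clusters[[length(clusters) + 1L]] <<- mem
    }
  }
  for (r in roots) split_node(r)

  out <- integer(n)
  names(out) <- labs
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k

  # stage 2: medoid-proximity assignment of stray items
  if (length(unlabeled) && length(clusters)) {
    medoid <- integer(length(clusters))
    radius <- numeric(length(clusters))
    for (k in seq_along(clusters)) {
      mem <- clusters[[k]]
      tot <- rowSums(dm[mem, mem, drop = FALSE])
      best <- which(tot <= min(tot) + 1e-12)
      medoid[k] <- mem[best[order(labs[mem[best]])[1L]]]
      radius[k] <- max(dm[medoid[k], mem])
    }
    for (i in unlabeled) {
      dmed <- dm[i, medoid]
      k <- order(dmed, labs[medoid])[1L]
      if (dmed[k] <= radius[k] + 1e-12) out[i] <- k
    }
  }

  out <- renumber_clusters(out)
  attr(out, "params") <- list(
    linkage = tree$method, deep_split = as.integer(deep_split),
    min_cluster_size = as.integer(min_cluster_size),
    cut_height = cut_height, cut_frac = cut_frac, gap_frac = gap_frac
  )
  out
}
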