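# Independent oracles used to validate the package's own implementations.

# Brute-force Ward agglomeration. At every step the merge cost of two
# clusters A, B is computed directly from the original dissimilarities via
# the within-cluster scatter identity
#   SS(C) = sum_{i<j in C} d_ij^2 / |C|,   cost(A,B) = sqrt(2 (SS(A u B) - SS(A) - SS(B)))
# (for Euclidean d this is the increase in within-cluster sum of squares),
# with the same label-lexicographic tie rule as the implementation.
# Returns the merged member-label sets and heights, step by step.
ward_oracle <- function(dm) {
  dm <- as.matrix(dm)
  labs <- rownames(dm)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(dm)))
  D2 <- dm^2
  ss <- function(mem) {
    if (length(mem) < 2L) return(0)
    sum(D2[mem, mem][upper.tri(D2[mem, mem])]) / length(mem)
  }
  clusters <- as.list(seq_len(nrow(dm)))
  steps <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    best_val <- Inf
    best_key <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        mem <- c(clusters[[i]], clusters[[j]])
        val <- sqrt(2 * (ss(mem) - ss(clusters[[i]]) - ss(clusters[[j]])))
        li <- min(labs[clusters[[i]]]); lj <- min(labs[clusters[[j]]])
        key <- c(min(li, lj), max(li, lj))
        better <- is.null(best) ||
          val < best_val - 1e-9 * (1 + abs(best_val)) ||
          (abs(val - best_val) <= 1e-9 * (1 + abs(best_val)) &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best <- c(i, j); best_val <- val; best_key <- key
        }
      }
    }
    steps[[length(steps) + 1L]] <- list(
      members = sort(labs[c(clusters[[best[1]]], clusters[[best[2]]])]),
      height = best_val
    )
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  steps
}

# Merge steps of an hclust object in the same shape as ward_oracle().
hclust_steps <- function(hc) {
  n <- length(hc$height) + 1L
  members <- vector("list", n - 1L)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    get_m <- function(id) if (id < 0L) hc$labels[-id] else members[[id]]
    members[[i]] <- c(get_m(hc$merge[i, 1L]), get_m(hc$merge[i, 2L]))
    out[[i]] <- list(members = sort(members[[i]]), height = hc$height[i])
  }
  out
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of a
# population of N genes of which the first K are annotated, and count the
# subsets with at least k annotated members.
hyper_oracle <- function(k, n, K, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  combos <- utils::combn(N, n)
  hits <- colSums(combos <= K)
  mean(hits >= k)
}

# Adjusted Rand index between two labellings (via mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Tiny two-block binary profile matrix used by several clustering tests.
two_block_matrix <- function(block = 10L, cols = 6L) {
  m <- matrix(0L, 2L * block, cols)
  m[seq_len(block), seq_len(cols %/% 2)] <- 1L
  m[block + seq_len(block), (cols %/% 2 + 1L):cols] <- 1L
  rownames(m) <- sprintf("g%02d", seq_len(2L * block))
  colnames(m) <- sprintf("E%02d", seq_len(cols))
  m
}
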