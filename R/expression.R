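#' Filter overexpressed genes from a differential-expression table
#'
#' Keeps genes significantly overexpressed in the multiciliated condition:
#' log fold-change at or above `logfc_min` and p-value at or below `p_max`.
#' Both thresholds are inclusive. Duplicate `gene_id` rows (a gene measured
#' by several probes or transcripts) are resolved before filtering by
#' keeping the row with the smallest p-value (ties: largest logFC).
#'
#' @param table Data frame with columns `gene_id`, `logfc`, `pvalue`.
#' @param logfc_min Minimum log fold-change, inclusive. Default 1.
#' @param p_max Maximum p-value, inclusive. Default 0.05.
#' @return Character vector of overexpressed gene ids (sorted, unique).
#' @export
filter_overexpressed <- function(table, logfc_min = 1, p_max = 0.05) {
  if (!all(c("gene_id", "logfc", "pvalue") %in% names(table))) {
    stop2("table needs columns gene_id, logfc, pvalue")
  }
  if (!is.finite(logfc_min) || !is.finite(p_max)) stop2("thresholds must be finite")
  bad <- !is.finite(table$logfc) | !is.finite(table$pvalue) |
    is.na(table$gene_id) | table$gene_id == ""
  if (any(bad)) {
    stop2("rows with missing values for gene(s): ",
          paste(utils::head(table$gene_id[bad], 5L), collapse = ", "))
  }
  if (any(table$pvalue < 0 | table$pvalue > 1)) stop2("pvalue outside [0, 1]")
  # dedup: smallest p, then largest logFC
  ord <- order(table$gene_id, table$pvalue, -table$logfc)
  table <- table[ord, ][!duplicated(table$gene_id[ord]), ]
  sort(table$gene_id[table$logfc >= logfc_min & table$pvalue <= p_max])
}

#' Harmonize gene identifiers to human symbols via ortholog maps
#'
#' Replaces each source gene of each experiment by all of its mapped human
#' symbols (union semantics: a source gene with several human co-orthologs
#' marks every one of them). Unmapped genes are dropped; the number dropped
#' per experiment is recorded in the `n_unmapped` attribute.
#'
#' @param gene_sets Named list of character vectors, one per experiment.
#' @param maps Named list parallel to `gene_sets`: either the string
#'   `"identity"` (human-source experiment, symbols kept as-is) or a data
#'   frame with columns `source_gene`, `target_gene`.
#' @return Named list of character vectors of human symbols, with attribute
#'   `n_unmapped` (named integer vector).
#' @export
harmonize_ids <- function(gene_sets, maps) {
  missing_map <- setdiff(names(gene_sets), names(maps))
  if (length(missing_map)) {
    stop2("no ortholog map for experiment(s): ", paste(missing_map, collapse = ", "))
  }
  n_unmapped <- integer(length(gene_sets))
  names(n_unmapped) <- names(gene_sets)
  out <- lapply(names(gene_sets), function(ex) {
    genes <- gene_sets[[ex]]
    map <- maps[[ex]]
    if (identical(map, "identity")) return(sort(unique(genes)))
    if (!all(c("source_gene", "target_gene") %in% names(map))) {
      stop2("ortholog map for ", ex, " needs columns source_gene, target_gene")
    }
    hit <- map$source_gene %in% genes
    n_unmapped[ex] <<- sum(!genes %in% map$source_gene)
    sort(unique(map$target_gene[hit]))
  })
  names(out) <- names(gene_sets)
  if (any(n_unmapped > 0L)) {
    message("harmonize_ids: dropped ", sum(n_unmapped), " unmapped gene(s) (",
            paste(sprintf("%s: %d", names(n_unmapped)[n_unmapped > 0],
                          n_unmapped[n_unmapped > 0]), collapse = ", "), ")")
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build the binary gene-by-experiment overexpression matrix
#'
#' One row per gene ever overexpressed, one column per experiment; cell
#' `(g, e)` is 1 when gene `g` is overexpressed in experiment `e`. Rows are
#' ordered lexicographically, columns follow the input experiment order.
#'
#' @param gene_sets Named list (>= 2 elements) of character vectors of
#'   overexpressed genes per experiment.
#' @return Integer 0/1 matrix with gene row names and experiment column names.
#' @export
build_binary_matrix <- function(gene_sets) {
  if (length(gene_sets) < 2L) stop2("need >= 2 experiments")
  genes <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  if (length(genes) == 0L) stop2("no overexpressed genes in any experiment")
  m <- vapply(gene_sets, function(s) as.integer(genes %in% s),
              integer(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(gene_sets)))
  stopifnot(all(rowSums(m) >= 1L))
  m
}

#' Drop genes overexpressed in a single experiment
#'
#' A cluster whose members are all overexpressed in exactly one experiment
#' carries no cross-experiment signal and is removed wholesale; in addition
#' any individual gene with a single-experiment profile is excluded, so the
#' retained genes are overexpressed in at least two experiments.
#'
#' @param matrix Binary gene-by-experiment matrix ([build_binary_matrix()]).
#' @param clusters Named integer cluster labels covering the matrix rows
#'   ([dynamic_hybrid_cut()]).
#' @return List with `retained` and `removed` (character vectors partitioning
#'   the rows) and `removed_clusters` (integer ids of dropped clusters).
#' @export
drop_single_experiment_genes <- function(matrix, clusters) {
  genes <- rownames(matrix)
  if (!all(genes %in% names(clusters))) stop2("clusters must cover all matrix rows")
  rs <- rowSums(matrix)
  ids <- setdiff(unique(clusters[genes]), 0L)
  removed_clusters <- ids[vapply(ids, function(i) {
    all(rs[genes[clusters[genes] == i]] == 1L)
  }, logical(1))]
  removed <- genes[clusters[genes] %in% removed_clusters | rs == 1L]
  list(retained = setdiff(genes, removed), removed = removed,
       removed_clusters = sort(as.integer(removed_clusters)))
}

#' Per-cluster overexpression signatures and signature groups
#'
#' For every cluster and experiment, the fraction of the cluster's genes
#' overexpressed in that experiment. A cluster's signature set is the
#' experiments where this fraction reaches `signature_threshold`; clusters
#' sharing an identical signature set are reported as one signature group
#' (e.g. the group of clusters driven by the same regulators).
#'
#' @param matrix Binary gene-by-experiment matrix.
#' @param clusters Named integer cluster labels covering the rows; label 0
#'   (unassigned) is ignored.
#' @param signature_threshold Fraction in (0, 1]; default 0.5.
#' @return List with `fractions` (cluster x experiment matrix), `signature`
#'   (list: cluster id -> character vector of experiments), and `groups`
#'   (data frame `cluster`, `group`: clusters with equal signatures share a
#'   group label formed from the signature set).
#' @export
cluster_signatures <- function(matrix, clusters, signature_threshold = 0.5) {
  check_fraction(signature_threshold, "signature_threshold")
  genes <- rownames(matrix)
  if (!all(genes %in% names(clusters))) stop2("clusters must cover all matrix rows")
  lab <- clusters[genes]
  ids <- sort(setdiff(unique(lab), 0L))
  if (length(ids) == 0L) stop2("no non-empty clusters")
  fr <- t(vapply(ids, function(i) colMeans(matrix[lab == i, , drop = FALSE]),
                 numeric(ncol(matrix))))
  rownames(fr) <- ids
  sig <- lapply(ids, function(i) {
    colnames(matrix)[fr[as.character(i), ] >= signature_threshold]
  })
  names(sig) <- ids
  key <- vapply(sig, function(s) paste(s, collapse = "+"), character(1))
  groups <- data.frame(cluster = ids, group = ifelse(key == "", "(none)", key),
                       stringsAsFactors = FALSE)
  list(fractions = fr, signature = sig, groups = groups,
       signature_threshold = signature_threshold)
}
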