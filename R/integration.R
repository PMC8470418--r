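#' The eight known multiciliation genes appended to the candidate list
#'
#' Core multiciliogenesis regulators used as positive anchors when
#' characterizing the candidate list: CCNO, GEMC1, CEP63, CEP152, E2F4,
#' E2F5, CCDC78 and CDC20B.
#'
#' @return Character vector of eight gene symbols.
#' @export
known_multiciliation_genes <- function() {
  c("CCNO", "GEMC1", "CEP63", "CEP152", "E2F4", "E2F5", "CCDC78", "CDC20B")
}

#' Intersect expression and conservation evidence into the candidate list
#'
#' A gene becomes a candidate when it is retained by the expression screen
#' (overexpressed in >= 2 experiments, non-single-experiment cluster) AND
#' flagged by the differential-conservation screen (ABSENT, HIGH_DIVERGENCE
#' or MILD_DIVERGENCE in the focal clade).
#'
#' @param retained_genes Character vector from
#'   [drop_single_experiment_genes()]`$retained`.
#' @param calls Conservation calls data frame (`gene`, `category`) from
#'   [screen_proteome()]`$calls`.
#' @return List with `candidates` (sorted character vector) and `counts`
#'   (named integer vector per flagged category).
#' @export
integrate_candidates <- function(retained_genes, calls) {
  flagged_levels <- c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE")
  sub <- calls[calls$gene %in% retained_genes &
                 calls$category %in% flagged_levels, ]
  counts <- vapply(flagged_levels, function(l) sum(sub$category == l), integer(1))
  list(candidates = sort(unique(sub$gene)), counts = counts)
}

#' Append known genes to the candidate list
#'
#' Union of candidates and the known-gene list, duplicates merged; flags
#' record where each target came from.
#'
#' @param candidates Character vector of candidate genes.
#' @param known Character vector of known genes; defaults to
#'   [known_multiciliation_genes()].
#' @return Data frame `gene`, `is_candidate`, `is_known`, sorted by gene.
#' @export
append_known <- function(candidates, known = known_multiciliation_genes()) {
  if (length(known) == 0L) stop2("known gene list must be non-empty")
  genes <- sort(unique(c(candidates, known)))
  data.frame(gene = genes,
             is_candidate = genes %in% candidates,
             is_known = genes %in% known,
             stringsAsFactors = FALSE)
}

#' Assemble the per-gene evidence table
#'
#' Merges all pipeline layers into one row per target gene: overexpression
#' breadth and cluster, cluster signature group, conservation category,
#' network community, profile cluster and pattern, and annotation count.
#'
#' @param targets Data frame from [append_known()].
#' @param matrix Binary gene-by-experiment matrix (may omit some targets).
#' @param expression_clusters Named cluster labels over the matrix rows.
#' @param signatures Result of [cluster_signatures()].
#' @param calls Conservation calls data frame.
#' @param network_membership Named community labels (or NULL).
#' @param profile_clusters Named profile-cluster labels (or NULL).
#' @param profile_annotation Result of [annotate_clusters()] (or NULL).
#' @param annotations An [annotation_map()] (or NULL; then annotation
#'   counts are 0).
#' @return Data frame with one [CandidateEvidence] row per target:
#'   `gene`, `is_candidate`, `is_known`, `overexpr_count`,
#'   `expression_cluster`, `cluster_signature_group`,
#'   `conservation_category`, `network_cluster`, `profile_cluster`,
#'   `profile_patterns` (labels joined by ";"), `annotation_count`.
#' @export
assemble_evidence <- function(targets, matrix, expression_clusters, signatures,
                              calls, network_membership = NULL,
                              profile_clusters = NULL,
                              profile_annotation = NULL,
                              annotations = NULL) {
  g <- targets$gene
  idx <- match(g, rownames(matrix))
  overexpr <- ifelse(is.na(idx), 0L, rowSums(matrix)[idx])
  expr_cl <- ifelse(g %in% names(expression_clusters),
                    expression_clusters[g], NA_integer_)
  grp <- signatures$groups
  sig_group <- grp$group[match(expr_cl, grp$cluster)]
  cons <- calls$category[match(g, calls$gene)]
  cons[is.na(cons)] <- "NOT_EVALUABLE"
  net_cl <- if (is.null(network_membership)) NA_integer_ else {
    ifelse(g %in% names(network_membership), network_membership[g], NA_integer_)
  }
  prof_cl <- if (is.null(profile_clusters)) NA_integer_ else {
    ifelse(g %in% names(profile_clusters), profile_clusters[g], NA_integer_)
  }
  prof_pat <- rep(NA_character_, length(g))
  if (!is.null(profile_annotation)) {
    pat <- vapply(profile_annotation$patterns, paste, character(1), collapse = ";")
    prof_pat <- ifelse(is.na(prof_cl) | prof_cl == 0L, NA_character_,
                       pat[as.character(prof_cl)])
  }
  ann_count <- rep(0L, length(g))
  if (!is.null(annotations)) {
    per_gene <- table(unlist(annotations$terms, use.names = FALSE))
    hit <- g %in% names(per_gene)
    ann_count[hit] <- as.integer(per_gene[g[hit]])
  }
  data.frame(gene = g, is_candidate = targets$is_candidate,
             is_known = targets$is_known,
             overexpr_count = as.integer(overexpr),
             expression_cluster = as.integer(expr_cl),
             cluster_signature_group = sig_group,
             conservation_category = cons,
             network_cluster = as.integer(net_cl),
             profile_cluster = as.integer(prof_cl),
             profile_patterns = prof_pat,
             annotation_count = ann_count,
             stringsAsFactors = FALSE)
}

#' Select the most promising poorly characterized candidates
#'
#' A target is promising when (i) it is essentially unannotated
#' (`annotation_count <= max_annotations`), (ii) its phylogenetic profile
#' points at cilia -- its profile cluster carries a ciliary-like pattern
#' label or is explicitly listed in `ciliary_profile_clusters` -- and
#' (iii) its conservation category is flagged (ABSENT, HIGH_DIVERGENCE or
#' MILD_DIVERGENCE in the focal clade). Promising genes whose expression
#' cluster belongs to a multiciliated signature group rank first; ordering
#' is deterministic (rank, then gene symbol).
#'
#' @param evidence Evidence data frame from [assemble_evidence()] (or any
#'   data frame with the columns it produces).
#' @param ciliary_profile_clusters Integer ids of profile clusters whose
#'   clade distribution matches ciliation/multiciliation.
#' @param multiciliated_signature_groups Character labels of expression
#'   signature groups considered multiciliated.
#' @param max_annotations Maximum annotation count of a "poorly
#'   characterized" gene. Default 0 (no annotations at all).
#' @param ciliary_patterns Profile pattern labels accepted as ciliary-like.
#' @return Subset of `evidence` with added columns `rank_class` (1 =
#'   multiciliated signature group, 2 = other) and `rank`, rows ordered by
#'   rank.
#' @export
prioritize <- function(evidence,
                       ciliary_profile_clusters = integer(0),
                       multiciliated_signature_groups = character(0),
                       max_annotations = 0L,
                       ciliary_patterns = c("ABSENT_FOCAL_CLADE",
                                            "ABSENT_NONCILIATED",
                                            "CHORDATE_RESTRICTED",
                                            "METAZOA_RESTRICTED")) {
  flagged_levels <- c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE")
  pat_hit <- vapply(seq_len(nrow(evidence)), function(i) {
    p <- evidence$profile_patterns[i]
    !is.na(p) && any(strsplit(p, ";", fixed = TRUE)[[1]] %in% ciliary_patterns)
  }, logical(1))
  cl_hit <- !is.na(evidence$profile_cluster) &
    evidence$profile_cluster %in% ciliary_profile_clusters
  promising <- evidence$annotation_count <= max_annotations &
    (pat_hit | cl_hit) &
    evidence$conservation_category %in% flagged_levels
  out <- evidence[promising, , drop = FALSE]
  in_mc <- !is.na(out$cluster_signature_group) &
    out$cluster_signature_group %in% multiciliated_signature_groups
  out$rank_class <- ifelse(in_mc, 1L, 2L)
  out <- out[order(out$rank_class, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write the evidence report
#'
#' Writes three files into `dir`: `evidence.tsv` (the full evidence table),
#' `summary.txt` (human-readable pipeline counts) and `summary.json`
#' (machine-readable counts). Output is byte-identical across re-runs on
#' the same inputs.
#'
#' @param evidence Evidence data frame from [assemble_evidence()].
#' @param summaries Named list of counts to report (numbers or named
#'   numeric vectors), e.g. candidate totals and per-category counts.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(evidence, summaries, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop2("cannot create output directory: ", dir)
  paths <- file.path(dir, c("evidence.tsv", "summary.txt", "summary.json"))
  utils::write.table(evidence, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- unlist(lapply(names(summaries), function(nm) {
    v <- summaries[[nm]]
    if (length(v) == 1L && is.null(names(v))) {
      sprintf("%s: %s", nm, format(v))
    } else {
      c(sprintf("%s:", nm),
        sprintf("  %s: %s", names(v), vapply(v, format, character(1))))
    }
  }))
  writeLines(lines, paths[2])
  jsonlite::write_json(summaries, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
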