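#' Deterministic fixture reproducing the published worked-example counts
#'
#' A fully deterministic input bundle whose planted structure yields the
#' screen's headline worked-example counts when run through the pipeline:
#' a 21,044-gene reference proteome in which 634 genes are planted as
#' focal-clade losses, 104 as strong divergences and 623 as mild
#' divergences (1361 flagged in total); of those, a disjoint
#' 41 + 10 + 63 = 114 genes are additionally overexpressed in at least two
#' of ten DE experiments, so intersecting both screens yields exactly 114
#' candidates (and 122 targets once the eight known multiciliation genes
#' are appended). The bundle also carries an evidence block for the eleven
#' named shortlist genes (C1orf189, C20orf85, C5orf24, KIAA1841, FAM181A,
#' IQCK, LRRC43, DYDC1, CFAP47, ANKRD60, TEX43) with their published
#' per-column values, plus decoy evidence rows violating each
#' prioritization criterion.
#'
#' @return List with elements:
#' \describe{
#'   \item{de_tables}{named list of ten DE tables (`gene_id`, `logfc`,
#'     `pvalue`).}
#'   \item{maps}{identity ortholog maps for the ten experiments.}
#'   \item{clade_table}{proteome-wide clade-contrast table for
#'     [screen_proteome()].}
#'   \item{table3_evidence}{evidence rows for the eleven shortlist genes.}
#'   \item{decoy_evidence}{evidence rows that must not be selected.}
#'   \item{known_genes}{the eight known multiciliation genes.}
#'   \item{ciliary_profile_clusters}{profile clusters treated as
#'     ciliary-like (5, 7, 8, 9).}
#'   \item{multiciliated_signature_groups}{signature-group label of the
#'     multiciliated expression clusters.}
#' }
#' @export
fixture_paper_counts <- function() {
  exps <- experiment_ids(10L)

  table3 <- data.frame(
    gene = c("C1orf189", "C20orf85", "C5orf24", "KIAA1841", "FAM181A",
             "IQCK", "LRRC43", "DYDC1", "CFAP47", "ANKRD60", "TEX43"),
    expression_cluster = c(13L, 18L, 3L, 19L, 9L, 12L, 22L, 8L, 12L, 17L, 18L),
    conservation_category = c("ABSENT", "ABSENT", "MILD_DIVERGENCE",
                              "MILD_DIVERGENCE", "HIGH_DIVERGENCE",
                              "MILD_DIVERGENCE", "MILD_DIVERGENCE",
                              "MILD_DIVERGENCE", "ABSENT", "ABSENT",
                              "ABSENT"),
    profile_cluster = c(9L, 9L, 8L, 5L, 8L, 7L, 8L, 8L, 5L, 9L, 9L),
    stringsAsFactors = FALSE
  )

  known <- known_multiciliation_genes()

  # candidate genes: 41 losses, 10 high, 63 mild, all overexpressed in >= 2
  # experiments; the 11 named genes are part of these counts
  n_abs3 <- sum(table3$conservation_category == "ABSENT")          # 5
  n_high3 <- sum(table3$conservation_category == "HIGH_DIVERGENCE") # 1
  n_mild3 <- sum(table3$conservation_category == "MILD_DIVERGENCE") # 5
  cand_absent <- c(table3$gene[table3$conservation_category == "ABSENT"],
                   sprintf("CANDA%03d", seq_len(41L - n_abs3)))
  cand_high <- c(table3$gene[table3$conservation_category == "HIGH_DIVERGENCE"],
                 sprintf("CANDH%03d", seq_len(10L - n_high3)))
  cand_mild <- c(table3$gene[table3$conservation_category == "MILD_DIVERGENCE"],
                 sprintf("CANDM%03d", seq_len(63L - n_mild3)))
  candidates <- c(cand_absent, cand_high, cand_mild)   # 114

  # flagged proteome genes never overexpressed (1361 - 114 of them)
  rest_absent <- sprintf("PABS%04d", seq_len(634L - 41L))
  rest_high <- sprintf("PHIGH%04d", seq_len(104L - 10L))
  rest_mild <- sprintf("PMILD%04d", seq_len(623L - 63L))

  # expression-only genes: retained but conserved, and single-experiment
  retained_conserved <- sprintf("BGRET%03d", seq_len(100L))
  single_exp <- sprintf("SINGLE%03d", seq_len(40L))

  n_total <- 21044L
  n_named <- length(candidates) + length(rest_absent) + length(rest_high) +
    length(rest_mild) + length(retained_conserved) + length(single_exp) +
    length(known)
  filler <- sprintf("PCONS%05d", seq_len(n_total - n_named))

  clade_genes <- c(candidates, rest_absent, rest_high, rest_mild,
                   retained_conserved, single_exp, known, filler)
  category <- c(
    rep(c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE"),
        c(length(cand_absent), length(cand_high), length(cand_mild))),
    rep(c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE"),
        c(length(rest_absent), length(rest_high), length(rest_mild))),
    rep("CONSERVED",
        length(retained_conserved) + length(single_exp) + length(known) +
          length(filler))
  )
  nf <- 10L; nr <- 10L
  ref_ids <- .ref_identity_profile(nr)
  target_d <- c(ABSENT = NA_real_, HIGH_DIVERGENCE = 6, MILD_DIVERGENCE = 2.25,
                CONSERVED = 0)[category]
  focal_val <- mean(ref_ids) - target_d * stats::sd(ref_ids)
  clade_table <- data.frame(
    gene = clade_genes,
    focal_presence = ifelse(category == "ABSENT", 0L, nf),
    n_focal = nf, ref_presence = nr, n_ref = nr,
    stringsAsFactors = FALSE
  )
  clade_table$focal_identities <- lapply(seq_along(clade_genes), function(i) {
    if (category[i] == "ABSENT") numeric(0) else rep(focal_val[i], nf)
  })
  clade_table$ref_identities <- rep(list(ref_ids), length(clade_genes))

  # DE tables: deterministic activation patterns, no randomness.
  # Candidates and known genes are overexpressed in >= 2 experiments;
  # single-experiment genes in exactly one; everything else sub-threshold.
  de_genes <- sort(c(candidates, known, retained_conserved, single_exp))
  active <- matrix(FALSE, length(de_genes), 10L,
                   dimnames = list(de_genes, exps))
  multi <- c(candidates, known, retained_conserved)
  for (i in seq_along(multi)) {
    e1 <- (i - 1L) %% 10L + 1L
    e2 <- (i + 2L) %% 10L + 1L
    e3 <- (i + 5L) %% 10L + 1L
    active[multi[i], c(e1, e2, e3)] <- TRUE
  }
  for (i in seq_along(single_exp)) {
    active[single_exp[i], (i - 1L) %% 10L + 1L] <- TRUE
  }
  de_tables <- lapply(exps, function(e) {
    data.frame(gene_id = de_genes,
               logfc = ifelse(active[, e], 2.5, 0.2),
               pvalue = ifelse(active[, e], 0.001, 0.5),
               stringsAsFactors = FALSE)
  })
  names(de_tables) <- exps
  maps <- stats::setNames(rep(list("identity"), 10L), exps)

  signature_group_of <- function(cl) {
    groups <- list("Foxj1/Foxn4 targets" = c(3L, 6L, 7L, 14L),
                   "MCIDAS/E2F4 and Foxj1/Foxn4 targets" = c(17L, 18L, 19L, 26L, 27L),
                   "Mouse genes" = c(22L, 24L, 25L, 28L),
                   "MCIDAS/E2F4 targets" = 20L,
                   "Multiciliated clusters" = c(8L, 9L, 12L, 13L))
    vapply(cl, function(x) {
      hit <- names(groups)[vapply(groups, function(g) x %in% g, logical(1))]
      if (length(hit)) hit[1] else NA_character_
    }, character(1))
  }
  table3_evidence <- data.frame(
    gene = table3$gene,
    is_candidate = TRUE, is_known = FALSE,
    overexpr_count = 3L,
    expression_cluster = table3$expression_cluster,
    cluster_signature_group = signature_group_of(table3$expression_cluster),
    conservation_category = table3$conservation_category,
    network_cluster = NA_integer_,
    profile_cluster = table3$profile_cluster,
    profile_patterns = NA_character_,
    annotation_count = 0L,
    stringsAsFactors = FALSE
  )
  decoy_evidence <- data.frame(
    gene = c("DECOY_ANNOTATED", "DECOY_CONSERVED", "DECOY_NONCILIARY"),
    is_candidate = TRUE, is_known = FALSE,
    overexpr_count = 3L,
    expression_cluster = c(8L, 13L, 12L),
    cluster_signature_group = "Multiciliated clusters",
    conservation_category = c("ABSENT", "CONSERVED", "MILD_DIVERGENCE"),
    network_cluster = NA_integer_,
    profile_cluster = c(9L, 8L, 2L),
    profile_patterns = NA_character_,
    annotation_count = c(12L, 0L, 0L),
    stringsAsFactors = FALSE
  )

  list(de_tables = de_tables, maps = maps, clade_table = clade_table,
       table3_evidence = table3_evidence, decoy_evidence = decoy_evidence,
       known_genes = known,
       ciliary_profile_clusters = c(5L, 7L, 8L, 9L),
       multiciliated_signature_groups = "Multiciliated clusters")
}
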