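#' Build the gene-by-species presence/absence profile matrix
#'
#' @param presence 0/1 matrix or data frame, genes in rows, species in
#'   columns (column names = species ids).
#' @param panel Species panel data frame (columns `species`, `supergroup`,
#'   `clade`, `subclade`, `ciliated`, `focal`); every matrix species must
#'   appear in it.
#' @return Integer 0/1 matrix with columns ordered as in the panel.
#' @export
build_profile_matrix <- function(presence, panel) {
  m <- as.matrix(presence)
  storage.mode(m) <- "integer"
  missing <- setdiff(colnames(m), panel$species)
  if (length(missing)) {
    stop2("species missing from panel: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  keep <- panel$species[panel$species %in% colnames(m)]
  m[, keep, drop = FALSE]
}

#' Cluster phylogenetic profiles
#'
#' Correlation distance between gene profiles, Ward.D2 linkage, dynamic
#' hybrid cut. Genes with a constant profile (present or absent everywhere)
#' have no defined correlation; they are excluded from the dendrogram and
#' returned unassigned (label 0, listed in the `not_evaluable` attribute).
#'
#' @param matrix Gene-by-species 0/1 matrix.
#' @param deep_split,min_cluster_size Passed to [dynamic_hybrid_cut()].
#' @return Named integer cluster labels over all genes (0 = unassigned).
#' @export
cluster_profiles <- function(matrix, deep_split = 2L, min_cluster_size = 20L) {
  if (nrow(matrix) < 2L) stop2("need >= 2 genes to cluster")
  const <- apply(matrix, 1L, function(r) stats::sd(r) == 0)
  usable <- rownames(matrix)[!const]
  if (length(usable) < 2L) stop2("fewer than 2 non-constant profiles")
  d <- correlation_profile_dist(matrix[usable, , drop = FALSE])
  cl <- dynamic_hybrid_cut(ward_linkage(d), d,
                           deep_split = deep_split,
                           min_cluster_size = min_cluster_size)
  out <- integer(nrow(matrix))
  names(out) <- rownames(matrix)
  out[usable] <- cl[usable]
  attr(out, "params") <- attr(cl, "params")
  attr(out, "not_evaluable") <- rownames(matrix)[const]
  out
}

#' Annotate profile clusters with clade presence patterns
#'
#' For each cluster, the mean presence fraction over the species of each
#' clade grouping is computed, and the cluster receives every pattern label
#' whose rule it satisfies (labels can co-occur; they are reported sorted):
#' \describe{
#'   \item{PRESENT_BROADLY}{fraction >= `tau_present` in every supergroup.}
#'   \item{ABSENT_NONCILIATED}{fraction <= `tau_absent` in non-ciliated
#'     species and >= `tau_present` in ciliated species.}
#'   \item{ABSENT_FOCAL_CLADE}{fraction <= `tau_absent` in the focal clade
#'     and >= `tau_present` in the other vertebrates (chordate species).}
#'   \item{CHORDATE_RESTRICTED}{>= `tau_present` in chordates, <=
#'     `tau_absent` elsewhere.}
#'   \item{METAZOA_RESTRICTED}{>= `tau_present` in metazoans, <=
#'     `tau_absent` outside Metazoa.}
#'   \item{NONE}{no rule satisfied.}
#' }
#'
#' @param matrix Gene-by-species 0/1 matrix.
#' @param clusters Named cluster labels covering the rows (0 ignored).
#' @param panel Species panel (see [build_profile_matrix()]).
#' @param tau_absent Fraction at or below which a clade counts as lacking
#'   the genes. Default 0.1.
#' @param tau_present Fraction at or above which a clade counts as carrying
#'   them. Default 0.6.
#' @return List with `patterns` (named list: cluster id -> sorted labels)
#'   and `fractions` (cluster x clade-group matrix of presence fractions).
#' @export
annotate_clusters <- function(matrix, clusters, panel,
                              tau_absent = 0.1, tau_present = 0.6) {
  check_fraction(tau_absent, "tau_absent")
  check_fraction(tau_present, "tau_present")
  genes <- rownames(matrix)
  if (!all(genes %in% names(clusters))) stop2("clusters must cover all matrix rows")
  panel <- panel[match(colnames(matrix), panel$species), ]
  groups <- list(
    focal = panel$focal,
    vertebrate_nonfocal = panel$clade == "Chordata" & !panel$focal,
    chordate = panel$clade == "Chordata",
    non_chordate = panel$clade != "Chordata",
    metazoa = panel$supergroup == "Metazoa",
    non_metazoa = panel$supergroup != "Metazoa",
    ciliated = panel$ciliated,
    non_ciliated = !panel$ciliated
  )
  sg <- split(seq_len(ncol(matrix)), panel$supergroup)
  lab <- clusters[genes]
  ids <- sort(setdiff(unique(lab), 0L))
  frac_of <- function(sub, cols) {
    if (!any(cols)) return(NA_real_)
    mean(sub[, cols, drop = FALSE])
  }
  fractions <- matrix(NA_real_, length(ids), length(groups),
                      dimnames = list(ids, names(groups)))
  patterns <- vector("list", length(ids))
  names(patterns) <- ids
  for (k in seq_along(ids)) {
    sub <- matrix[lab == ids[k], , drop = FALSE]
    fr <- vapply(groups, function(g) frac_of(sub, g), numeric(1))
    fractions[k, ] <- fr
    sg_fr <- vapply(sg, function(cols) mean(sub[, cols, drop = FALSE]), numeric(1))
    labs <- character(0)
    if (all(sg_fr >= tau_present)) labs <- c(labs, "PRESENT_BROADLY")
    if (!is.na(fr["non_ciliated"]) && fr["non_ciliated"] <= tau_absent &&
        fr["ciliated"] >= tau_present) labs <- c(labs, "ABSENT_NONCILIATED")
    if (!is.na(fr["focal"]) && fr["focal"] <= tau_absent &&
        !is.na(fr["vertebrate_nonfocal"]) &&
        fr["vertebrate_nonfocal"] >= tau_present) {
      labs <- c(labs, "ABSENT_FOCAL_CLADE")
    }
    if (!is.na(fr["chordate"]) && fr["chordate"] >= tau_present &&
        !is.na(fr["non_chordate"]) && fr["non_chordate"] <= tau_absent) {
      labs <- c(labs, "CHORDATE_RESTRICTED")
    }
    if (fr["metazoa"] >= tau_present && fr["non_metazoa"] <= tau_absent) {
      labs <- c(labs, "METAZOA_RESTRICTED")
    }
    patterns[[k]] <- if (length(labs)) sort(labs) else "NONE"
  }
  list(patterns = patterns, fractions = fractions,
       tau_absent = tau_absent, tau_present = tau_present)
}
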