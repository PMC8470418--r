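#' Parameters of the differential-conservation classifier
#'
#' @param z_hi Divergence score at or above which a gene is called
#'   HIGH_DIVERGENCE. Default 3 (standard-deviation units).
#' @param z_lo Score at or above which (but below `z_hi`) a gene is called
#'   MILD_DIVERGENCE. Default 1.5.
#' @param min_ref_presence_frac Minimum fraction of reference-clade species
#'   that must carry an ortholog for the gene to be evaluable; an ABSENT
#'   call also requires this support, so genes missing everywhere are not
#'   mistaken for focal-clade losses. Default 0.5.
#' @return List of class `conservation_params`.
#' @export
conservation_params <- function(z_hi = 3, z_lo = 1.5, min_ref_presence_frac = 0.5) {
  if (!is.numeric(z_hi) || !is.numeric(z_lo) || z_lo > z_hi) {
    stop2("need numeric thresholds with z_lo <= z_hi",
          class = "ciliascreen_config_error")
  }
  check_fraction(min_ref_presence_frac, "min_ref_presence_frac")
  structure(list(z_hi = z_hi, z_lo = z_lo,
                 min_ref_presence_frac = min_ref_presence_frac),
            class = "conservation_params")
}

#' Divergence score of a gene in the focal clade
#'
#' Standardised identity deficit of the focal clade relative to the
#' reference clade:
#' `D = (mean(reference identities) - mean(focal identities)) / sd(reference identities)`.
#' Larger D means the focal-clade orthologs are further from the human
#' query than the reference-clade spread would predict.
#'
#' @param focal_identities Percent identities (0--100) of the gene's focal-clade
#'   orthologs to the reference proteome query.
#' @param reference_identities Percent identities of the reference-clade
#'   orthologs; needs >= 2 values with nonzero spread.
#' @return Numeric score, or `NA_real_` when the score is undefined (empty
#'   focal list, < 2 reference values, or zero reference spread).
#' @export
divergence_score <- function(focal_identities, reference_identities) {
  f <- focal_identities[!is.na(focal_identities)]
  r <- reference_identities[!is.na(reference_identities)]
  if (length(f) < 1L || length(r) < 2L) return(NA_real_)
  s <- stats::sd(r)
  if (s == 0) return(NA_real_)
  (mean(r) - mean(f)) / s
}

#' Classify one gene's focal-clade conservation behaviour
#'
#' Categories, in precedence order:
#' \describe{
#'   \item{ABSENT}{no focal-clade ortholog while the reference clade has
#'     sufficient support (clade-specific gene loss).}
#'   \item{HIGH_DIVERGENCE}{divergence score `D >= z_hi`.}
#'   \item{MILD_DIVERGENCE}{`z_lo <= D < z_hi`.}
#'   \item{CONSERVED}{`D < z_lo`.}
#'   \item{NOT_EVALUABLE}{insufficient reference support or undefined score.}
#' }
#'
#' @param entry One-row list/data frame with fields `gene`, `focal_presence`,
#'   `n_focal`, `ref_presence`, `n_ref`, `focal_identities`,
#'   `ref_identities` (identity fields: numeric vectors).
#' @param params A [conservation_params()] object.
#' @return List with `gene`, `category`, `divergence_score`.
#' @export
classify_gene <- function(entry, params = conservation_params()) {
  ref_frac <- entry$ref_presence / entry$n_ref
  fid <- unlist(entry$focal_identities, use.names = FALSE)
  rid <- unlist(entry$ref_identities, use.names = FALSE)
  category <- if (ref_frac < params$min_ref_presence_frac) {
    "NOT_EVALUABLE"
  } else if (entry$focal_presence == 0L) {
    "ABSENT"
  } else {
    d <- divergence_score(fid, rid)
    if (is.na(d)) "NOT_EVALUABLE"
    else if (d >= params$z_hi) "HIGH_DIVERGENCE"
    else if (d >= params$z_lo) "MILD_DIVERGENCE"
    else "CONSERVED"
  }
  score <- if (category %in% c("ABSENT", "NOT_EVALUABLE")) NA_real_ else d
  list(gene = entry$gene, category = category, divergence_score = score)
}

#' Screen a whole proteome for differential conservation
#'
#' Applies [classify_gene()] to every row of a clade table and summarises
#' the outcome. The flagged set (candidate evolutionary signature) is the
#' union of ABSENT, HIGH_DIVERGENCE and MILD_DIVERGENCE genes.
#'
#' @param clade_table Data frame with the [classify_gene()] fields, one row
#'   per gene; `focal_identities` / `ref_identities` are list columns of
#'   numeric vectors.
#' @param params A [conservation_params()] object.
#' @return List with `calls` (data frame `gene`, `category`,
#'   `divergence_score`), `by_category` (named list of gene vectors),
#'   `counts` (named integer vector over all five categories), `flagged`
#'   (character vector) and `n_flagged`.
#' @export
screen_proteome <- function(clade_table, params = conservation_params()) {
  if (nrow(clade_table) < 1L) stop2("empty clade table")
  cats <- character(nrow(clade_table))
  score <- numeric(nrow(clade_table))
  ref_frac <- clade_table$ref_presence / clade_table$n_ref
  for (i in seq_len(nrow(clade_table))) {
    cl <- classify_gene(list(
      gene = clade_table$gene[i],
      focal_presence = clade_table$focal_presence[i],
      n_focal = clade_table$n_focal[i],
      ref_presence = clade_table$ref_presence[i],
      n_ref = clade_table$n_ref[i],
      focal_identities = clade_table$focal_identities[[i]],
      ref_identities = clade_table$ref_identities[[i]]
    ), params)
    cats[i] <- cl$category
    score[i] <- if (is.null(cl$divergence_score)) NA_real_ else cl$divergence_score
  }
  levels <- c("ABSENT", "HIGH_DIVERGENCE", "MILD_DIVERGENCE", "CONSERVED",
              "NOT_EVALUABLE")
  calls <- data.frame(gene = clade_table$gene, category = cats,
                      divergence_score = score, stringsAsFactors = FALSE)
  by_category <- lapply(levels, function(l) sort(calls$gene[calls$category == l]))
  names(by_category) <- levels
  counts <- vapply(by_category, length, integer(1))
  flagged <- sort(unlist(by_category[1:3], use.names = FALSE))
  list(calls = calls, by_category = by_category, counts = counts,
       flagged = flagged, n_flagged = length(flagged))
}
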