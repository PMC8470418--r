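#' Upper-tail hypergeometric over-representation test
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes without replacement from a population of `N` genes of which `K`
#' carry the annotation:
#' `p = sum_{i = k..min(n, K)} C(K, i) C(N - K, n - i) / C(N, n)`.
#'
#' @param k Annotated genes observed in the study set.
#' @param n Study-set size.
#' @param K Annotated genes in the population.
#' @param N Population size.
#' @return Upper-tail p-value in `[0, 1]`.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  k <- check_count(k, "k"); n <- check_count(n, "n")
  K <- check_count(K, "K"); N <- check_count(N, "N")
  if (n > N || K > N || k > min(n, K)) {
    stop2("need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Construct an annotation map
#'
#' @param term2gene Data frame with columns `term_id`, `gene` and optionally
#'   `term_name`.
#' @param population Character vector of all genes the enrichment universe
#'   should contain; defaults to every annotated gene.
#' @return List of class `annotation_map` with `terms` (named list of gene
#'   vectors), `term_names` and `population`.
#' @export
annotation_map <- function(term2gene, population = NULL) {
  if (!all(c("term_id", "gene") %in% names(term2gene))) {
    stop2("term2gene needs columns term_id, gene")
  }
  terms <- lapply(split(term2gene$gene, term2gene$term_id), function(g) {
    sort(unique(g))
  })
  if (is.null(population)) population <- sort(unique(term2gene$gene))
  population <- sort(unique(population))
  stray <- setdiff(unlist(terms, use.names = FALSE), population)
  if (length(stray)) {
    stop2("annotated gene(s) outside population: ",
          paste(utils::head(stray, 5L), collapse = ", "))
  }
  term_names <- if ("term_name" %in% names(term2gene)) {
    tn <- term2gene$term_name[!duplicated(term2gene$term_id)]
    names(tn) <- term2gene$term_id[!duplicated(term2gene$term_id)]
    tn[names(terms)]
  } else {
    stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms, term_names = term_names,
                 population = population),
            class = "annotation_map")
}

#' Term over-representation in a study gene set
#'
#' One hypergeometric test per annotation term with at least one annotated
#' population gene, with multiple-testing correction
#' (Benjamini--Hochberg by default). Results are sorted by
#' (`adjusted_p`, `term_id`), so ties rank deterministically.
#'
#' @param study Character vector of study genes (must lie in the
#'   population).
#' @param annotations An [annotation_map()].
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return Data frame with columns `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `p_value`, `adjusted_p`.
#' @export
enrich <- function(study, annotations, correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(annotations, "annotation_map"))
  study <- unique(study)
  outside <- setdiff(study, annotations$population)
  if (length(outside)) {
    stop2("study gene(s) outside the population: ",
          paste(utils::head(outside, 10L), collapse = ", "))
  }
  N <- length(annotations$population)
  n <- length(study)
  terms <- annotations$terms
  res <- data.frame(
    term_id = names(terms),
    term_name = unname(annotations$term_names[names(terms)]),
    k = vapply(terms, function(g) length(intersect(study, g)), integer(1)),
    n = n,
    K = vapply(terms, length, integer(1)),
    N = N,
    stringsAsFactors = FALSE
  )
  res <- res[res$K >= 1L, ]
  res$p_value <- mapply(hypergeometric_test, res$k, res$n, res$K, res$N)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = correction)
  res <- res[order(res$adjusted_p, res$term_id), ]
  rownames(res) <- NULL
  res
}
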