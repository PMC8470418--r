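#' Jaccard distance between two binary profiles
#'
#' Distance between two 0/1 overexpression (or presence) profiles:
#' `1 - |intersection| / |union|` of their supports. This is the "binary"
#' dissimilarity used to compare gene overexpression profiles across
#' experiments.
#'
#' @param a,b Numeric or logical vectors of equal length containing only 0/1
#'   values. At least one of the two must have a nonzero entry.
#' @return A single numeric distance in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1 - 1/3
#' @export
jaccard_distance <- function(a, b) {
  a <- as.integer(as.logical(a))
  b <- as.integer(as.logical(b))
  if (length(a) != length(b)) stop2("profiles must have equal length")
  u <- sum(a | b)
  if (u == 0L) stop2("Jaccard distance undefined for two all-zero profiles")
  1 - sum(a & b) / u
}

#' Jaccard distance matrix for a binary profile matrix
#'
#' Pairwise Jaccard distances between the rows of a 0/1 matrix, as a
#' [stats::dist] object suitable for [ward_linkage()].
#'
#' @param x 0/1 matrix, items in rows. Every row must have at least one
#'   nonzero entry.
#' @return A `dist` object.
#' @export
binary_profile_dist <- function(x) {
  x <- as.matrix(x)
  if (any(rowSums(x != 0) == 0L)) {
    stop2("all-zero rows have no defined Jaccard distance; drop them first")
  }
  stats::dist(x, method = "binary")
}

#' Correlation distance between two presence/absence profiles
#'
#' `1 - r` where `r` is the Pearson correlation of the two profiles, so the
#' distance lies in `[0, 2]` (0 = identical up to affine scaling, 2 = perfectly
#' anti-correlated). A constant profile has no defined correlation; by
#' convention it is placed at the maximal distance 2 from every partner so
#' clustering stays total.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return A single numeric distance in `[0, 2]`.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b)) stop2("profiles must have equal length")
  if (length(a) < 2L) stop2("profiles must have length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(2)
  1 - stats::cor(a, b)
}

#' Correlation distance matrix for a profile matrix
#'
#' Pairwise `1 - Pearson` distances between rows. Constant rows (all-0 or
#' all-1 phylogenetic profiles) get the sentinel distance 2 to every other
#' row and 0 to themselves.
#'
#' @param x Numeric matrix, items in rows, >= 2 columns.
#' @return A `dist` object with values in `[0, 2]`.
#' @export
correlation_profile_dist <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop2("need >= 2 columns for correlation distance")
  const <- apply(x, 1L, function(r) stats::sd(r) == 0)
  d <- matrix(2, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  if (any(!const)) {
    cc <- stats::cor(t(x[!const, , drop = FALSE]))
    d[!const, !const] <- 1 - cc
  }
  diag(d) <- 0
  stats::as.dist(d)
}
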