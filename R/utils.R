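#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. Errors are classed so tests can target them.

stop2 <- function(..., class = "ciliascreen_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop2(name, " must be a fraction in [0, 1]", class = "ciliascreen_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) || any(x != floor(x))) {
    stop2(name, " must be an integer count >= ", min,
          class = "ciliascreen_config_error")
  }
  invisible(as.integer(x))
}

# Renumber a cluster labelling so cluster 1 is the largest (ties broken by
# the lexicographically smallest member name); 0 (unassigned) is preserved.
renumber_clusters <- function(labels) {
  stopifnot(!is.null(names(labels)))
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0L) return(labels)
  size <- vapply(ids, function(i) sum(labels == i), integer(1))
  first <- vapply(ids, function(i) min(names(labels)[labels == i]), character(1))
  ord <- ids[order(-size, first)]
  out <- labels
  for (k in seq_along(ord)) out[labels == ord[k]] <- k
  out
}
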