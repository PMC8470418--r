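#' @name pipeline_io
#' @title TSV readers and writers for all pipeline tables
#'
#' @description
#' All pipeline inputs and outputs are tab-separated text with a header
#' row. Each writer/reader pair round-trips its table losslessly:
#' DE tables (`gene_id`, `logfc`, `pvalue`), two-column ortholog maps,
#' binary profile matrices (gene rows, experiment or species columns),
#' clade tables (identity lists as comma-joined values), species panels,
#' weighted edge lists, annotation maps and cluster assignments.
#'
#' @param x Table to write (see the individual writer).
#' @param path File path.
#' @return Readers return the parsed table; writers return `path`
#'   invisibly.
NULL

write_tsv <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               row_label),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @rdname pipeline_io
#' @export
write_de_table <- function(x, path) {
  write_tsv(x[, c("gene_id", "logfc", "pvalue")], path)
}

#' @rdname pipeline_io
#' @export
read_de_table <- function(path) {
  x <- read_tsv(path)
  if (!all(c("gene_id", "logfc", "pvalue") %in% names(x))) {
    stop2("DE table needs header gene_id, logfc, pvalue: ", path)
  }
  x
}

#' @rdname pipeline_io
#' @export
write_ortholog_map <- function(x, path) {
  write_tsv(x[, c("source_gene", "target_gene")], path)
}

#' @rdname pipeline_io
#' @export
read_ortholog_map <- function(path) {
  x <- read_tsv(path)
  if (!all(c("source_gene", "target_gene") %in% names(x))) {
    stop2("ortholog map needs header source_gene, target_gene: ", path)
  }
  if (any(x$source_gene == "" | x$target_gene == "")) {
    stop2("empty labels in ortholog map: ", path)
  }
  x
}

#' @rdname pipeline_io
#' @export
write_binary_matrix <- function(x, path) {
  write_tsv(x, path, row_label = "gene")
}

#' @rdname pipeline_io
#' @export
read_binary_matrix <- function(path) {
  x <- read_tsv(path)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x[[1]]
  m
}

#' @rdname pipeline_io
#' @export
write_clade_table <- function(x, path) {
  flat <- x[, c("gene", "focal_presence", "n_focal", "ref_presence", "n_ref")]
  flat$focal_identities <- vapply(x$focal_identities, paste,
                                  character(1), collapse = ",")
  flat$ref_identities <- vapply(x$ref_identities, paste,
                                character(1), collapse = ",")
  write_tsv(flat, path)
}

#' @rdname pipeline_io
#' @export
read_clade_table <- function(path) {
  x <- read_tsv(path, colClasses = list(focal_identities = "character",
                                        ref_identities = "character"))
  parse_csv <- function(s) {
    lapply(s, function(v) if (is.na(v) || v == "") numeric(0)
           else as.numeric(strsplit(v, ",", fixed = TRUE)[[1]]))
  }
  x$focal_identities <- parse_csv(x$focal_identities)
  x$ref_identities <- parse_csv(x$ref_identities)
  x
}

#' @rdname pipeline_io
#' @export
write_species_panel <- function(x, path) {
  write_tsv(x[, c("species", "supergroup", "clade", "subclade",
                  "ciliated", "focal")], path)
}

#' @rdname pipeline_io
#' @export
read_species_panel <- function(path) {
  x <- read_tsv(path)
  x$ciliated <- as.logical(x$ciliated)
  x$focal <- as.logical(x$focal)
  x
}

#' @rdname pipeline_io
#' @export
write_edge_list <- function(x, path) {
  write_tsv(x[, c("gene_a", "gene_b", "score")], path)
}

#' @rdname pipeline_io
#' @export
read_edge_list <- function(path) {
  x <- read_tsv(path)
  if (!all(c("gene_a", "gene_b", "score") %in% names(x))) {
    stop2("edge list needs header gene_a, gene_b, score: ", path)
  }
  x
}

#' @rdname pipeline_io
#' @export
write_annotation_table <- function(x, path) {
  write_tsv(x[, c("term_id", "term_name", "gene")], path)
}

#' @rdname pipeline_io
#' @export
read_annotation_table <- function(path) {
  x <- read_tsv(path)
  if (!all(c("term_id", "gene") %in% names(x))) {
    stop2("annotation table needs header term_id, term_name, gene: ", path)
  }
  x
}

#' @rdname pipeline_io
#' @export
write_cluster_assignment <- function(x, path) {
  write_tsv(data.frame(item = names(x), cluster = as.integer(x),
                       stringsAsFactors = FALSE), path)
}

#' @rdname pipeline_io
#' @export
read_cluster_assignment <- function(path) {
  x <- read_tsv(path)
  stats::setNames(as.integer(x$cluster), x$item)
}
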