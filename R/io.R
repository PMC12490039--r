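# Readers and writers for the pipeline's plain-text interchange formats:
# expression / condition TSV, GMT gene sets, parent-child ontology TSV,
# drug-signature library TSV, edge tables and GraphML.

#' Read an expression matrix and its condition labels
#'
#' Expression is a TSV with genes as rows (first column gene symbols) and
#' samples as columns; conditions a two-column TSV (`sample`, `condition`).
#' Every sample must have a condition; non-numeric or missing cells are
#' rejected with the offending location named.
#'
#' @param path expression TSV path.
#' @param condition_path condition TSV path.
#' @return List with `expr` (wide tibble) and `conditions` (tibble).
#' @export
read_expression <- function(path, condition_path) {
  expr <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  names(expr)[1] <- "gene"
  if (anyDuplicated(names(expr))) abort("duplicate sample id in expression header")
  for (j in seq(2, ncol(expr))) {
    v <- suppressWarnings(as.numeric(expr[[j]]))
    if (anyNA(v)) {
      abort(sprintf("parse error: non-numeric value in column '%s', row %d",
                    names(expr)[j], which(is.na(v))[1]))
    }
    expr[[j]] <- v
  }
  conditions <- readr::read_tsv(condition_path,
                                col_types = readr::cols(.default = readr::col_character()))
  names(conditions)[1:2] <- c("sample", "condition")
  check_conditions(conditions, names(expr)[-1])
  list(expr = expr, conditions = conditions)
}

#' Write an expression matrix and condition labels as TSV
#' @param expr wide expression tibble (first column `gene`).
#' @param conditions tibble (`sample`, `condition`).
#' @param path,condition_path output paths.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, conditions, path, condition_path) {
  readr::write_tsv(expr, path)
  readr::write_tsv(conditions, condition_path)
  invisible(path)
}

#' Read or write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) abort("duplicate set name in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write an ontology as a parent-child TSV
#' @param path file path; two columns `child`, `parent`.
#' @return `read_ontology_edges()`: tibble (`child`, `parent`).
#' @export
read_ontology_edges <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' @rdname read_ontology_edges
#' @param edges tibble (`child`, `parent`).
#' @export
write_ontology_edges <- function(edges, path) {
  readr::write_tsv(edges[, c("child", "parent")], path)
  invisible(path)
}

#' Read or write a drug-signature library as long TSV
#' @param path file path; columns `drug`, `gene`, `score`.
#' @return `read_drug_library()`: long tibble.
#' @export
read_drug_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = "ccd")
  names(lib)[1:3] <- c("drug", "gene", "score")
  dup <- dplyr::summarise(dplyr::group_by(lib, .data$drug),
                          dup = anyDuplicated(.data$gene) > 0)
  if (any(dup$dup)) abort("duplicate gene within a drug profile")
  lib
}

#' @rdname read_drug_library
#' @param library long tibble (`drug`, `gene`, `score`).
#' @export
write_drug_library <- function(library, path) {
  readr::write_tsv(library, path)
  invisible(path)
}

#' Export a weighted edge table to GraphML
#'
#' Keeps edges at or above `min_weight` (mirroring the convention of
#' displaying only edges exceeding a weight of 0.3 in co-expression network
#' figures) and writes GraphML via igraph.
#'
#' @param edges data frame whose first two columns are endpoints and which
#'   has a `weight` column; extra columns become edge attributes.
#' @param path output path.
#' @param min_weight minimum edge weight retained (default 0.3).
#' @param directed logical.
#' @return Invisibly, the igraph object written.
#' @export
write_graphml <- function(edges, path, min_weight = 0.3, directed = FALSE) {
  keep <- edges[edges$weight >= min_weight, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep, directed = directed)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
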