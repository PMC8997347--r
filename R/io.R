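# Plain-text readers and writers for every artifact the pipeline exchanges.
# All formats are tab-separated with a header row; lines starting with '#'
# are comments. Gene/node order is preserved on round-trip.

read_tsv_checked <- function(path, required, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s '%s' lacks required columns: %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and write expression matrices
#'
#' Expression matrices are stored genes-as-rows, one column per sample, with
#' a leading `gene` column. Duplicate gene identifiers are rejected.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_checked(path, "gene", "expression table")
  if (anyDuplicated(df$gene)) {
    dup <- df$gene[duplicated(df$gene)][1]
    stop(sprintf("duplicate gene id '%s' in %s", dup, path), call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(colnames(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression_tsv
#' @param mat numeric matrix with gene rownames.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write shape-feature tables
#'
#' Rows are samples (cell lines) or single cells; columns are morphology
#' features. A leading `sample` column carries identifiers; an optional
#' `batch` column carries batch labels.
#'
#' @param path file path.
#' @return data.frame with `sample` column and numeric feature columns.
#' @export
read_shape_tsv <- function(path) {
  read_tsv_checked(path, "sample", "shape-feature table")
}

#' @rdname read_shape_tsv
#' @param df data.frame with a `sample` column.
#' @export
write_shape_tsv <- function(df, path) {
  stopifnot("sample" %in% colnames(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Regulon sign is encoded by a name suffix: `TF+` (activated),
#' `TF-` (repressed), `TF?` (unknown sign).
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept as an
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed GMT line %d in %s (need name, description, >=1 member)",
                 bad[1], path), call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write signed edge lists
#'
#' Prior-network edges: columns `source`, `target`, `sign` (+1/-1),
#' `n_sources` (citation count >= 1). Assembled-network edges add `weight`
#' and `origin`.
#'
#' @param path file path.
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_checked(path, c("source", "target", "sign"), "edge list")
  if (!all(df$sign %in% c(-1L, 1L))) {
    bad <- which(!(df$sign %in% c(-1L, 1L)))[1]
    stop(sprintf("edge list %s row %d: sign must be +1 or -1 (got %s)",
                 path, bad, df$sign[bad]), call. = FALSE)
  }
  if ("n_sources" %in% colnames(df) && any(df$n_sources < 1L)) {
    stop(sprintf("edge list %s: n_sources must be >= 1", path), call. = FALSE)
  }
  df
}

#' @rdname read_edge_list
#' @param edges data.frame of edges.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the flat ontology format
#'
#' The ontology is stored as two files: a parent-child TSV (`child`,
#' `parent`; the root appears with parent `NA` or is absent as a child) and
#' a two-column annotation TSV (`gene`, `term`).
#'
#' @param terms_path parent-child TSV path.
#' @param annot_path annotation TSV path.
#' @return an `ontology` object (see [build_ontology()]).
#' @export
read_ontology_tsv <- function(terms_path, annot_path) {
  pc <- read_tsv_checked(terms_path, c("child", "parent"), "ontology table")
  an <- read_tsv_checked(annot_path, c("gene", "term"), "annotation table")
  build_ontology(pc, an)
}

#' @rdname read_ontology_tsv
#' @param ontology an `ontology` object.
#' @export
write_ontology_tsv <- function(ontology, terms_path, annot_path) {
  utils::write.table(ontology$parents_df, terms_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ontology$annotations_df, annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(terms_path, annot_path))
}

#' Read and write drug tables
#'
#' Target-affinity table: `drug`, `target`, `binding_class`. Morphology
#' response table: `cell_id`, `drug`, `batch` plus numeric feature columns;
#' the control condition is labeled `control` in the `drug` column.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_drug_targets_tsv <- function(path) {
  read_tsv_checked(path, c("drug", "target", "binding_class"), "drug-target table")
}

#' @rdname read_drug_targets_tsv
#' @export
read_morphology_tsv <- function(path) {
  read_tsv_checked(path, c("cell_id", "drug", "batch"), "morphology table")
}

#' @rdname read_drug_targets_tsv
#' @param df data.frame to write.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
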