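#' Read / write the pipeline's plain-text formats
#'
#' Expression travels as TSV with genes in rows (first column `gene_id`,
#' remaining columns one per sample), annotations as CSV with a `sample_id`
#' column, and gene sets as single-line GMT (set name, description, then gene
#' ids, tab-separated).
#'
#' @param path file path.
#' @name ionstim-io
NULL

#' @rdname ionstim-io
#' @param expr genes x samples numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ionstim-io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_expression_matrix(m)
}

#' @rdname ionstim-io
#' @param ann per-sample annotation data.frame.
#' @export
write_annotations_csv <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ionstim-io
#' @export
read_annotations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname ionstim-io
#' @param genes character vector of gene ids.
#' @param set_name,description GMT set name and description fields.
#' @export
write_gmt <- function(genes, path, set_name = "SIGNATURE",
                      description = "gene set") {
  writeLines(paste(c(set_name, description, genes), collapse = "\t"), path)
  invisible(path)
}

#' @rdname ionstim-io
#' @return `read_gmt()` returns a named list of character vectors, one per
#'   GMT line.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}
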