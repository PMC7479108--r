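# Plain-text interchange: TSV expression tables and metadata, newick trees
# (via ape), and JSON reports (sorted keys, so reruns are byte-identical).

#' Write an expression table to TSV
#'
#' Genes as rows (first column `gene_id`), samples as columns; 10
#' significant digits.
#'
#' @param table An [expression_table()] or plain matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(table, path) {
  df <- data.frame(gene_id = rownames(table),
                   signif(as.matrix(table), 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression table from TSV
#'
#' @param path TSV with a `gene_id` column.
#' @param metric Metric tag to attach.
#' @return An [expression_table()].
#' @export
read_expression_tsv <- function(path, metric = "TPM") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_table(m, metric)
}

#' Write sample metadata to TSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path TSV with sample_id, project_id, species, organ columns.
#' @return Data.frame.
#' @export
read_meta_tsv <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "project_id", "species", "organ")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta
}

#' Write a JSON report with sorted keys
#' @param x List to serialize.
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
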