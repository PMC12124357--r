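#' Write a copy-number matrix as TSV
#'
#' Loci as rows (first column `locus_id`), haplotypes as columns, `NA` for
#' missing calls.  Formatting is fixed so identical inputs give
#' byte-identical files.
#'
#' @param mat Numeric matrix with locus rownames and haplotype colnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(locus_id = rownames(mat),
                   format(mat, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a copy-number matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with locus rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df[[1]]
  mat
}

#' Write haplotype metadata as TSV
#'
#' @param meta Data frame with haplotype_id, sample_id, species, clade.
#' @param path Output path.
#' @export
write_meta_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read haplotype metadata
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_meta_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write classification records with a JSON summary
#'
#' Writes the per-locus classification table as TSV and, optionally, a
#' JSON side-car with tier counts and the configuration echo.
#'
#' @param records Output of [classify_strs()].
#' @param path TSV output path.
#' @param json_path Optional JSON summary path.
#' @export
write_classification <- function(records, path, json_path = NULL) {
  out <- records
  num <- vapply(out, function(x) {
    is.numeric(x) && !all(is.na(x) | x == round(x))
  }, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 10, trim = TRUE,
                                scientific = TRUE))
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(json_path)) {
    jsonlite::write_json(classification_summary(records), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
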