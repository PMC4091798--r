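#' Read and write the pipeline's plain-text formats
#'
#' Thin, validated wrappers around the tab-delimited formats the pipeline
#' exchanges: probe libraries (`probeset_id  probe_id  sequence`), count and
#' intensity matrices (first column = row ids, header row = sample ids),
#' ontology edge lists (`child  parent`), gene-to-term and family tables,
#' and one-id-per-line set files.  FASTA goes through Biostrings.
#'
#' @param path file path.
#' @return \code{read_probe_library}: data.frame with columns
#'   \code{probeset_id}, \code{probe_id}, \code{sequence}.
#' @name io
NULL

#' @rdname io
#' @export
read_probe_library <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("probeset_id", "probe_id", "sequence")
  if (!all(need %in% names(df)))
    stop("probe library must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$sequence <- toupper(df$sequence)
  df
}

#' @rdname io
#' @param probes probe library data.frame.
#' @export
write_probe_library <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (anyNA(m)) stop("matrix file contains missing values: ", path,
                     call. = FALSE)
  m
}

#' @rdname io
#' @param m numeric matrix with row and column names.
#' @param id_col name for the row-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_set_file <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname io
#' @param ids character vector.
#' @export
write_set_file <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname io
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
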