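# Plain-text I/O: sample tables, lineage lists and corpora.

#' Read / write a sample table
#'
#' The TSV dialect has columns `id`, `sequence`, `label`, `methyl_type` and
#' the 8 lineage ranks `species` ... `domain`.
#'
#' @param path TSV file.
#' @param validate validate invariants on read (default `TRUE`).
#' @return a [methyl_dataset()].
#' @export
read_samples_tsv <- function(path, validate = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  methyl_dataset(df, validate = validate)
}

#' @param dataset a [methyl_dataset()].
#' @rdname read_samples_tsv
#' @export
write_samples_tsv <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lineage list
#'
#' A pre-extracted taxonomy table (e.g. from NCBI or GTDB dumps) with the 8
#' rank columns `species` ... `domain`; empty cells become `"unknown"`.
#'
#' @param path TSV file.
#' @return list of [taxonomic_lineage()] objects.
#' @export
read_lineages_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(LINEAGE_RANKS, names(df))
  if (length(missing_cols)) {
    stop("lineage table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    do.call(taxonomic_lineage,
            as.list(vapply(LINEAGE_RANKS, function(r) df[[r]][i],
                           character(1))))
  })
}

#' Write / read a corpus as plain text
#'
#' One sentence per line, UTF-8.
#'
#' @param corpus a [build_corpus()] object.
#' @param path output file.
#' @return `path` (or the corpus), invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(corpus$sentences, con)
  invisible(path)
}

#' @param vocab_size_target vocabulary target restored on read.
#' @rdname write_corpus
#' @export
read_corpus <- function(path, vocab_size_target = 25000L) {
  sentences <- readLines(path, encoding = "UTF-8")
  structure(list(sentences = sentences,
                 vocab_size_target = as.integer(vocab_size_target),
                 metadata = list(n_samples = NA_integer_,
                                 n_extra_lineages = NA_integer_)),
            class = "methylm_corpus")
}
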