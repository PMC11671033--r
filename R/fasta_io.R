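#' Read a FASTA file
#'
#' Parses a plain-text FASTA file (nucleotide or protein) into a
#' [seq_records] collection, one record per `>` header, in file order.
#' Sequence lines belonging to one record are concatenated with line breaks
#' and surrounding whitespace removed. Both LF and CRLF line endings are
#' accepted; blank lines are skipped; records with empty bodies are retained
#' with length 0; duplicate identifiers are preserved. Residue case is kept
#' as-is and no alphabet validation is performed.
#'
#' @param path path to an existing FASTA file.
#' @return a `seq_records` data frame (columns `id`, `desc`, `seq`).
#' @seealso [write_fasta()]
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a desc", "ACGT", "ACG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path) || dir.exists(path)) {
    stop_input(sprintf(
      "[Errno 2] No such file or directory: '%s'", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop_input(sprintf("malformed FASTA file '%s': %s",
                         path, conditionMessage(e)))
    }
  )
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- sub("^[^[:space:]]*[[:space:]]*", "", headers)
  seq_records(id = id, desc = desc, seq = as.character(set))
}

#' Write records to a FASTA file
#'
#' Emits each record as `>id desc` (single space, omitted when the
#' description is empty) followed by its residues wrapped at `wrap_width`
#' characters per line. Re-reading the file with [read_fasta()] recovers the
#' input records exactly (identifier, description, residues), for any wrap
#' width.
#'
#' @param records a [seq_records] collection.
#' @param path destination file path; an existing file is overwritten.
#' @param wrap_width positive integer, residues per sequence line
#'   (default 60, the conventional FASTA width).
#' @return (invisibly) the number of records written.
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  wrap_width <- as.integer(wrap_width)
  if (is.na(wrap_width) || wrap_width < 1L) {
    stop_config("'wrap_width' must be a positive integer")
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc),
                       records$id)
  tryCatch(
    Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                                width = wrap_width),
    error = function(e) {
      stop_output(sprintf("cannot write FASTA output to '%s': %s",
                          path, conditionMessage(e)))
    }
  )
  invisible(nrow(records))
}
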