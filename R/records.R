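#' Construct a collection of sequence records
#'
#' A `seq_records` object is an ordered collection of FASTA entries, stored as
#' a data frame with one row per record and columns `id` (the first
#' whitespace-delimited token of the header), `desc` (the remainder of the
#' header line, possibly empty) and `seq` (the residue string, case
#' preserved). Length of a record is `nchar(seq)`; gap (`-`) and stop (`*`)
#' characters count toward length.
#'
#' @param id character vector of identifiers; must contain no whitespace.
#' @param desc character vector of descriptions (may be empty strings).
#'   Recycled if length 1.
#' @param seq character vector of residue strings; must contain no whitespace
#'   or `>` characters. Empty strings (length-0 records) are allowed.
#' @return a data frame of class `seq_records` with columns `id`, `desc`,
#'   `seq`.
#' @examples
#' seq_records(c("a", "b"), c("first", ""), c("ACGT", "MKV*"))
#' @export
seq_records <- function(id = character(), desc = "", seq = character()) {
  id <- as.character(id)
  seq <- as.character(seq)
  n <- length(id)
  if (length(seq) != n) {
    stop_config("'id' and 'seq' must have the same length")
  }
  desc <- rep_len(as.character(desc), n)
  if (any(grepl("[[:space:]]", id))) {
    stop_config("record identifiers must not contain whitespace")
  }
  if (any(grepl("[[:space:]>]", seq))) {
    stop_config("residue strings must not contain whitespace or '>'")
  }
  out <- data.frame(id = id, desc = desc, seq = seq,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Sequence lengths of a record collection
#'
#' @param records a `seq_records` object (or any data frame with a `seq`
#'   column).
#' @return integer vector of residue counts, one per record.
#' @export
record_lengths <- function(records) {
  nchar(records$seq, type = "chars")
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d record(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    len <- record_lengths(x)
    cat(sprintf("  lengths: min %d, max %d\n", min(len), max(len)))
    show <- utils::head(x, 5L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  >%s%s  [%d]\n", show$id[i],
                  ifelse(nzchar(show$desc[i]), paste0(" ", show$desc[i]), ""),
                  nchar(show$seq[i])))
    }
    if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  }
  invisible(x)
}
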