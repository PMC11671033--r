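#' Partition records at a length cutoff
#'
#' Splits a record collection into the two categories the tool reports:
#' sequences of length greater than or equal to the cutoff ("above") and
#' strictly shorter than the cutoff ("below"). Every input record lands in
#' exactly one side and relative input order is preserved within each side.
#' A record of length exactly `cutoff` is always "above"; at the default
#' cutoff of 200 the two sides are the above-199 and below-200 sets.
#'
#' @param records a [seq_records] collection.
#' @param cutoff positive integer length threshold (default 200, the
#'   conventional minimum length for transcriptome-assembly submission).
#' @return an object of class `length_partition`: a list with `seq_records`
#'   elements `above` and `below` and the integer `cutoff`.
#' @examples
#' recs <- seq_records(c("a", "b", "c"), "",
#'                     c(strrep("A", 150), strrep("A", 200), strrep("A", 250)))
#' p <- partition_by_length(recs, 200)
#' record_lengths(p$above)  # 200 250
#' record_lengths(p$below)  # 150
#' @export
partition_by_length <- function(records, cutoff = 200L) {
  cutoff <- suppressWarnings(as.integer(cutoff))
  if (is.na(cutoff) || cutoff < 1L) {
    stop_config("'cutoff' must be a positive integer")
  }
  len <- record_lengths(records)
  up <- len >= cutoff
  above <- records[up, , drop = FALSE]
  below <- records[!up, , drop = FALSE]
  rownames(above) <- NULL
  rownames(below) <- NULL
  class(above) <- class(below) <- c("seq_records", "data.frame")
  structure(list(above = above, below = below, cutoff = cutoff),
            class = "length_partition")
}

#' @export
print.length_partition <- function(x, ...) {
  cat(sprintf("<length_partition> cutoff %d: %d above, %d below\n",
              x$cutoff, nrow(x$above), nrow(x$below)))
  invisible(x)
}

#' Length statistics for a partition
#'
#' Computes the summary the tool writes to its stats file: the total number
#' of input sequences, and the count, minimum and maximum length on each
#' side of the cutoff. Minimum and maximum of an empty side are `NA`
#' (reported as "N/A" in the text rendering), never 0, since 0 is a valid
#' sequence length.
#'
#' @param partition a `length_partition` from [partition_by_length()].
#' @param unit length unit label: `"bp"` for nucleotide, `"aa"` for protein.
#' @return an object of class `length_stats`: a list with fields
#'   `total_count`, `above_count`, `below_count`, `above_min`, `above_max`,
#'   `below_min`, `below_max`, `input_min`, `input_max`, `cutoff`, `unit`.
#' @export
compute_stats <- function(partition, unit = c("bp", "aa")) {
  unit <- match.arg(unit)
  la <- record_lengths(partition$above)
  lb <- record_lengths(partition$below)
  rng <- function(x) {
    if (length(x) == 0L) c(NA_integer_, NA_integer_) else range(x)
  }
  ra <- rng(la)
  rb <- rng(lb)
  ri <- rng(c(la, lb))
  structure(list(
    total_count = length(la) + length(lb),
    above_count = length(la),
    below_count = length(lb),
    above_min = ra[1], above_max = ra[2],
    below_min = rb[1], below_max = rb[2],
    input_min = ri[1], input_max = ri[2],
    cutoff = partition$cutoff,
    unit = unit
  ), class = "length_stats")
}

#' Render a statistics summary as text
#'
#' Produces the human-readable lines written to
#' `seq_length_stats_by_threshold_{cutoff}.txt`: one `key: value` line per
#' field, in the order total / above count, min, max / below count, min,
#' max, with the unit embedded in the labels ("above 199 bp" / "below 200
#' bp" at the default cutoff). Undefined extremes (empty side) render as
#' "N/A".
#'
#' @param summary a `length_stats` object from [compute_stats()].
#' @return character vector of lines.
#' @export
render_stats_text <- function(summary) {
  fmt <- function(x) if (is.na(x)) "N/A" else format(x, scientific = FALSE)
  hi <- sprintf("above %d %s", summary$cutoff - 1L, summary$unit)
  lo <- sprintf("below %d %s", summary$cutoff, summary$unit)
  c(
    sprintf("Sequence length statistics (threshold = %d %s)",
            summary$cutoff, summary$unit),
    sprintf("Total input sequences: %d", summary$total_count),
    sprintf("Sequences %s: %d", hi, summary$above_count),
    sprintf("Minimum length %s: %s", hi, fmt(summary$above_min)),
    sprintf("Maximum length %s: %s", hi, fmt(summary$above_max)),
    sprintf("Sequences %s: %d", lo, summary$below_count),
    sprintf("Minimum length %s: %s", lo, fmt(summary$below_min)),
    sprintf("Maximum length %s: %s", lo, fmt(summary$below_max))
  )
}

#' @export
print.length_stats <- function(x, ...) {
  writeLines(render_stats_text(x))
  invisible(x)
}
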