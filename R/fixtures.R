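#' Specify a synthetic FASTA fixture
#'
#' Describes a reproducible synthetic FASTA input with a controlled length
#' distribution, for testing the splitting, statistics and plotting paths
#' without external data. Length models: `"ladder"` (an explicit vector of
#' lengths, deterministic), `"uniform"` (integer lengths on
#' `[min_len, max_len]`), and `"lognormal"` (rounded log-normal truncated to
#' length >= 1, the realistic default for transcript-length distributions,
#' which are heavy-tailed). The log-normal default `meanlog = 6, sdlog = 1`
#' puts the median near `exp(6) ~ 403` with substantial mass on both sides
#' of the 200-length default cutoff, so a default-sized fixture exercises
#' all four plots.
#'
#' @param n_records positive integer, number of records (ignored for
#'   `"ladder"`, where `length(ladder)` rules).
#' @param length_model `"lognormal"`, `"uniform"` or `"ladder"`.
#' @param meanlog,sdlog log-normal parameters (lognormal model).
#' @param min_len,max_len inclusive integer bounds (uniform model).
#' @param ladder integer vector of exact lengths (ladder model).
#' @param alphabet `"nucleotide"` (A/C/G/T, plus N when
#'   `ambiguity = TRUE`) or `"protein"` (the 20 standard amino-acid letters,
#'   plus `*` when `ambiguity = TRUE`).
#' @param ambiguity logical; include N (nucleotide) or `*` (protein) in the
#'   sampled alphabet.
#' @param wrap_width positive integer line width for the written file.
#' @param seed integer; the same spec and seed always produce a
#'   byte-identical file.
#' @param empty_record logical; append one record with an empty body
#'   (length 0).
#' @param duplicate_ids logical; give the second record the same identifier
#'   as the first (requires >= 2 records).
#' @param crlf logical; write the file with CRLF line endings.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_records = 1000L,
                         length_model = c("lognormal", "uniform", "ladder"),
                         meanlog = 6, sdlog = 1,
                         min_len = 1L, max_len = 500L,
                         ladder = NULL,
                         alphabet = c("nucleotide", "protein"),
                         ambiguity = FALSE,
                         wrap_width = 60L,
                         seed = 1L,
                         empty_record = FALSE,
                         duplicate_ids = FALSE,
                         crlf = FALSE) {
  length_model <- match.arg(length_model)
  alphabet <- match.arg(alphabet)
  if (length_model == "ladder") {
    if (is.null(ladder) || length(ladder) == 0L || any(ladder < 0)) {
      stop_config("ladder model requires a vector of nonnegative lengths")
    }
    n_records <- length(ladder)
  } else {
    n_records <- as.integer(n_records)
    if (is.na(n_records) || n_records < 1L) {
      stop_config("'n_records' must be a positive integer")
    }
  }
  if (length_model == "uniform" && (min_len < 0L || max_len < min_len)) {
    stop_config("uniform model requires 0 <= min_len <= max_len")
  }
  if (length_model == "lognormal" && sdlog < 0) {
    stop_config("lognormal model requires sdlog >= 0")
  }
  structure(list(
    n_records = n_records, length_model = length_model,
    meanlog = meanlog, sdlog = sdlog,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    ladder = ladder, alphabet = alphabet, ambiguity = ambiguity,
    wrap_width = as.integer(wrap_width), seed = as.integer(seed),
    empty_record = empty_record, duplicate_ids = duplicate_ids,
    crlf = crlf
  ), class = "fixture_spec")
}

fixture_alphabet <- function(spec) {
  if (spec$alphabet == "protein") {
    ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    if (spec$ambiguity) ab <- c(ab, "*")
  } else {
    ab <- c("A", "C", "G", "T")
    if (spec$ambiguity) ab <- c(ab, "N")
  }
  ab
}

sample_lengths <- function(spec) {
  switch(spec$length_model,
    ladder = as.integer(spec$ladder),
    uniform = sample(spec$min_len:spec$max_len, spec$n_records,
                     replace = TRUE),
    lognormal = pmax(1L, as.integer(round(
      stats::rlnorm(spec$n_records, spec$meanlog, spec$sdlog))))
  )
}

wrap_seq <- function(s, w) {
  n <- nchar(s)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = w)
  substring(s, starts, pmin(starts + w - 1L, n))
}

#' Generate a synthetic FASTA file
#'
#' Writes the fixture described by a [fixture_spec()] to `path` and returns
#' the records as a [seq_records] collection — identical to what
#' [read_fasta()] recovers from the file. All randomness is driven by the
#' spec's seed (the caller's RNG state is left untouched), so the same spec
#' always produces byte-identical output.
#'
#' @param spec a [fixture_spec()].
#' @param path destination file path.
#' @return (invisibly) the generated `seq_records`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' recs <- generate_fasta(fixture_spec(ladder = 1:10, length_model = "ladder"), f)
#' record_lengths(read_fasta(f))  # 1..10
#' @export
generate_fasta <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  lens <- sample_lengths(spec)
  ab <- fixture_alphabet(spec)
  seqs <- vapply(lens, function(L) {
    paste(sample(ab, L, replace = TRUE), collapse = "")
  }, character(1))
  ids <- sprintf("%s_%05d",
                 if (spec$alphabet == "protein") "pep" else "seq",
                 seq_along(seqs))
  desc <- sprintf("len=%d", lens)
  if (spec$empty_record) {
    ids <- c(ids, "empty_record")
    desc <- c(desc, "len=0")
    seqs <- c(seqs, "")
  }
  if (spec$duplicate_ids && length(ids) >= 2L) {
    ids[2L] <- ids[1L]
  }
  records <- seq_records(ids, desc, seqs)

  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    c(sprintf(">%s %s", records$id[i], records$desc[i]),
      wrap_seq(records$seq[i], spec$wrap_width))
  }), use.names = FALSE)
  eol <- if (spec$crlf) "\r\n" else "\n"
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE, after = FALSE)
  if (length(lines) > 0L) {
    writeBin(charToRaw(paste0(paste(lines, collapse = eol), eol)), con)
  }
  invisible(records)
}
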