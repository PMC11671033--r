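# Independent oracles, deliberately naive and separate from the package's
# I/O path (which goes through Biostrings).

# Line-by-line FASTA parse: returns a plain data.frame(id, desc, seq).
naive_parse_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  id <- character(0); desc <- character(0); seq <- character(0)
  cur <- -1L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      header <- substring(ln, 2L)
      toks <- regmatches(header, regexpr("^[^[:space:]]*", header))
      id <- c(id, toks)
      desc <- c(desc, trimws(substring(header, nchar(toks) + 1L)))
      seq <- c(seq, "")
      cur <- length(seq)
    } else if (cur > 0L) {
      seq[cur] <- paste0(seq[cur], trimws(ln))
    }
  }
  data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
}

# Random record collection built without the fixtures module.
random_records <- function(n, max_len = 120L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(0:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c(LETTERS, "-", "*"), L, replace = TRUE), collapse = "")
  }, character(1))
  descs <- ifelse(stats::runif(n) < 0.5, "", paste("len", lens, "extra"))
  seq_records(sprintf("r%03d", seq_len(n)), descs, seqs)
}

default_fixture <- function(path, n = 400L, seed = 11L, ...) {
  generate_fasta(fixture_spec(n_records = n, seed = seed, ...), path)
}
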