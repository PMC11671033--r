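make_recs <- function(lens) {
  seq_records(sprintf("s%04d", seq_along(lens)), "",
              vapply(lens, function(L) strrep("A", L), character(1)))
}

test_that("a record of length exactly cutoff goes to the above side", {
  p <- partition_by_length(make_recs(c(150, 200, 250)), 200)
  expect_equal(record_lengths(p$above), c(200L, 250L))
  expect_equal(record_lengths(p$below), 150L)
})

test_that("empty input partitions into two empty sides", {
  p <- partition_by_length(seq_records(), 200)
  expect_equal(nrow(p$above), 0L)
  expect_equal(nrow(p$below), 0L)
})

test_that("partition agrees record-by-record with a brute-force filter", {
  set.seed(77)
  lens <- sample(1:500, 1000, replace = TRUE)
  recs <- make_recs(lens)
  for (cutoff in c(1L, 2L, 100L, 200L)) {
    p <- partition_by_length(recs, cutoff)
    # brute force: independent loop over records
    above_ids <- character(0); below_ids <- character(0)
    for (i in seq_len(nrow(recs))) {
      if (nchar(recs$seq[i]) >= cutoff) {
        above_ids <- c(above_ids, recs$id[i])
      } else {
        below_ids <- c(below_ids, recs$id[i])
      }
    }
    expect_equal(p$above$id, above_ids)
    expect_equal(p$below$id, below_ids)
    expect_equal(nrow(p$above) + nrow(p$below), 1000L)
    if (nrow(p$above) > 0) expect_gte(min(record_lengths(p$above)), cutoff)
    if (nrow(p$below) > 0) expect_lte(max(record_lengths(p$below)), cutoff - 1L)
  }
})

test_that("boundary records land deterministically across cutoffs", {
  for (cutoff in c(1L, 2L, 100L, 200L)) {
    recs <- make_recs(c(cutoff, max(cutoff - 1L, 0L)))
    p <- partition_by_length(recs, cutoff)
    expect_true("s0001" %in% p$above$id)  # length == cutoff
    expect_true("s0002" %in% p$below$id)  # length == cutoff - 1
  }
})

test_that("invalid cutoffs are rejected", {
  expect_error(partition_by_length(seq_records(), 0), class = "slp_config_error")
  expect_error(partition_by_length(seq_records(), "x"), class = "slp_config_error")
})

test_that("compute_stats reports counts and extremes; NA for empty sides", {
  p <- partition_by_length(make_recs(c(300, 10)), 200)
  s <- compute_stats(p, "bp")
  expect_equal(s$total_count, 2L)
  expect_equal(s$above_count, 1L)
  expect_equal(s$above_min, 300L)
  expect_equal(s$above_max, 300L)
  expect_equal(s$below_count, 1L)
  expect_equal(s$below_min, 10L)
  expect_equal(s$below_max, 10L)
  expect_equal(s$input_min, 10L)
  expect_equal(s$input_max, 300L)

  s0 <- compute_stats(partition_by_length(seq_records(), 200), "bp")
  expect_equal(s0$total_count, 0L)
  expect_true(all(is.na(c(s0$above_min, s0$above_max, s0$below_min,
                          s0$below_max, s0$input_min, s0$input_max))))
})

test_that("stats match an independent recomputation on random input", {
  set.seed(99)
  lens <- sample(0:400, 500, replace = TRUE)
  s <- compute_stats(partition_by_length(make_recs(lens), 200), "bp")
  hi <- lens[lens >= 200]; lo <- lens[lens < 200]
  expect_equal(s$above_count + s$below_count, s$total_count)
  expect_equal(s$above_count, length(hi))
  expect_equal(s$above_min, min(hi))
  expect_equal(s$above_max, max(hi))
  expect_equal(s$below_min, min(lo))
  expect_equal(s$below_max, max(lo))
  expect_equal(s$input_min, min(lens))
  expect_equal(s$input_max, max(lens))
})

test_that("stats text carries unit-labelled sides and N/A for empty sides", {
  s <- compute_stats(partition_by_length(make_recs(c(300, 10)), 200), "bp")
  txt <- render_stats_text(s)
  expect_true(any(grepl("above 199 bp", txt)))
  expect_true(any(grepl("below 200 bp", txt)))
  expect_true(any(grepl("Total input sequences: 2", txt)))
  expect_true(any(grepl(": 300$", txt)))
  expect_true(any(grepl(": 10$", txt)))

  s0 <- compute_stats(partition_by_length(seq_records(), 100), "aa")
  txt0 <- render_stats_text(s0)
  expect_true(any(grepl("Total input sequences: 0", txt0)))
  expect_equal(sum(grepl("N/A$", txt0)), 4L)
  expect_true(any(grepl("above 99 aa", txt0)))
})

test_that("every number in the stats text parses back to its field", {
  set.seed(5)
  s <- compute_stats(
    partition_by_length(make_recs(sample(1:400, 200, TRUE)), 200), "bp")
  txt <- render_stats_text(s)
  grab <- function(pattern) {
    line <- grep(pattern, txt, value = TRUE)
    as.integer(sub(".*: ", "", line))
  }
  expect_equal(grab("^Total input"), s$total_count)
  expect_equal(grab("^Sequences above"), s$above_count)
  expect_equal(grab("^Minimum length above"), s$above_min)
  expect_equal(grab("^Maximum length above"), s$above_max)
  expect_equal(grab("^Sequences below"), s$below_count)
  expect_equal(grab("^Minimum length below"), s$below_min)
  expect_equal(grab("^Maximum length below"), s$below_max)
})
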