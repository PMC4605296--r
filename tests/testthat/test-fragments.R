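cs <- c(chr1 = 1000, chr2 = 500)

make_frags <- function(lens, chrom = "chr1", start = 0) {
  suppressMessages(fragments(
    tibble::tibble(chrom = chrom, start = start + seq_along(lens) * 0L,
                   end = start + lens),
    cs))
}

test_that("BED-PE fragments span the mate extremes", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c(
    "chr1\t10\t61\tchr1\t100\t151\tp1\t0\t+\t-",
    "chr1\t200\t251\tchr1\t180\t231\tp2\t0\t+\t-",
    "chr1\t5\t56\tchr1\t5\t56\tp3\t0\t+\t-"
  ), f)
  fr <- suppressMessages(read_fragments(f, "bedpe", cs))
  expect_equal(nrow(fr), 3)
  expect_equal(fr$start, c(10L, 180L, 5L))
  expect_equal(fr$end, c(151L, 251L, 56L))
})

test_that("empty input yields an empty fragment set without error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  fr <- suppressWarnings(suppressMessages(read_fragments(f, "fragment-tsv", cs)))
  expect_equal(nrow(fr), 0)
  expect_equal(nrow(length_histogram(fr)), 0)
  expect_equal(attr(length_histogram(fr), "total"), 0L)
  expect_true(is.na(attr(length_histogram(fr), "modal_length")))
})

test_that("records violating chrom_sizes are dropped; all-dropped is an error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t900\t1200", f)   # end beyond chr1
  expect_error(suppressMessages(read_fragments(f, "fragment-tsv", cs)),
               class = "nucmap_input_error")
  writeLines(c("chr1\t900\t1200", "chr1\t0\t150", "chrX\t0\t100"), f)
  expect_message(fr <- read_fragments(f, "fragment-tsv", cs), "Dropped 2")
  expect_equal(nrow(fr), 1)
  expect_equal(attr(fr, "n_invalid"), 2L)
})

test_that("unknown format and unreadable path are usage/input errors", {
  expect_error(read_fragments("x.tsv", "fancy", cs), class = "nucmap_usage_error")
  expect_error(read_fragments(file.path(tempdir(), "nope.tsv"), "fragment-tsv", cs),
               class = "nucmap_input_error")
})

test_that("BAM proper pairs reduce to the same fragments as the BED-PE truth", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    # fragment [10, 160): left mate POS 11 TLEN 150, right mate POS 110
    "r1\t99\tchr1\t11\t60\t51M\t=\t110\t150\t*\t*",
    "r1\t147\tchr1\t110\t60\t51M\t=\t11\t-150\t*\t*",
    # fragment [300, 435)
    "r2\t99\tchr1\t301\t60\t51M\t=\t385\t135\t*\t*",
    "r2\t147\tchr1\t385\t60\t51M\t=\t301\t-135\t*\t*",
    # improper pair: must be ignored
    "r3\t65\tchr1\t500\t60\t51M\t=\t700\t251\t*\t*"
  ), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  fr <- suppressMessages(read_fragments(bam, "bam", cs))
  expect_equal(nrow(fr), 2)
  expect_equal(fr$start, c(10L, 300L))
  expect_equal(fr$end, c(160L, 435L))
})

test_that("length histogram counts lengths and reports the mode", {
  fr <- make_frags(c(150, 150, 147, 200))
  h <- length_histogram(fr)
  expect_equal(h$count[h$length == 147], 1)
  expect_equal(h$count[h$length == 150], 2)
  expect_equal(h$count[h$length == 200], 1)
  expect_equal(attr(h, "total"), 4L)
  expect_equal(attr(h, "modal_length"), 150L)
})

test_that("synthetic library modal length reflects the sampling distribution", {
  fr <- sim_fragments(medium_truth(), n_fragments = 10000)
  h <- length_histogram(fr)
  expect_true(attr(h, "modal_length") >= 147 && attr(h, "modal_length") <= 153)
})

test_that("size filter bounds are inclusive and counts are conserved", {
  fr <- make_frags(c(126, 127, 168, 169))
  kept <- filter_by_length(fr)
  expect_equal(sort(kept$end - kept$start), c(127L, 168L))
  expect_equal(attr(kept, "n_kept") + attr(kept, "n_dropped"), nrow(fr))

  # brute-force recount oracle on a synthetic library
  lib <- sim_fragments(medium_truth(), n_fragments = 5000)
  flt <- filter_by_length(lib)
  lens <- lib$end - lib$start
  expect_equal(attr(flt, "n_kept"), sum(lens >= 127 & lens <= 168))
  expect_equal(attr(flt, "n_kept") + attr(flt, "n_dropped"), nrow(lib))

  # idempotence and support containment
  again <- filter_by_length(flt)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(flt), ignore_attr = TRUE)
  h <- length_histogram(flt)
  expect_true(all(h$length >= 127 & h$length <= 168))

  expect_error(filter_by_length(fr, 200, 100), class = "nucmap_usage_error")
})

test_that("fragment BED and histogram TSV round-trip", {
  fr <- make_frags(c(150, 160))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(fr, bed)
  back <- suppressMessages(read_fragments(bed, "fragment-tsv", cs))
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_length_histogram(length_histogram(fr), tsv)
  expect_equal(nrow(utils::read.table(tsv)), 2)
})
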