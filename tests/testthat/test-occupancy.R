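cs30 <- c(chrA = 30)

frag_tbl <- function(starts, ends, chrom = "chrA", sizes = cs30) {
  suppressMessages(fragments(tibble::tibble(chrom = chrom, start = starts, end = ends), sizes))
}

test_that("coverage counts fragments containing each base", {
  fr <- frag_tbl(10, 20)
  tr <- coverage_track(fr, "chrA")
  expect_equal(tr$values, c(rep(0, 10), rep(1, 10), rep(0, 10)))

  fr2 <- frag_tbl(c(10, 15), c(20, 25))
  v <- coverage_track(fr2, "chrA")$values
  expect_equal(v[16:20], rep(2, 5))
  expect_equal(v[11:15], rep(1, 5))
  expect_equal(v[21:25], rep(1, 5))

  expect_error(coverage_track(fr, "chrZ"), class = "nucmap_usage_error")
})

test_that("total coverage equals total fragment length (conservation)", {
  fr <- medium_frags()
  tr <- coverage_track(fr, "chrS")
  expect_equal(sum(tr$values), sum(fr$end - fr$start))
})

test_that("dyad-window coverage counts midpoint windows", {
  fr <- frag_tbl(10, 20)           # midpoint 15
  tr <- coverage_track(fr, "chrA", mode = "dyad", dyad_window = 2)
  expect_equal(which(tr$values == 1) - 1, 13:17)
})

test_that("Fourier filter preserves the mean and is the identity at pc_keep 1", {
  set.seed(3)
  x <- abs(rnorm(1024)) + 1
  tr <- occ_track(x, "chrA", "raw")
  sm <- fft_smooth(tr, 0.02)
  expect_lt(abs(mean(sm$values) - mean(x)), 1e-9)
  expect_lt(max(abs(fft_smooth(tr, 1)$values - x)), 1e-9)
  expect_equal(fft_smooth(occ_track(rep(4, 256), "chrA", "raw"), 0.1)$values,
               rep(4, 256))
  expect_error(fft_smooth(tr, 0), class = "nucmap_usage_error")
  expect_error(fft_smooth(sm, 0.5), class = "nucmap_usage_error")
})

test_that("Fourier filter matches a direct discrete-Fourier-sum oracle", {
  set.seed(4)
  x <- abs(rnorm(512)) + 2
  tr <- occ_track(x, "chrA", "raw")
  pc <- 0.05
  k <- ceiling(pc * length(x))
  expect_lt(max(abs(fft_smooth(tr, pc)$values - dft_lowpass_oracle(x, k))), 1e-9)

  # a pure sinusoid above the cutoff is annihilated
  n <- 1024
  supra <- sin(2 * pi * 100 * (0:(n - 1)) / n) + 5
  out <- fft_smooth(occ_track(supra, "chrA", "raw"), 0.02)
  expect_lt(max(abs(out$values - 5)), 1e-6)
})

test_that("chunked filtering does not create spurious peaks at seams", {
  # peak calls from chunk-stitched smoothing must agree with whole-signal
  # smoothing: same peak count, summits within a couple of bases
  fr <- medium_frags()
  raw <- coverage_track(fr, "chrS", mode = "dyad")
  pk_whole <- call_peaks(fft_smooth(raw), raw, fr)
  sm_chunk <- fft_smooth(raw, chunk = 2^15, overlap = 2000)
  pk_chunk <- call_peaks(sm_chunk, raw, fr)
  expect_equal(nrow(pk_chunk), nrow(pk_whole))
  expect_true(all(abs(sort(pk_chunk$center) - sort(pk_whole$center)) <= 3))
})

test_that("a flat track yields no peaks and zero coverage warns", {
  flat_raw <- occ_track(rep(3, 400), "chrA", "raw")
  flat_sm <- fft_smooth(flat_raw, 0.5)
  fr <- frag_tbl(integer(0), integer(0), sizes = c(chrA = 400))
  expect_equal(nrow(call_peaks(flat_sm, flat_raw, fr)), 0)

  zero_raw <- occ_track(rep(0, 400), "chrA", "raw")
  zero_sm <- fft_smooth(zero_raw, 0.5)
  expect_warning(pk <- call_peaks(zero_sm, zero_raw, fr), "no covered")
  expect_equal(nrow(pk), 0)
})

test_that("a planted Gaussian bump is called once at its argmax", {
  n <- 1000
  set.seed(8)
  bump <- 60 * exp(-((0:(n - 1)) - 500)^2 / (2 * 30^2))
  raw <- occ_track(bump + runif(n, 0, 0.5), "chrA", "raw")
  sm <- fft_smooth(raw, 0.02)
  # fragments phased on the bump so the positioning score is high
  mids <- 500 + round(rnorm(300, 0, 15))
  fr <- frag_tbl(mids - 73, mids + 74, sizes = c(chrA = n))
  pk <- call_peaks(sm, raw, fr)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$center - 500), 5)
})

test_that("noiseless well-separated bumps are recovered at their argmaxes", {
  n <- 2000
  centers <- c(400, 1000, 1600)
  x <- rowSums(sapply(centers, function(c0) 50 * exp(-((0:(n - 1)) - c0)^2 / (2 * 30^2))))
  raw <- occ_track(x, "chrA", "raw")
  sm <- fft_smooth(raw, 1)          # identity: noiseless argmax check
  mids <- rep(centers, each = 50)
  fr <- frag_tbl(mids - 73, mids + 74, sizes = c(chrA = n))
  pk <- call_peaks(sm, raw, fr)
  expect_equal(pk$center, centers)
})

test_that("raising min_score is monotone and summits respect min_sep", {
  fr <- medium_frags()
  raw <- coverage_track(fr, "chrS", mode = "dyad")
  sm <- fft_smooth(raw)
  n1 <- nrow(call_peaks(sm, raw, fr, peak_params(min_score = 0.25)))
  n2 <- nrow(call_peaks(sm, raw, fr, peak_params(min_score = 0.5)))
  n3 <- nrow(call_peaks(sm, raw, fr, peak_params(min_score = 0.75)))
  expect_true(n1 >= n2 && n2 >= n3)

  pk <- medium_peaks()
  expect_true(all(diff(pk$center) >= 120))
  expect_true(all(pk$score >= 0 & pk$score <= 1))
  expect_equal(pk$score, (pk$score_h + pk$score_w) / 2)
  expect_true(all(pk$start <= pk$center & pk$center < pk$end))
})

test_that("track and peak writers emit well-formed files", {
  raw <- coverage_track(frag_tbl(c(5, 5), c(15, 20)), "chrA")
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_track_bedgraph(raw, bg)
  df <- utils::read.table(bg)
  expect_true(all(df$V3 > df$V2))
  expect_true(all(df$V4 != 0))
  # reconstructed signal matches
  v <- numeric(20)
  for (i in seq_len(nrow(df))) v[(df$V2[i] + 1):df$V3[i]] <- df$V4[i]
  expect_equal(v, raw$values[1:20])

  pk <- medium_peaks()
  out <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, out)
  bed <- utils::read.table(out)
  expect_equal(nrow(bed), nrow(pk))
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
})
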