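#' Construct an occupancy track
#'
#' A per-base float signal over one chromosome, 0-based: `values[b + 1]` is
#' the signal at base `b`. `kind` distinguishes raw coverage from its
#' low-pass-filtered form.
#'
#' @param values Numeric vector, one entry per base.
#' @param chrom Chromosome name.
#' @param kind `"raw"` or `"smoothed"`.
#' @return An `occ_track` object.
#' @export
occ_track <- function(values, chrom, kind = c("raw", "smoothed")) {
  kind <- match.arg(kind)
  if (kind == "raw" && any(values < 0)) stop_usage("raw occupancy must be non-negative")
  structure(list(values = as.numeric(values), chrom = as.character(chrom), kind = kind),
            class = "occ_track")
}

#' @export
print.occ_track <- function(x, ...) {
  cat(sprintf("<occ_track> %s  %d bp  kind=%s  mean=%.4g\n",
              x$chrom, length(x$values), x$kind, mean(x$values)))
  invisible(x)
}

#' @export
length.occ_track <- function(x) length(x$values)

#' Per-base fragment coverage
#'
#' With `mode = "full"` (the default occupancy signal), `values[b]` counts
#' the fragments whose interval contains base `b`, realizing the
#' nucleosome-occupancy signal graph; the total signal equals the summed
#' length of the chromosome's fragments. With `mode = "dyad"` each fragment
#' is first trimmed to its midpoint `+/- dyad_window` before counting — the
#' sharper signal customarily used for nucleosome positioning, since the
#' midpoint of a mononucleosomal fragment estimates the dyad while the
#' full-span pileup has a plateau the width of the fragment.
#'
#' @param frags A fragment set.
#' @param chrom Chromosome to cover (must appear in the set's `chrom_sizes`).
#' @param mode `"full"` (span coverage) or `"dyad"` (midpoint-window
#'   coverage).
#' @param dyad_window Half-width in bp of the midpoint window for
#'   `mode = "dyad"` (default 20).
#' @return An `occ_track` of kind `"raw"`.
#' @export
coverage_track <- function(frags, chrom, mode = c("full", "dyad"),
                           dyad_window = 20) {
  mode <- match.arg(mode)
  cs <- chrom_sizes(frags)
  if (!chrom %in% names(cs)) stop_usage(sprintf("unknown chromosome '%s'", chrom))
  len <- as.integer(cs[[chrom]])
  sel <- frags$chrom == chrom
  s <- frags$start[sel]
  e <- frags$end[sel]
  if (mode == "dyad") {
    mid <- (s + e) %/% 2L
    s <- pmax(0L, mid - as.integer(dyad_window))
    e <- pmin(len, mid + as.integer(dyad_window) + 1L)
  }
  d <- tabulate(s + 1L, nbins = len + 1L) - tabulate(e + 1L, nbins = len + 1L)
  occ_track(cumsum(d)[seq_len(len)], chrom, "raw")
}

# Low-pass filter one vector: zero all but the lowest k = ceiling(pc_keep * n)
# frequency components of the real DFT (the zero frequency is always kept, so
# the mean is preserved exactly).
fft_lowpass <- function(x, pc_keep) {
  n <- length(x)
  k <- min(n, max(1L, as.integer(ceiling(pc_keep * n))))
  if (k >= n) return(x)
  X <- stats::fft(x)
  keep <- logical(n)
  keep[seq_len(k)] <- TRUE                  # frequencies 0 .. k-1
  if (k >= 2) keep[seq(n - k + 2L, n)] <- TRUE  # conjugate mirror of 1 .. k-1
  X[!keep] <- 0+ 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Fourier low-pass smoothing of a coverage track
#'
#' Retains only the lowest `ceiling(pc_keep * n)` frequency components of the
#' track's discrete Fourier transform (the zero-frequency component is always
#' kept, so the track mean is preserved to numerical tolerance) and inverts
#' the transform. `pc_keep = 1` is the identity. Long chromosomes are
#' processed in overlapping chunks whose inner regions are stitched, bounding
#' memory without creating seam artifacts.
#'
#' Smoothed values may dip slightly negative at sharp coverage edges (Gibbs
#' ringing); they are left unclamped so percentile thresholds in peak calling
#' are unbiased. Use [clamp_track()] before exporting a smoothed track.
#'
#' @param track A raw `occ_track`.
#' @param pc_keep Fraction of lowest-frequency components to retain, in
#'   (0, 1]. Default 0.02, the customary component-retention fraction for
#'   nucleosome coverage.
#' @param chunk,overlap Chunk length and per-side overlap (bp) for long
#'   chromosomes.
#' @return An `occ_track` of kind `"smoothed"`.
#' @export
fft_smooth <- function(track, pc_keep = 0.02, chunk = 2^20, overlap = 2000) {
  if (!inherits(track, "occ_track") || track$kind != "raw") {
    stop_usage("fft_smooth expects a raw occ_track")
  }
  if (!is.numeric(pc_keep) || length(pc_keep) != 1 || pc_keep <= 0 || pc_keep > 1) {
    stop_usage("pc_keep must lie in (0, 1]")
  }
  x <- track$values
  n <- length(x)
  if (n <= chunk) {
    sm <- fft_lowpass(x, pc_keep)
  } else {
    sm <- numeric(n)
    step <- chunk - 2L * overlap
    starts <- seq(1L, n, by = step)
    for (s in starts) {
      e <- min(n, s + chunk - 1L)
      seg <- fft_lowpass(x[s:e], pc_keep)
      keep_from <- if (s == 1L) 1L else overlap + 1L
      keep_to <- if (e == n) (e - s + 1L) else (e - s + 1L - overlap)
      sm[(s + keep_from - 1L):(s + keep_to - 1L)] <- seg[keep_from:keep_to]
      if (e == n) break
    }
  }
  structure(list(values = sm, chrom = track$chrom, kind = "smoothed"),
            class = "occ_track")
}

#' Clamp negative track values to zero (for export)
#' @param track An `occ_track`.
#' @return The track with negative values set to 0.
#' @export
clamp_track <- function(track) {
  track$values <- pmax(track$values, 0)
  track
}

#' Peak-calling parameters
#'
#' @param pc_keep Fourier component-retention fraction used upstream.
#' @param threshold_pct Percentile (0-100) of the smoothed signal defining the
#'   calling threshold; summits must exceed it strictly. Default 50.
#' @param min_score Minimum combined peak score; peaks scoring at or below it
#'   are discarded. Default 0.25.
#' @param footprint Nucleosome footprint length in bp (default 147, the DNA
#'   wrapped around the octamer).
#' @param min_sep Minimum summit separation in bp (default 120: below one
#'   footprint, so one nucleosome is never double-called, yet permissive of
#'   the short ~120 bp internucleosomal spacings seen in vivo).
#' @return A `peak_params` list.
#' @export
peak_params <- function(pc_keep = 0.02, threshold_pct = 50, min_score = 0.25,
                        footprint = 147, min_sep = 120) {
  stopifnot(pc_keep > 0, pc_keep <= 1, threshold_pct >= 0, threshold_pct <= 100,
            min_score >= 0, min_score <= 1, footprint >= 1, min_sep >= 1)
  structure(list(pc_keep = pc_keep, threshold_pct = threshold_pct,
                 min_score = min_score, footprint = as.integer(footprint),
                 min_sep = as.integer(min_sep)),
            class = "peak_params")
}

#' Call scored nucleosome peaks on a smoothed track
#'
#' Candidate summits are strict local maxima of the smoothed signal lying
#' strictly above the threshold (the `threshold_pct`-th percentile of the
#' smoothed values, by default over covered positions only, i.e. where raw
#' coverage is positive). Summits closer than `min_sep` are merged keeping the
#' higher (ties resolved leftmost). Each peak's footprint is
#' `[center - footprint/2, center + footprint/2)` clipped to the chromosome.
#'
#' Peaks are scored in `[0, 1]` as the mean of a height score and a
#' positioning (fuzziness) score: `score_h = pnorm((height - m) / s)` with
#' `m`, `s` the mean and SD of the smoothed signal over covered positions, and
#' `score_w = max(0, 1 - MAD / (footprint / 4))` where MAD is the raw median
#' absolute deviation of fragment midpoints within the footprint (a uniform
#' scatter of midpoints across the footprint scores ~0; perfectly phased
#' midpoints score 1). Peaks with combined score `<= min_score` are dropped.
#'
#' @param track Smoothed `occ_track`.
#' @param raw Matching raw `occ_track` (same chromosome and length).
#' @param frags The fragment set the tracks were built from (used for the
#'   positioning score).
#' @param params A [peak_params()] list.
#' @param threshold_over `"covered"` (default) computes the percentile over
#'   positions with raw coverage > 0; `"all"` uses every position.
#' @return Tibble of peaks sorted by center: `chrom`, `center`, `start`,
#'   `end`, `height`, `score_h`, `score_w`, `score`.
#' @export
call_peaks <- function(track, raw, frags, params = peak_params(),
                       threshold_over = c("covered", "all")) {
  threshold_over <- match.arg(threshold_over)
  if (!inherits(track, "occ_track") || track$kind != "smoothed") {
    stop_usage("call_peaks expects a smoothed track")
  }
  if (raw$chrom != track$chrom || length(raw$values) != length(track$values)) {
    stop_usage("raw and smoothed tracks must match in chromosome and length")
  }
  empty <- tibble(chrom = character(0), center = integer(0), start = integer(0),
                  end = integer(0), height = numeric(0), score_h = numeric(0),
                  score_w = numeric(0), score = numeric(0))
  covered <- raw$values > 0
  if (!any(covered)) {
    rlang::warn("no covered positions; returning zero peaks")
    return(empty)
  }
  v <- track$values
  n <- length(v)
  pool <- if (threshold_over == "covered") v[covered] else v
  thr <- stats::quantile(pool, params$threshold_pct / 100, names = FALSE)
  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] > v[i + 1] & v[i] > thr]
  if (length(cand) == 0) return(empty)

  # Merge summits closer than min_sep, keeping the higher (ties -> leftmost):
  # visit candidates by decreasing height and block min_sep neighbourhoods.
  ord <- order(-v[cand], cand)
  blocked <- logical(n)
  keep <- integer(0)
  for (ci in cand[ord]) {
    if (blocked[ci]) next
    keep <- c(keep, ci)
    lo <- max(1L, ci - params$min_sep + 1L)
    hi <- min(n, ci + params$min_sep - 1L)
    blocked[lo:hi] <- TRUE
  }
  centers0 <- sort(keep) - 1L   # back to 0-based coordinates

  fp <- params$footprint
  start0 <- pmax(0L, centers0 - fp %/% 2L)
  end0 <- pmin(n, centers0 - fp %/% 2L + fp)
  height <- v[idx(centers0)]
  m <- mean(v[covered]); s <- stats::sd(v[covered])
  score_h <- if (is.na(s) || s == 0) rep(0.5, length(height)) else pnorm((height - m) / s)

  mids <- sort((frags$start[frags$chrom == track$chrom] +
                frags$end[frags$chrom == track$chrom]) %/% 2L)
  half <- fp / 2
  score_w <- vapply(centers0, function(ct) {
    lo <- findInterval(ct - half, mids, left.open = TRUE) + 1L
    hi <- findInterval(ct + half, mids)
    if (hi - lo + 1L < 2L) return(0)
    w <- mids[lo:hi]
    max(0, 1 - stats::mad(w, constant = 1) / (fp / 4))
  }, numeric(1))

  out <- tibble(
    chrom = track$chrom, center = centers0, start = start0, end = end0,
    height = height, score_h = as.numeric(score_h), score_w = score_w,
    score = (as.numeric(score_h) + score_w) / 2
  )
  dplyr::arrange(out[out$score > params$min_score, ], .data$center)
}

#' Write an occupancy track as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are omitted.
#'
#' @param track An `occ_track` (negative values are clamped for export).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  v <- pmax(track$values, 0)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  readr::write_tsv(
    tibble(chrom = track$chrom, start = starts[keep], end = ends[keep],
           value = signif(r$values[keep], 6)),
    path, col_names = FALSE)
  invisible(path)
}

#' Write called peaks as BED6+ TSV
#'
#' Columns: chrom, start, end, name, score (combined score scaled 0-1000),
#' strand ".", then height, score_h, score_w.
#'
#' @param peaks A [call_peaks()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = as.integer(round(peaks$score * 1000)), strand = ".",
    height = signif(peaks$height, 6), score_h = signif(peaks$score_h, 4),
    score_w = signif(peaks$score_w, 4)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
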