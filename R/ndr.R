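check_peaks_sorted <- function(peaks) {
  if (nrow(peaks) < 2) return(invisible(TRUE))
  o <- order(peaks$chrom, peaks$center)
  if (!identical(o, seq_len(nrow(peaks)))) {
    stop_usage("peaks must be sorted by (chrom, center)")
  }
  invisible(TRUE)
}

#' Internucleosomal distance distribution
#'
#' The internucleosomal distance is the distance between adjacent called
#' peaks; by default center-to-center (parameter-free), optionally
#' edge-to-edge of the called footprints. Each chromosome with `k >= 2` peaks
#' contributes `k - 1` distances. A Gaussian kernel density (Silverman
#' bandwidth, evaluated on a log-spaced grid to resolve the heavy right tail)
#' summarizes the genome-wide distribution.
#'
#' @param peaks Peak tibble sorted by (chrom, center).
#' @param method `"center"` (default) or `"edge"`.
#' @return An `ndr_size_dist` object: `sizes` (integer multiset), `density`
#'   (tibble `size`, `density` integrating to 1), `bw`, `mode` (grid argmax).
#' @export
internucleosomal_distances <- function(peaks, method = c("center", "edge")) {
  method <- match.arg(method)
  check_peaks_sorted(peaks)
  sizes <- unlist(lapply(split(peaks, peaks$chrom), function(p) {
    if (nrow(p) < 2) return(integer(0))
    if (method == "center") diff(p$center) else p$start[-1] - p$end[-nrow(p)]
  }), use.names = FALSE)
  new_ndr_size_dist(as.integer(sizes))
}

new_ndr_size_dist <- function(sizes) {
  if (length(sizes) == 0) {
    den <- tibble(size = numeric(0), density = numeric(0))
    return(structure(list(sizes = sizes, density = den, bw = NA_real_,
                          mode = NA_real_), class = "ndr_size_dist"))
  }
  s <- as.numeric(sizes)
  bw <- if (length(s) >= 2) stats::bw.nrd0(s) else 0
  if (bw == 0) bw <- max(1, 0.1 * abs(mean(s)))
  lo <- min(s) - 6 * bw
  hi <- max(s) + 6 * bw
  # log-spaced evaluation resolves the heavy right tail; fall back to linear
  # spacing if the padded support is not strictly positive (edge-to-edge
  # distances can be <= 0 when footprints overlap)
  grid <- if (lo > 0) exp(seq(log(lo), log(hi), length.out = 2048)) else
    seq(lo, hi, length.out = 2048)
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = s, sd = bw)), numeric(1))
  structure(list(
    sizes = sizes,
    density = tibble(size = grid, density = dens),
    bw = bw,
    mode = grid[which.max(dens)]
  ), class = "ndr_size_dist")
}

#' @export
print.ndr_size_dist <- function(x, ...) {
  cat(sprintf("<ndr_size_dist> n=%d  median=%s bp  mode~%.0f bp\n",
              length(x$sizes),
              if (length(x$sizes)) stats::median(x$sizes) else NA, x$mode))
  invisible(x)
}

#' Call nucleosome-depleted regions
#'
#' An NDR is any internucleosomal region without a called peak: one NDR per
#' adjacent peak pair on each chromosome, spanning center to center. The
#' regions before the first and after the last peak of a chromosome are not
#' NDRs (no flanking pair).
#'
#' @param peaks Peak tibble sorted by (chrom, center).
#' @return Tibble `chrom`, `start`, `end`, `size`, `left_peak`, `right_peak`
#'   (peak row indices in `peaks`).
#' @export
call_ndrs <- function(peaks) {
  check_peaks_sorted(peaks)
  peaks$.row <- seq_len(nrow(peaks))
  parts <- lapply(split(peaks, peaks$chrom), function(p) {
    if (nrow(p) < 2) return(NULL)
    k <- nrow(p)
    tibble(chrom = p$chrom[-k], start = p$center[-k], end = p$center[-1],
           size = diff(p$center), left_peak = p$.row[-k], right_peak = p$.row[-1])
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  size = integer(0), left_peak = integer(0), right_peak = integer(0)))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' NDRs overlapping query intervals
#'
#' For each query interval, reports the overlapping NDRs with their sizes and
#' the quantile of each size within the genome-wide size distribution — the
#' dots-on-the-distribution comparison of locus NDRs to the whole genome.
#'
#' @param ndrs A [call_ndrs()] tibble.
#' @param query Data frame of intervals (`chrom`, `start`, `end`).
#' @return Tibble with one row per (query, overlapping NDR) pair: query
#'   coordinates, NDR coordinates, `size`, and `size_quantile` (empirical CDF
#'   of the genome-wide sizes at `size`).
#' @export
ndrs_at <- function(ndrs, query) {
  query <- tibble::as_tibble(query)
  if (nrow(ndrs) == 0 || nrow(query) == 0) {
    return(tibble(query_chrom = character(0), query_start = integer(0),
                  query_end = integer(0), chrom = character(0),
                  start = integer(0), end = integer(0), size = integer(0),
                  size_quantile = numeric(0)))
  }
  cdf <- stats::ecdf(ndrs$size)
  rows <- purrr::pmap(list(query$chrom, query$start, query$end), function(qc, qs, qe) {
    hit <- ndrs$chrom == qc & ndrs$start < qe & ndrs$end > qs
    if (!any(hit)) return(NULL)
    tibble(query_chrom = qc, query_start = qs, query_end = qe,
           chrom = ndrs$chrom[hit], start = ndrs$start[hit], end = ndrs$end[hit],
           size = ndrs$size[hit], size_quantile = cdf(ndrs$size[hit]))
  })
  dplyr::bind_rows(rows)
}

#' Write NDRs as BED4 with size
#' @param ndrs A [call_ndrs()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ndrs_bed <- function(ndrs, path) {
  out <- tibble(chrom = ndrs$chrom, start = ndrs$start, end = ndrs$end,
                name = sprintf("ndr_%d_%dbp", seq_len(nrow(ndrs)), ndrs$size))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write an NDR size distribution as TSV
#' @param dist An `ndr_size_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ndr_distribution <- function(dist, path) {
  readr::write_tsv(dist$density, path, col_names = FALSE)
  invisible(path)
}
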