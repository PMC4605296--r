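#' Construct feature sites from a data frame
#'
#' Scored point features (e.g. ChIP-defined ORC binding sites), unstranded.
#'
#' @param df Data frame with `chrom`, `center`, `score`.
#' @return A `nuc_sites` tibble.
#' @export
feature_sites <- function(df) {
  if (!all(c("chrom", "center", "score") %in% names(df))) {
    stop_usage("sites need columns chrom, center, score")
  }
  if (any(!is.finite(df$score))) stop_input("non-finite site score")
  out <- tibble(chrom = as.character(df$chrom), center = as.integer(df$center),
                score = as.numeric(df$score))
  structure(out, class = c("nuc_sites", class(out)))
}

#' Load scored feature sites from BED
#'
#' Reads a BED file with a numeric score (column 5 of BED6, or a 4-column
#' `chrom start end score` TSV) and keeps sites with `score >= min_score`.
#' The default threshold 7.5 matches the customary cutoff for significant
#' ORC ChIP sites. The site center is the interval midpoint (floored for odd
#' widths).
#'
#' @param path Input file (tab-separated, no header).
#' @param min_score Inclusive score threshold; default 7.5. Use `-Inf` to keep
#'   all sites.
#' @return A [feature_sites()] tibble.
#' @export
load_sites <- function(path, min_score = 7.5) {
  if (!file.exists(path)) stop_input(sprintf("cannot read sites file '%s'", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  score_col <- if (ncol(raw) >= 5) 5L else if (ncol(raw) == 4) 4L else
    stop_input("sites file needs >= 4 columns (chrom, start, end, [name,] score)")
  score <- suppressWarnings(as.numeric(raw[[score_col]]))
  if (anyNA(score)) {
    stop_input(sprintf("malformed score on line %d of '%s'",
                       which(is.na(score))[1], path))
  }
  start <- as.integer(raw[[2]]); end <- as.integer(raw[[3]])
  keep <- score >= min_score
  feature_sites(tibble(
    chrom = raw[[1]][keep],
    center = start[keep] + (end[keep] - start[keep]) %/% 2L,
    score = score[keep]
  ))
}

#' Meta-occupancy profile around feature sites
#'
#' Averages an occupancy track in a window of `2 * half_width + 1` bases
#' centered on each site, the standard "average occupancy around ChIP site
#' centers" plot. Sites closer than `half_width` to a chromosome end are
#' dropped and counted. Under `"genome-mean"` normalization the profile is
#' divided by the mean track value over covered (positive) positions, so a
#' constant track profiles at 1.
#'
#' @param tracks A single `occ_track` or a list of tracks (one per
#'   chromosome; names are taken from the tracks themselves).
#' @param sites A [feature_sites()] tibble.
#' @param half_width Half-window in bp (default 1000).
#' @param normalization `"genome-mean"` (default) or `"raw"`.
#' @return A `meta_profile` tibble (`offset`, `mean_occ`) with attributes
#'   `n_sites`, `n_dropped`, `normalization`.
#' @export
meta_occupancy <- function(tracks, sites, half_width = 1000,
                           normalization = c("genome-mean", "raw")) {
  normalization <- match.arg(normalization)
  if (inherits(tracks, "occ_track")) tracks <- list(tracks)
  names(tracks) <- vapply(tracks, function(t) t$chrom, character(1))
  offsets <- (-half_width):half_width
  acc <- numeric(length(offsets))
  n_used <- 0L; n_dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    tr <- tracks[[sites$chrom[i]]]
    if (is.null(tr)) { n_dropped <- n_dropped + 1L; next }
    ct <- sites$center[i]
    if (ct - half_width < 0 || ct + half_width >= length(tr$values)) {
      n_dropped <- n_dropped + 1L
      next
    }
    acc <- acc + tr$values[idx(ct + offsets)]
    n_used <- n_used + 1L
  }
  if (n_dropped > 0) {
    rlang::inform(sprintf("Dropped %d site(s) within half_width of a chromosome end or on an absent chromosome", n_dropped))
  }
  if (n_used == 0) stop_usage("no sites remain after edge filtering")
  mean_occ <- acc / n_used
  if (normalization == "genome-mean") {
    all_v <- unlist(lapply(tracks, `[[`, "values"), use.names = FALSE)
    gm <- mean(all_v[all_v > 0])
    if (!is.finite(gm) || gm == 0) stop_usage("cannot normalize: no covered positions")
    mean_occ <- mean_occ / gm
  }
  out <- tibble(offset = offsets, mean_occ = mean_occ)
  structure(out, n_sites = n_used, n_dropped = n_dropped,
            normalization = normalization,
            class = c("meta_profile", class(out)))
}

#' Site score versus containing-NDR size
#'
#' For every site (typically all scores, unfiltered), finds the NDR whose
#' half-open interval contains the site center and pairs the site score with
#' that NDR's size; sites falling on or outside peak summits have no
#' containing NDR and are excluded with a count. The Spearman rank correlation
#' of the pairs tests whether stronger-bound sites sit in larger depleted
#' regions.
#'
#' @param sites A [feature_sites()] tibble.
#' @param ndrs A [call_ndrs()] tibble.
#' @return A `score_ndr` object: `pairs` tibble (`chrom`, `center`, `score`,
#'   `ndr_size`), `spearman_rho`, `n_excluded`.
#' @export
score_vs_ndr <- function(sites, ndrs) {
  pairs <- purrr::pmap(list(sites$chrom, sites$center, sites$score),
                       function(ch, ct, sc) {
    hit <- which(ndrs$chrom == ch & ndrs$start <= ct & ct < ndrs$end)
    if (length(hit) == 0) return(NULL)
    tibble(chrom = ch, center = ct, score = sc, ndr_size = ndrs$size[hit[1]])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble(chrom = character(0), center = integer(0),
                    score = numeric(0), ndr_size = integer(0))
  }
  rho <- if (nrow(pairs) >= 3 && stats::sd(pairs$score) > 0 &&
             stats::sd(pairs$ndr_size) > 0) {
    stats::cor(pairs$score, pairs$ndr_size, method = "spearman")
  } else {
    NA_real_
  }
  structure(list(pairs = pairs, spearman_rho = rho,
                 n_excluded = nrow(sites) - nrow(pairs)),
            class = "score_ndr")
}

#' @export
print.score_ndr <- function(x, ...) {
  cat(sprintf("<score_ndr> %d pairs (%d sites excluded)  Spearman rho = %s\n",
              nrow(x$pairs), x$n_excluded, format(x$spearman_rho, digits = 3)))
  invisible(x)
}

#' Write a meta profile as TSV
#' @param profile A [meta_occupancy()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path, col_names = FALSE)
  invisible(path)
}
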