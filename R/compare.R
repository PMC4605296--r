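# Coerce a track-like object to a per-base numeric vector.
track_values <- function(x) {
  if (inherits(x, "occ_track")) x$values
  else if (inherits(x, "pred_occupancy")) x$occ
  else if (is.numeric(x)) as.numeric(x)
  else stop_usage("expected an occ_track, pred_occupancy, or numeric vector")
}

#' Compare two occupancy tracks over a region
#'
#' Mean-bins both tracks at `bin` bp over the region, drops bins where either
#' track is undefined (NA), and reports Pearson and Spearman correlations over
#' the shared bins — the quantitative form of overlaying an observed and a
#' predicted occupancy profile.
#'
#' @param a,b Tracks (`occ_track`, `pred_occupancy`, or numeric vectors on the
#'   same coordinates).
#' @param region Optional `c(start, end)` 0-based half-open interval; default
#'   is the full shared extent.
#' @param bin Bin size in bp (default 50); `bin = 1` compares per-base values.
#' @return A `track_comparison`: `pearson_r`, `spearman_rho`, `bin`, `n_bins`,
#'   `n_dropped`.
#' @export
compare_tracks <- function(a, b, region = NULL, bin = 50) {
  va <- track_values(a)
  vb <- track_values(b)
  if (is.null(region)) region <- c(0, min(length(va), length(vb)))
  if (region[1] < 0 || region[2] > min(length(va), length(vb))) {
    stop_usage("region outside the tracks' shared extent")
  }
  if (diff(region) < 3 * bin) stop_usage("region must span at least 3 bins")
  sel <- (region[1] + 1):region[2]
  va <- va[sel]; vb <- vb[sel]
  g <- (seq_along(va) - 1) %/% bin
  ma <- tapply(va, g, mean)
  mb <- tapply(vb, g, mean)
  ok <- is.finite(ma) & is.finite(mb)
  n_dropped <- sum(!ok)
  if (sum(ok) < 3) stop_usage("fewer than 3 shared bins")
  structure(list(
    pearson_r = stats::cor(ma[ok], mb[ok], method = "pearson"),
    spearman_rho = stats::cor(ma[ok], mb[ok], method = "spearman"),
    bin = bin, n_bins = sum(ok), n_dropped = n_dropped
  ), class = "track_comparison")
}

#' @export
print.track_comparison <- function(x, ...) {
  cat(sprintf("<track_comparison> r=%.3f  rho=%.3f  (%d bins of %d bp)\n",
              x$pearson_r, x$spearman_rho, x$n_bins, x$bin))
  invisible(x)
}

#' Read an in-vitro binding profile
#'
#' @param path 4-column TSV: chrom, start, end, relative binding (no header).
#' @return Tibble `chrom`, `start`, `end`, `binding`.
#' @export
read_binding_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "binding"),
                  col_types = "ciid", progress = FALSE)
}

#' Occupancy versus in-vitro binding fragments
#'
#' For each naked-DNA fragment with a measured relative binding value,
#' computes the mean in-vivo occupancy over its interval and correlates
#' binding with occupancy across fragments (Spearman as the headline
#' statistic: the biological claim is ordinal — an inverse relationship gives
#' a negative rho). Fragments are summarized by mean (not summed) occupancy so
#' long fragments are not overweighted. A one-sided permutation test (shuffle
#' binding values, count permutations at least as negative) gives the p-value.
#'
#' @param track An `occ_track`.
#' @param profile Tibble of fragments `chrom`, `start`, `end`, `binding`
#'   (binding finite, >= 0). Fragments outside the track are dropped and
#'   counted; at least 3 usable fragments are required.
#' @param n_perm Permutations for the p-value (default 999; 0 skips it).
#' @param seed Optional RNG seed for the permutations.
#' @return An `occ_binding` object: `pairs` tibble (fragments plus
#'   `mean_occ`), `spearman_rho`, `pearson_r`, `p_perm`, `n_dropped`,
#'   `reason` (NA, or why the correlation is undefined).
#' @export
occupancy_vs_binding <- function(track, profile, n_perm = 999, seed = NULL) {
  profile <- tibble::as_tibble(profile)
  if (any(!is.finite(profile$binding)) || any(profile$binding < 0)) {
    stop_input("binding values must be finite and non-negative")
  }
  inb <- profile$chrom == track$chrom & profile$start >= 0 &
    profile$end <= length(track$values) & profile$end > profile$start
  n_dropped <- sum(!inb)
  if (n_dropped > 0) {
    rlang::inform(sprintf("Dropped %d fragment(s) outside the track bounds", n_dropped))
  }
  pf <- profile[inb, , drop = FALSE]
  if (nrow(pf) < 3) stop_usage("need at least 3 fragments within the track")
  cs <- c(0, cumsum(track$values))
  pf$mean_occ <- (cs[pf$end + 1] - cs[pf$start + 1]) / (pf$end - pf$start)

  rho <- NA_real_; r <- NA_real_; p_perm <- NA_real_; reason <- NA_character_
  if (stats::sd(pf$binding) == 0 || stats::sd(pf$mean_occ) == 0) {
    reason <- "zero variance"
  } else {
    rho <- stats::cor(pf$binding, pf$mean_occ, method = "spearman")
    r <- stats::cor(pf$binding, pf$mean_occ, method = "pearson")
    if (n_perm > 0) {
      p_perm <- with_seed(seed, {
        perm <- vapply(seq_len(n_perm), function(k) {
          stats::cor(sample(pf$binding), pf$mean_occ, method = "spearman")
        }, numeric(1))
        (1 + sum(perm <= rho)) / (n_perm + 1)
      })
    }
  }
  structure(list(pairs = pf, spearman_rho = rho, pearson_r = r,
                 p_perm = p_perm, n_dropped = n_dropped, reason = reason),
            class = "occ_binding")
}

#' @export
print.occ_binding <- function(x, ...) {
  if (!is.na(x$reason)) {
    cat(sprintf("<occ_binding> %d fragments  correlation undefined (%s)\n",
                nrow(x$pairs), x$reason))
  } else {
    cat(sprintf("<occ_binding> %d fragments  rho=%.3f  r=%.3f  perm p=%s\n",
                nrow(x$pairs), x$spearman_rho, x$pearson_r,
                format(x$p_perm, digits = 3)))
  }
  invisible(x)
}
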