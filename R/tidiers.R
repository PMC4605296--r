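#' Tidy an occupancy track
#'
#' @param x An `occ_track`.
#' @param ... Unused.
#' @return Tibble `chrom`, `pos` (0-based), `value`.
#' @method tidy occ_track
#' @export
tidy.occ_track <- function(x, ...) {
  tibble(chrom = x$chrom, pos = 0:(length(x$values) - 1L), value = x$values)
}

#' Tidy an energy track
#' @param x An `energy_track`.
#' @param ... Unused.
#' @return Tibble `pos` (0-based footprint start), `energy`, `contains_n`.
#' @method tidy energy_track
#' @export
tidy.energy_track <- function(x, ...) {
  tibble(pos = 0:(length(x$E) - 1L), energy = x$E, contains_n = x$contains_n)
}

#' Tidy a predicted-occupancy object
#' @param x A `pred_occupancy`.
#' @param ... Unused.
#' @return Tibble `pos` (0-based base), `occ`.
#' @method tidy pred_occupancy
#' @export
tidy.pred_occupancy <- function(x, ...) {
  tibble(pos = 0:(length(x$occ) - 1L), occ = x$occ)
}

#' Tidy an NDR size distribution
#' @param x An `ndr_size_dist`.
#' @param ... Unused.
#' @return The density tibble (`size`, `density`).
#' @method tidy ndr_size_dist
#' @export
tidy.ndr_size_dist <- function(x, ...) x$density

#' Tidy a score-vs-NDR result
#' @param x A `score_ndr`.
#' @param ... Unused.
#' @return The (score, ndr_size) pairs tibble.
#' @method tidy score_ndr
#' @export
tidy.score_ndr <- function(x, ...) x$pairs

#' Tidy an occupancy-vs-binding result
#' @param x An `occ_binding`.
#' @param ... Unused.
#' @return The per-fragment pairs tibble.
#' @method tidy occ_binding
#' @export
tidy.occ_binding <- function(x, ...) x$pairs

#' One-row summary of a track comparison
#' @param x A `track_comparison`.
#' @param ... Unused.
#' @return Tibble with `pearson_r`, `spearman_rho`, `bin`, `n_bins`,
#'   `n_dropped`.
#' @method glance track_comparison
#' @export
glance.track_comparison <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
         bin = x$bin, n_bins = x$n_bins, n_dropped = x$n_dropped)
}

#' One-row summary of an occupancy-vs-binding analysis
#' @param x An `occ_binding`.
#' @param ... Unused.
#' @return Tibble with `spearman_rho`, `pearson_r`, `p_perm`, `n_fragments`,
#'   `n_dropped`, `reason`.
#' @method glance occ_binding
#' @export
glance.occ_binding <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho, pearson_r = x$pearson_r,
         p_perm = x$p_perm, n_fragments = nrow(x$pairs),
         n_dropped = x$n_dropped, reason = x$reason)
}

#' One-row summary of a score-vs-NDR analysis
#' @param x A `score_ndr`.
#' @param ... Unused.
#' @return Tibble with `spearman_rho`, `n_pairs`, `n_excluded`.
#' @method glance score_ndr
#' @export
glance.score_ndr <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho, n_pairs = nrow(x$pairs),
         n_excluded = x$n_excluded)
}
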